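# Promoter extraction and IUPAC consensus scanning for cis-regulatory
# elements (G-box/E-box and the common stress-responsive elements).

.iupac_letters <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                    "B", "D", "H", "V", "N")

#' Load a motif-definition table
#'
#' Reads a TSV with columns `name`, `consensus`, `both_strands`
#' (TRUE/FALSE). Consensi must be IUPAC degenerate DNA strings of length
#' >= 4. With no argument, the bundled representative table is loaded
#' (G-box CACGTG, E-box CANNTG, ABRE ACGTG, MBS CAACTG, MRE AACCTAA, HSE
#' AAAAAATTTC, LTR CCGAAA, CRT/DRE RCCGAC, P-box CCTTTTG, TATC-box
#' TATCCCA). The table is data, not code: edit or replace it freely.
#'
#' @param path Path to a motif TSV; default the bundled table.
#' @return Tibble `name`, `consensus`, `both_strands`.
#' @export
load_motifs <- function(path = NULL) {
  path <- path %||% system.file("extdata", "motifs.tsv", package = "genefam")
  tb <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  tb <- as_tibble(tb)
  stopifnot(all(c("name", "consensus", "both_strands") %in% names(tb)))
  tb$consensus <- toupper(tb$consensus)
  bad <- map_lgl(strsplit(tb$consensus, ""), function(ch) any(!ch %in% .iupac_letters))
  if (any(bad)) {
    abort(sprintf("invalid IUPAC letter in motif(s): %s",
                  paste(tb$name[bad], collapse = ", ")))
  }
  if (any(nchar(tb$consensus) < 4)) abort("motif consensi must be at least 4 nt")
  tb$both_strands <- as.logical(tb$both_strands)
  tb
}

#' Extract promoters from a genome and gene models
#'
#' Strand-aware upstream region of `length` nt ending immediately before
#' the translation start (the first base of the first CDS exon in
#' transcript order). Minus-strand promoters are reverse-complemented so
#' that position 1 is the most distal base and the last base abuts the ATG.
#' Regions running off the contig edge are clipped and flagged.
#'
#' @param genome A named character vector / `DNAStringSet` of contigs, or a
#'   FASTA path.
#' @param models Gene-model tibble from [parse_gene_models()].
#' @param length Promoter length in nt (default 2000, a conventional choice
#'   for plant promoter scans).
#' @return Tibble `gene_id`, `promoter`, `length`, `clipped`.
#' @export
extract_promoters <- function(genome, models, length = 2000) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  seqs <- if (inherits(genome, "DNAStringSet")) {
    setNames(as.character(genome), names(genome))
  } else genome
  rows <- map(seq_len(nrow(models)), function(i) {
    chr <- models$chromosome[i]
    if (!chr %in% names(seqs)) {
      inform(sprintf("extract_promoters: contig %s absent for %s; skipped",
                     chr, models$gene_id[i]))
      return(NULL)
    }
    contig <- seqs[[chr]]
    ex <- models$exons[[i]]
    strand <- models$strand[i]
    if (strand == "+") {
      tss <- min(ex$start[1], ex$end[1])
      from <- max(1, tss - length); to <- tss - 1
      if (to < from) return(tibble(gene_id = models$gene_id[i], promoter = "",
                                   length = 0L, clipped = TRUE))
      p <- substr(contig, from, to)
      clipped <- (tss - length) < 1
    } else {
      tss <- max(ex$start[1], ex$end[1])
      from <- tss + 1; to <- min(nchar(contig), tss + length)
      if (to < from) return(tibble(gene_id = models$gene_id[i], promoter = "",
                                   length = 0L, clipped = TRUE))
      p <- revcomp(substr(contig, from, to))
      clipped <- (tss + length) > nchar(contig)
    }
    tibble(gene_id = models$gene_id[i], promoter = p,
           length = nchar(p), clipped = clipped)
  })
  bind_rows(rows)
}

# single-sequence scan of one consensus on the forward strand
.scan_one <- function(sequence, consensus) {
  hits <- Biostrings::matchPattern(consensus, Biostrings::DNAString(sequence),
                                   fixed = "subject")
  IRanges::start(hits@ranges)
}

#' Scan sequences for IUPAC consensus motifs
#'
#' Reports every position where the consensus matches. Degenerate letters in
#' the consensus match their IUPAC sets; an `N` in the *sequence* never
#' matches anything. For motifs with `both_strands = TRUE`, reverse-strand
#' hits are reported at the 1-based position of the match on the forward
#' sequence. A palindromic consensus (its own reverse complement, e.g. the
#' G-box CACGTG) would hit both strands at every site; only the + strand
#' record is kept. Overlapping hits of the same motif are all reported.
#'
#' @param sequences Tibble with `gene_id` and a sequence column
#'   (`promoter` or `sequence`), or a named character vector.
#' @param motifs Motif table from [load_motifs()].
#' @return Tibble `gene_id`, `motif`, `position`, `strand`,
#'   `matched_sequence`, sorted by gene and position.
#' @export
scan_motifs <- function(sequences, motifs = load_motifs()) {
  if (is.data.frame(sequences)) {
    col <- intersect(c("promoter", "sequence"), names(sequences))[1]
    seqs <- setNames(sequences[[col]], sequences$gene_id)
  } else {
    seqs <- sequences
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  }
  motifs <- mutate(motifs,
                   rc = map_chr(.data$consensus, revcomp),
                   palindromic = .data$consensus == .data$rc)
  rows <- imap(seqs, function(s, id) {
    s <- toupper(s)
    if (nchar(s) == 0) return(NULL)
    per_motif <- map(seq_len(nrow(motifs)), function(m) {
      cons <- motifs$consensus[m]
      w <- nchar(cons)
      fwd <- .scan_one(s, cons)
      out <- if (length(fwd)) {
        tibble(gene_id = id, motif = motifs$name[m], position = fwd,
               strand = "+",
               matched_sequence = substring(s, fwd, fwd + w - 1))
      } else NULL
      if (motifs$both_strands[m] && !motifs$palindromic[m]) {
        rev_hits <- .scan_one(s, motifs$rc[m])
        if (length(rev_hits)) {
          out <- bind_rows(out, tibble(
            gene_id = id, motif = motifs$name[m], position = rev_hits,
            strand = "-",
            matched_sequence = substring(s, rev_hits, rev_hits + w - 1)
          ))
        }
      }
      out
    })
    bind_rows(per_motif)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(gene_id = character(0), motif = character(0),
                  position = integer(0), strand = character(0),
                  matched_sequence = character(0)))
  }
  # an ambiguous base in the sequence never matches any consensus letter
  out <- filter(out, !grepl("[^ACGT]", .data$matched_sequence))
  arrange(out, .data$gene_id, .data$position, .data$motif)
}

#' Presence/absence matrix and group fractions of motif hits
#'
#' Per-gene boolean presence for every motif (idempotent in hit
#' multiplicity), plus "any-of" fractions over named motif groups (e.g. the
#' share of promoters carrying a G-box or E-box).
#'
#' @param hits Tibble from [scan_motifs()].
#' @param gene_set Character vector of genes to tabulate (genes without hits
#'   get all-FALSE rows).
#' @param motif_groups Named list of motif-name vectors, e.g.
#'   `list(gbox_or_ebox = c("G-box", "E-box"))`.
#' @return List with `presence` (tibble, one row per gene, one logical
#'   column per motif) and `group_fractions` (tibble `group`, `n_genes`,
#'   `n_with`, `fraction`).
#' @export
summarize_elements <- function(hits, gene_set, motif_groups = list()) {
  if (length(gene_set) == 0) abort("summarize_elements: empty gene set")
  motifs <- sort(unique(hits$motif))
  presence <- tibble(gene_id = gene_set)
  for (m in motifs) {
    with_m <- unique(hits$gene_id[hits$motif == m])
    presence[[m]] <- gene_set %in% with_m
  }
  fractions <- bind_rows(imap(motif_groups, function(ms, nm) {
    ms <- intersect(ms, motifs)
    has <- if (length(ms) == 0) rep(FALSE, length(gene_set)) else {
      rowSums(as.matrix(presence[, ms, drop = FALSE])) > 0
    }
    tibble(group = nm, n_genes = length(gene_set), n_with = sum(has),
           fraction = mean(has))
  }))
  list(presence = presence, group_fractions = fractions)
}
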