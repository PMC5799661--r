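# Synthetic gene models: introns with planted phases inserted into a CDS,
# a genomic fragment carrying the locus, and FASTA/GFF3 writers so the
# structures round-trip through the GFF3 parser.

#' Generate a gene model with planted intron phases
#'
#' Inserts `length(intron_phases)` introns into the CDS at randomly chosen
#' cut points consistent with the requested phases (phase p = cumulative
#' CDS length before the intron modulo 3), embeds the exons in a genomic
#' fragment with `offset` nt of random flank on each side, and returns both
#' the fragment and a gene-model row in the layout of
#' [parse_gene_models()]. Introns carry canonical GT...AG ends. On the
#' minus strand the fragment is reverse-complemented, so exon coordinates
#' descend in transcript order while the spliced CDS still reproduces the
#' input exactly.
#'
#' @param cds Coding sequence (length divisible by 3).
#' @param intron_phases Integer vector over `{0, 1, 2}`; empty for an
#'   intron-less gene.
#' @param intron_length Intron length in nt (default 200, >= 4 for the
#'   splice dinucleotides).
#' @param chromosome Contig name.
#' @param strand `"+"` or `"-"`.
#' @param offset Flank length on each side of the gene (default 500).
#' @param gene_id Identifier (default `"gene1"`).
#' @param seed Integer seed.
#' @return List: `model` (one-row tibble: `gene_id`, `chromosome`,
#'   `strand`, `n_exons`, `cds_length`, `valid`, `exons` list-column in
#'   transcript order), `fragment` (named character, the contig sequence),
#'   `phases` (the planted phases).
#' @export
generate_gene_model <- function(cds, intron_phases = integer(0),
                                intron_length = 200, chromosome = "chr1",
                                strand = c("+", "-"), offset = 500,
                                gene_id = "gene1", seed = 1) {
  strand <- match.arg(strand)
  stopifnot(intron_length >= 4, offset >= 0)
  if (length(intron_phases) > 0 && any(!intron_phases %in% 0:2)) {
    abort("intron_phases must be drawn from {0, 1, 2}")
  }
  cds <- toupper(as.character(cds))
  len <- nchar(cds)
  if (len %% 3 != 0) abort("CDS length must be divisible by 3")
  k <- length(intron_phases)

  cuts <- integer(0)
  if (k > 0) {
    cuts <- with_local_seed(seed, {
      ok <- FALSE
      for (try in 1:2000) {
        cand <- integer(k); prev <- 0; feasible <- TRUE
        for (i in seq_len(k)) {
          p <- intron_phases[i]
          # cut after CDS position c with c %% 3 == p, 0 < c < len
          pool <- seq_len(len - 1)
          pool <- pool[pool %% 3 == p & pool > prev]
          # leave room: at least one valid position per remaining intron
          if (length(pool) == 0) { feasible <- FALSE; break }
          cand[i] <- if (length(pool) == 1) pool else sample(pool, 1)
          prev <- cand[i]
        }
        if (feasible) { ok <- TRUE; break }
      }
      if (!ok) abort("generate_gene_model: requested phases not implementable for this CDS length")
      cand
    })
  }

  exon_seqs <- if (k == 0) list(cds) else {
    bounds <- c(0, cuts, len)
    map(seq_len(k + 1), function(i) substr(cds, bounds[i] + 1, bounds[i + 1]))
  }
  rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
  pieces <- with_local_seed(seed + 1L, {
    introns <- map_chr(seq_len(max(k, 0)), function(i) {
      paste0("GT", rand_dna(intron_length - 4), "AG")
    })
    left <- rand_dna(offset); right <- rand_dna(offset)
    list(left = left, right = right, introns = introns)
  })

  # assemble in plus orientation first
  frag <- pieces$left
  starts <- integer(k + 1); ends <- integer(k + 1)
  pos <- nchar(pieces$left)
  for (i in seq_len(k + 1)) {
    starts[i] <- pos + 1
    frag <- paste0(frag, exon_seqs[[i]])
    pos <- pos + nchar(exon_seqs[[i]])
    ends[i] <- pos
    if (i <= k) {
      frag <- paste0(frag, pieces$introns[i])
      pos <- pos + nchar(pieces$introns[i])
    }
  }
  frag <- paste0(frag, pieces$right)

  if (strand == "-") {
    L <- nchar(frag)
    frag <- revcomp(frag)
    new_starts <- L - ends + 1
    new_ends <- L - starts + 1
    starts <- new_starts; ends <- new_ends
    # transcript order keeps exon 1 first; its genomic coordinates now descend
  }
  model <- tibble(
    gene_id = gene_id, chromosome = chromosome, strand = strand,
    n_exons = k + 1L, cds_length = len, valid = TRUE,
    exons = list(tibble(start = starts, end = ends))
  )
  fragment <- setNames(frag, chromosome)
  list(model = model, fragment = fragment, phases = as.integer(intron_phases))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), filepath = path)
  invisible(path)
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA and CDS features (1-based inclusive coordinates) in a
#' deterministic order so identical models produce byte-identical files.
#'
#' @param models Gene-model tibble (as from [generate_gene_model()] or
#'   [parse_gene_models()]).
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_gff3 <- function(models, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(models))) {
    g <- models$gene_id[i]
    ex <- models$exons[[i]]
    lo <- min(ex$start); hi <- max(ex$end)
    chr <- models$chromosome[i]; strand <- models$strand[i]
    lines <- c(lines,
      sprintf("%s\tgenefam\tgene\t%d\t%d\t.\t%s\t.\tID=%s", chr, lo, hi, strand, g),
      sprintf("%s\tgenefam\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              chr, lo, hi, strand, g, g))
    gex <- ex[order(ex$start), , drop = FALSE]
    # CDS phase column: fraction of a codon carried over from upstream exons
    tx <- ex  # transcript order
    carried <- c(0, cumsum(tx$end - tx$start + 1))[seq_len(nrow(tx))] %% 3
    frame <- (3 - carried) %% 3
    frame_by_start <- frame[match(gex$start, tx$start)]
    for (j in seq_len(nrow(gex))) {
      lines <- c(lines,
        sprintf("%s\tgenefam\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.t1.cds;Parent=%s.t1",
                chr, gex$start[j], gex$end[j], strand, frame_by_start[j], g, g))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
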