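# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately use different mechanisms from the
# package code (positional walks, recursive enumeration, regex).

GENCODE <- setNames(as.character(Biostrings::GENETIC_CODE),
                    names(Biostrings::GENETIC_CODE))
SENSE <- names(GENCODE)[GENCODE != "*"]
FAMS <- split(SENSE, GENCODE[SENSE])

# position-walk codon counter
oracle_codon_counts <- function(cds) {
  out <- setNames(integer(64), names(GENCODE))
  for (i in seq(1, nchar(cds) - 2, by = 3)) {
    cod <- substr(cds, i, i + 2)
    if (cod %in% names(out)) out[cod] <- out[cod] + 1L
  }
  out
}

# position-indexed GC3s tally
oracle_gc3s <- function(cds) {
  num <- 0; den <- 0
  for (i in seq(1, nchar(cds) - 2, by = 3)) {
    cod <- substr(cds, i, i + 2)
    aa <- GENCODE[cod]
    if (is.na(aa) || aa == "*") next
    if (length(FAMS[[aa]]) < 2) next
    den <- den + 1
    if (substr(cod, 3, 3) %in% c("G", "C")) num <- num + 1
  }
  if (den == 0) NA_real_ else num / den
}

oracle_rscu <- function(cds) {
  cnt <- oracle_codon_counts(cds)
  out <- setNames(rep(NA_real_, length(SENSE)), SENSE)
  for (aa in names(FAMS)) {
    cods <- FAMS[[aa]]
    tot <- sum(cnt[cods])
    if (tot > 0) out[cods] <- length(cods) * cnt[cods] / tot
  }
  out
}

# exhaustive recursive global-alignment scorer (affine gaps, BLOSUM62),
# for toy proteins; enumerates all monotone alignment paths
oracle_nw_score <- function(a, b, gap_open = 10, gap_ext = 0.5) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  sub <- get("BLOSUM62", envir = environment())
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  rec <- function(i, j, state) {
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      best <- max(best, sub[ca[i], cb[j]] + rec(i + 1, j + 1, "m"))
    }
    if (i <= length(ca)) {
      pen <- if (state == "ga") gap_ext else gap_open + gap_ext
      best <- max(best, -pen + rec(i + 1, j, "ga"))
    }
    if (j <= length(cb)) {
      pen <- if (state == "gb") gap_ext else gap_open + gap_ext
      best <- max(best, -pen + rec(i, j + 1, "gb"))
    }
    best
  }
  rec(1, 1, "m")
}

# exhaustive pathway enumeration across a whole toy codon alignment
oracle_ng_diffs <- function(codons_a, codons_b) {
  flat_a <- strsplit(paste(codons_a, collapse = ""), "")[[1]]
  flat_b <- strsplit(paste(codons_b, collapse = ""), "")[[1]]
  pos <- which(flat_a != flat_b)
  if (length(pos) == 0) return(c(sd = 0, nd = 0))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    }
    out
  }
  translate_at <- function(flat, k) {
    ci <- (k - 1) %/% 3
    GENCODE[paste(flat[ci * 3 + 1:3], collapse = "")]
  }
  tallies <- list()
  for (ord in perms(pos)) {
    cur <- flat_a; sd <- 0; nd <- 0; ok <- TRUE
    for (k in ord) {
      aa_before <- translate_at(cur, k)
      cur[k] <- flat_b[k]
      aa_after <- translate_at(cur, k)
      if (aa_after == "*") { ok <- FALSE; break }
      if (aa_before == aa_after) sd <- sd + 1 else nd <- nd + 1
    }
    if (ok) tallies[[length(tallies) + 1]] <- c(sd, nd)
  }
  m <- do.call(rbind, tallies)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

# regex-based IUPAC consensus scan, overlapping, both strands
oracle_motif_scan <- function(sequence, consensus) {
  sets <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT", S = "CG",
            W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT", H = "ACT",
            V = "ACG", N = "ACGT")
  to_re <- function(cons) {
    paste(vapply(strsplit(cons, "")[[1]],
                 function(ch) paste0("[", sets[[ch]], "]"), character(1)),
          collapse = "")
  }
  rc <- function(x) {
    chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  }
  find <- function(re) {
    m <- gregexpr(paste0("(?=", re, ")"), sequence, perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m)
  }
  fwd <- find(to_re(consensus))
  rev_ <- find(to_re(rc(consensus)))
  list(fwd = fwd, rev = rev_)
}

# helper: CDS table -> protein table
as_protein_tbl <- function(cds_tbl) {
  dplyr::mutate(cds_tbl, protein = vapply(cds, function(s) {
    p <- paste(GENCODE[substring(s, seq(1, nchar(s) - 2, 3),
                                 seq(3, nchar(s), 3))], collapse = "")
    sub("\\*$", "", p)
  }, character(1)))
}

# random sense-codon CDS for oracle tests
random_cds <- function(n_codons, seed) {
  withr::with_seed(seed, {
    paste(c("ATG", sample(SENSE, n_codons - 1, replace = TRUE)), collapse = "")
  })
}
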