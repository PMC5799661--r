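# Duplicate-pair and triplicate-group detection from pairwise global protein
# alignments, with the two stringency standards (low: >=30% identity over
# >=70% of the longer protein; high: >=50% over >=90%) and duplication
# mechanism classification.

#' Global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment (via `Biostrings::pairwiseAlignment`)
#' with BLOSUM62 and affine gaps (open 10, extend 0.5) by default. Identity
#' is the fraction of identical residue pairs over all alignment columns
#' (needle-style; the gap-excluded BLAST-style denominator is available via
#' `identity_denominator`); coverage is the number of residues of the
#' longer protein inside the non-terminal-gap span of the alignment,
#' divided by the length of the longer protein (the conservative reading of
#' "covering X% of the protein length").
#'
#' @param a,b Protein sequences (character or `AAString`).
#' @param gene_a,gene_b Identifiers carried into the result.
#' @param substitution_matrix Name of the scoring matrix (default
#'   `"BLOSUM62"`).
#' @param gap_opening,gap_extension Affine gap penalties (default 10, 0.5).
#' @param identity_denominator `"alignment_length"` (default) or
#'   `"gap_excluded"`.
#' @return A tibble with one row: `gene_a`, `gene_b`, `aligned_a`,
#'   `aligned_b`, `score`, `identity`, `coverage`.
#' @export
global_align <- function(a, b, gene_a = "a", gene_b = "b",
                         substitution_matrix = "BLOSUM62",
                         gap_opening = 10, gap_extension = 0.5,
                         identity_denominator = c("alignment_length", "gap_excluded")) {
  identity_denominator <- match.arg(identity_denominator)
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (nchar(a) == 0 || nchar(b) == 0) abort("global_align: empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  ra <- as.character(Biostrings::alignedPattern(aln))
  rb <- as.character(Biostrings::alignedSubject(aln))
  stats <- alignment_stats(ra, rb, identity_denominator = identity_denominator,
                           longer = max(nchar(a), nchar(b)))
  tibble(gene_a = gene_a, gene_b = gene_b,
         aligned_a = ra, aligned_b = rb,
         score = Biostrings::score(aln),
         identity = stats$identity, coverage = stats$coverage)
}

# identity and coverage from two gapped rows of equal length
alignment_stats <- function(ra, rb, identity_denominator = "alignment_length",
                            longer = NULL) {
  ca <- strsplit(ra, "")[[1]]
  cb <- strsplit(rb, "")[[1]]
  stopifnot(length(ca) == length(cb))
  both <- ca != "-" & cb != "-"
  ident <- sum(ca[both] == cb[both])
  denom <- if (identity_denominator == "gap_excluded") sum(both) else length(ca)
  # aligned span: residues of the longer protein falling between the first
  # and last column where both rows carry a residue (terminal gaps excluded)
  longer_row <- if (sum(ca != "-") >= sum(cb != "-")) ca else cb
  longer <- longer %||% sum(longer_row != "-")
  span <- if (any(both)) {
    core <- seq(min(which(both)), max(which(both)))
    sum(longer_row[core] != "-")
  } else 0L
  list(identity = if (denom > 0) ident / denom else NA_real_,
       coverage = span / longer)
}

#' Classify a pair under the duplication stringency standards
#'
#' High stringency: identity >= 0.50 and coverage >= 0.90; low stringency:
#' identity >= 0.30 and coverage >= 0.70; otherwise `"none"`. All thresholds
#' inclusive; every high-stringency pair also satisfies the low thresholds.
#'
#' @param identity,coverage Fractions in `[0, 1]` (vectorized).
#' @return Character vector: `"high"`, `"low"` or `"none"`.
#' @export
classify_pair <- function(identity, coverage) {
  dplyr::case_when(
    identity >= 0.50 & coverage >= 0.90 ~ "high",
    identity >= 0.30 & coverage >= 0.70 ~ "low",
    TRUE ~ "none"
  )
}

#' Find duplicate gene pairs in a protein family
#'
#' Aligns every unordered pair of proteins globally and keeps pairs meeting
#' at least the low-stringency standard. The family-sized all-vs-all
#' dynamic programming is affordable for families of ~100 members.
#'
#' @param proteins Tibble with columns `gene_id` and `protein`.
#' @param ... Passed to [global_align()] (scoring scheme, thresholds are
#'   fixed by [classify_pair()]).
#' @return Tibble `gene_a`, `gene_b` (with `gene_a < gene_b`), `identity`,
#'   `coverage`, `stringency` for every pair with stringency != "none".
#' @export
find_duplicates <- function(proteins, ...) {
  stopifnot(is.data.frame(proteins), all(c("gene_id", "protein") %in% names(proteins)))
  if (nrow(proteins) < 2) abort("find_duplicates needs at least 2 proteins")
  ids <- proteins$gene_id
  idx <- combn(seq_along(ids), 2)
  rows <- map(seq_len(ncol(idx)), function(k) {
    i <- idx[1, k]; j <- idx[2, k]
    ga <- ids[i]; gb <- ids[j]
    if (ga > gb) { tmp <- i; i <- j; j <- tmp; ga <- ids[i]; gb <- ids[j] }
    aln <- global_align(proteins$protein[i], proteins$protein[j],
                        gene_a = ga, gene_b = gb, ...)
    tibble(gene_a = ga, gene_b = gb,
           identity = aln$identity, coverage = aln$coverage,
           stringency = classify_pair(aln$identity, aln$coverage))
  })
  bind_rows(rows) |>
    filter(.data$stringency != "none") |>
    arrange(.data$gene_a, .data$gene_b)
}

#' Find triplicate gene groups
#'
#' A triplicate group is a 3-clique in the duplicate-pair graph: three genes
#' whose three pairwise links each meet at least the low-stringency
#' standard. Cliques larger than 3 are reported as all their 3-subsets with
#' a notice.
#'
#' @param pairs Tibble from [find_duplicates()] (columns `gene_a`,
#'   `gene_b`).
#' @return Tibble `gene_1`, `gene_2`, `gene_3` in canonical (sorted) order,
#'   one row per group.
#' @export
find_triplicates <- function(pairs) {
  if (nrow(pairs) == 0) {
    return(tibble(gene_1 = character(0), gene_2 = character(0), gene_3 = character(0)))
  }
  edge <- paste(pmin(pairs$gene_a, pairs$gene_b), pmax(pairs$gene_a, pairs$gene_b),
                sep = "\r")
  genes <- sort(unique(c(pairs$gene_a, pairs$gene_b)))
  has_edge <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "\r") %in% edge
  if (length(genes) < 3) {
    return(tibble(gene_1 = character(0), gene_2 = character(0), gene_3 = character(0)))
  }
  trip <- combn(genes, 3)
  keep <- map_lgl(seq_len(ncol(trip)), function(k) {
    g <- trip[, k]
    has_edge(g[1], g[2]) && has_edge(g[1], g[3]) && has_edge(g[2], g[3])
  })
  out <- tibble(gene_1 = trip[1, keep], gene_2 = trip[2, keep], gene_3 = trip[3, keep])
  # flag larger cliques: a gene appearing in >= 3 groups with shared partners
  if (nrow(out) > 1) {
    member_count <- table(c(out$gene_1, out$gene_2, out$gene_3))
    if (any(member_count >= 3)) {
      inform("find_triplicates: some genes participate in >= 3 groups; a larger clique is reported as all its 3-subsets")
    }
  }
  out
}

#' Classify duplication mechanism for a pair
#'
#' Tandem duplication: both genes on the same chromosome, separated by at
#' most `max_span` bases and at most `max_intervening` other family genes.
#' Segmental / large-scale duplication requires external collinearity
#' evidence (a user-supplied collinear-block table); otherwise the pair is
#' `"unclassified"`.
#'
#' @param pairs Tibble with `gene_a`, `gene_b`.
#' @param positions Tibble with `gene_id`, `chromosome`, `start`.
#' @param collinear Optional tibble of collinear pairs (`gene_a`, `gene_b`,
#'   order-insensitive).
#' @param max_span Maximum genomic distance for a tandem call (default
#'   2e5 nt).
#' @param max_intervening Maximum number of other family genes between the
#'   two (default 5).
#' @return `pairs` with a `mechanism` column: `"tandem"`,
#'   `"segmental_or_large_scale"` or `"unclassified"`.
#' @export
classify_mechanism <- function(pairs, positions, collinear = NULL,
                               max_span = 2e5, max_intervening = 5) {
  stopifnot(all(c("gene_id", "chromosome", "start") %in% names(positions)))
  coll_key <- if (!is.null(collinear) && nrow(collinear) > 0) {
    paste(pmin(collinear$gene_a, collinear$gene_b),
          pmax(collinear$gene_a, collinear$gene_b), sep = "\r")
  } else character(0)
  mech <- map_chr(seq_len(nrow(pairs)), function(k) {
    ga <- pairs$gene_a[k]; gb <- pairs$gene_b[k]
    pa <- positions[positions$gene_id == ga, ]
    pb <- positions[positions$gene_id == gb, ]
    if (nrow(pa) == 0 || nrow(pb) == 0) {
      inform(sprintf("classify_mechanism: missing position for %s-%s; unclassified",
                     ga, gb))
      return("unclassified")
    }
    if (pa$chromosome[1] == pb$chromosome[1]) {
      lo <- min(pa$start[1], pb$start[1]); hi <- max(pa$start[1], pb$start[1])
      between <- positions$chromosome == pa$chromosome[1] &
        positions$start > lo & positions$start < hi &
        !(positions$gene_id %in% c(ga, gb))
      if ((hi - lo) <= max_span && sum(between) <= max_intervening) {
        return("tandem")
      }
    }
    if (paste(min(ga, gb), max(ga, gb), sep = "\r") %in% coll_key) {
      return("segmental_or_large_scale")
    }
    "unclassified"
  })
  mutate(pairs, mechanism = mech)
}
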