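# Gene-structure analysis: GFF3 gene models, intron phases, symmetric /
# asymmetric exon classification, and family-level summaries.

#' Parse gene models from a GFF3 file
#'
#' Reads gene/mRNA/CDS features (via `rtracklayer`) and builds one model per
#' gene: the transcript with the longest total CDS is selected, its CDS
#' exons are ordered in transcript order (descending genomic coordinates on
#' the minus strand), and the model is validated. Models whose CDS length is
#' not divisible by 3 are flagged (`valid = FALSE`) and excluded from phase
#' analysis downstream; overlapping CDS exons within a transcript are an
#' error.
#'
#' @param gff3 Path to a GFF3 file.
#' @return A tibble with columns `gene_id`, `chromosome`, `strand`,
#'   `n_exons`, `cds_length`, `valid` and a list-column `exons` of tibbles
#'   (`start`, `end`, 1-based inclusive, transcript order).
#' @export
parse_gene_models <- function(gff3) {
  gr <- rtracklayer::import(gff3, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  ids <- as.character(meta$ID %||% rep(NA_character_, length(gr)))
  parents <- meta$Parent
  parent1 <- vapply(seq_along(gr), function(i) {
    p <- parents[[i]]
    if (length(p) == 0) NA_character_ else as.character(p[1])
  }, character(1))

  mrna_gene <- setNames(parent1[type == "mRNA"], ids[type == "mRNA"])
  cds_idx <- which(type == "CDS")
  if (length(cds_idx) == 0) abort("parse_gene_models: no CDS features found")

  cds_tbl <- tibble(
    tx = parent1[cds_idx],
    chromosome = as.character(GenomicRanges::seqnames(gr)[cds_idx]),
    strand = as.character(GenomicRanges::strand(gr)[cds_idx]),
    start = GenomicRanges::start(gr)[cds_idx],
    end = GenomicRanges::end(gr)[cds_idx]
  )
  models <- cds_tbl |>
    group_by(.data$tx) |>
    dplyr::group_map(function(df, key) {
      tx <- key$tx[[1]]
      gene <- unname(mrna_gene[tx] %||% NA_character_)
      if (is.na(gene)) gene <- tx  # CDS attached directly to a gene feature
      strand <- df$strand[1]
      df <- if (strand == "-") arrange(df, dplyr::desc(.data$start)) else arrange(df, .data$start)
      # overlap check in genomic order
      g <- arrange(df, .data$start)
      if (nrow(g) > 1 && any(g$start[-1] <= g$end[-nrow(g)])) {
        abort(sprintf("parse_gene_models: overlapping CDS exons in transcript %s", tx))
      }
      len <- sum(df$end - df$start + 1)
      tibble(gene_id = gene, transcript_id = tx,
             chromosome = df$chromosome[1], strand = strand,
             n_exons = nrow(df), cds_length = len,
             valid = len %% 3 == 0,
             exons = list(tibble(start = df$start, end = df$end)))
    }) |>
    bind_rows()

  # longest CDS per gene
  out <- models |>
    group_by(.data$gene_id) |>
    arrange(dplyr::desc(.data$cds_length), .data$transcript_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    arrange(.data$gene_id)
  bad <- !out$valid
  if (any(bad)) {
    warn(sprintf("parse_gene_models: CDS length not divisible by 3 for %s; excluded from phase analysis",
                 paste(out$gene_id[bad], collapse = ", ")))
  }
  out
}

#' Intron phases of a gene model
#'
#' Phase of intron *i* is the cumulative CDS length of exons 1..i modulo 3:
#' 0 = the intron falls between codons, 1 = after the first base of a codon,
#' 2 = after the second. An intron-less gene returns an empty vector.
#'
#' @param exons Tibble of CDS exons (`start`, `end`) in transcript order, or
#'   a one-row model from [parse_gene_models()].
#' @return Integer vector of phases, length `n_exons - 1`.
#' @export
intron_phases <- function(exons) {
  if (is.data.frame(exons) && "exons" %in% names(exons)) {
    exons <- exons$exons[[1]]
  }
  lens <- abs(exons$end - exons$start) + 1
  if (length(lens) <= 1) return(integer(0))
  as.integer(cumsum(lens)[-length(lens)] %% 3)
}

#' Classify exons as symmetric, asymmetric or terminal
#'
#' An internal exon is symmetric when its two flanking introns share the
#' same phase (`symmetric_phase0/1/2`), asymmetric otherwise. Terminal exons
#' (first and last, including the single exon of an intron-less gene) have
#' only one flank and are labelled `terminal` by default; with
#' `count_terminal = TRUE` they are classified against a virtual phase-0
#' boundary at the CDS ends.
#'
#' @param exons As in [intron_phases()].
#' @param count_terminal Treat the CDS start/end as a phase-0 boundary so
#'   terminal exons can be classified too (default `FALSE`).
#' @return Character vector, one label per exon.
#' @export
classify_exons <- function(exons, count_terminal = FALSE) {
  if (is.data.frame(exons) && "exons" %in% names(exons)) {
    exons <- exons$exons[[1]]
  }
  n <- nrow(exons)
  phases <- intron_phases(exons)
  if (n == 1) {
    return(if (count_terminal) "symmetric_phase0" else "terminal")
  }
  left <- c(if (count_terminal) 0L else NA_integer_, phases)
  right <- c(phases, if (count_terminal) 0L else NA_integer_)
  vapply(seq_len(n), function(i) {
    if (is.na(left[i]) || is.na(right[i])) return("terminal")
    if (left[i] == right[i]) paste0("symmetric_phase", left[i]) else "asymmetric"
  }, character(1))
}

#' Family-level gene-structure summary
#'
#' Aggregates exon/intron counts, intron phases, symmetric-exon classes and
#' intron-less genes over a set of gene models. Models flagged invalid
#' (CDS length not divisible by 3) are excluded.
#'
#' @param models Tibble from [parse_gene_models()] (or the synthetic
#'   generator).
#' @param count_terminal Passed to [classify_exons()].
#' @return A list of class `structure_summary`: `n_genes`, `n_exons`,
#'   `n_introns`, `introns_by_phase` (named 0/1/2), `symmetric_exons_by_phase`,
#'   `n_asymmetric_exons`, `n_terminal_exons`, `intronless_genes`, and a
#'   `per_gene` tibble (`gene_id`, `n_exons`, `phases` list-column,
#'   `intronless`).
#' @export
summarize_structures <- function(models, count_terminal = FALSE) {
  stopifnot(nrow(models) >= 1)
  models <- models[models$valid %||% rep(TRUE, nrow(models)), ]
  per_gene <- map(seq_len(nrow(models)), function(i) {
    ex <- models$exons[[i]]
    ph <- intron_phases(ex)
    cls <- classify_exons(ex, count_terminal = count_terminal)
    tibble(gene_id = models$gene_id[i], n_exons = nrow(ex),
           phases = list(ph), classes = list(cls),
           intronless = nrow(ex) == 1)
  }) |> bind_rows()

  all_phases <- unlist(per_gene$phases)
  all_classes <- unlist(per_gene$classes)
  phase_count <- function(x) {
    setNames(vapply(0:2, function(p) sum(x == p), integer(1)), as.character(0:2))
  }
  sym <- setNames(vapply(0:2, function(p) {
    sum(all_classes == paste0("symmetric_phase", p))
  }, integer(1)), as.character(0:2))

  structure(list(
    n_genes = nrow(per_gene),
    n_exons = sum(per_gene$n_exons),
    n_introns = sum(per_gene$n_exons) - nrow(per_gene),
    introns_by_phase = phase_count(all_phases),
    symmetric_exons_by_phase = sym,
    n_asymmetric_exons = sum(all_classes == "asymmetric"),
    n_terminal_exons = sum(all_classes == "terminal"),
    intronless_genes = per_gene$gene_id[per_gene$intronless],
    per_gene = select(per_gene, -"classes")
  ), class = "structure_summary")
}

#' @export
print.structure_summary <- function(x, ...) {
  cat(sprintf("<structure_summary> %d genes, %d exons, %d introns\n",
              x$n_genes, x$n_exons, x$n_introns))
  cat("  introns by phase: ", paste(sprintf("%s:%d", names(x$introns_by_phase),
                                            x$introns_by_phase), collapse = " "), "\n")
  cat("  symmetric exons:  ", paste(sprintf("%s:%d", names(x$symmetric_exons_by_phase),
                                            x$symmetric_exons_by_phase), collapse = " "), "\n")
  cat(sprintf("  intron-less genes: %s\n",
              if (length(x$intronless_genes)) paste(x$intronless_genes, collapse = ", ") else "none"))
  invisible(x)
}

#' @export
tidy.structure_summary <- function(x, ...) {
  x$per_gene |>
    mutate(phases = map_chr(.data$phases, function(p) paste(p, collapse = ",")))
}

#' @export
glance.structure_summary <- function(x, ...) {
  tibble(n_genes = x$n_genes, n_exons = x$n_exons, n_introns = x$n_introns,
         introns_phase0 = x$introns_by_phase[["0"]],
         introns_phase1 = x$introns_by_phase[["1"]],
         introns_phase2 = x$introns_by_phase[["2"]],
         symmetric_phase0 = x$symmetric_exons_by_phase[["0"]],
         symmetric_phase1 = x$symmetric_exons_by_phase[["1"]],
         symmetric_phase2 = x$symmetric_exons_by_phase[["2"]],
         n_intronless = length(x$intronless_genes))
}
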