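# Replicate-aware differential expression on RMA-normalized microarray
# intensities: log2 high-expression calls, fold change on raw means, and a
# one-tailed paired t-test per gene.

#' Log2-transform an expression matrix
#'
#' @param matrix Numeric matrix (genes x samples) or a tibble whose first
#'   column is `gene_id` and remaining columns are intensities. All values
#'   must be positive.
#' @return Same shape, log2 scale.
#' @export
log2_matrix <- function(matrix) {
  if (is.data.frame(matrix)) {
    vals <- as.matrix(matrix[, -1, drop = FALSE])
    if (any(vals <= 0)) abort("log2_matrix: intensities must be positive")
    out <- matrix
    out[, -1] <- log2(vals)
    return(out)
  }
  if (any(matrix <= 0)) abort("log2_matrix: intensities must be positive")
  log2(matrix)
}

#' Flag highly expressed gene/sample cells
#'
#' A cell is called highly expressed when its log2 intensity is strictly
#' greater than `threshold` (default 14, the conventional cut on
#' RMA-normalized Affymetrix intensities for "highly expressed").
#'
#' @param log2_mat A log2-scale matrix or tibble from [log2_matrix()].
#' @param threshold Strict lower bound on the log2 value (default 14).
#' @return Logical matrix / tibble of flags.
#' @export
call_high_expression <- function(log2_mat, threshold = 14) {
  if (is.data.frame(log2_mat)) {
    out <- log2_mat
    out[, -1] <- as.data.frame(as.matrix(log2_mat[, -1, drop = FALSE]) > threshold)
    return(out)
  }
  log2_mat > threshold
}

#' Paired differential expression for one gene
#'
#' Means over replicates, fold change as the ratio of raw means
#' (`mean(treatment) / mean(control)`), and a one-tailed paired t-test on
#' the raw intensities (alternative: treatment > control, df = n - 1).
#' Replicates are paired by index: treatment replicate i is compared with
#' control replicate i. When the paired differences have zero variance the
#' t statistic is undefined; p is reported as 0 if the mean difference is
#' positive and 1 otherwise, with `flat_variance = TRUE`.
#'
#' @param control,treatment Numeric vectors of equal length (>= 2),
#'   replicate intensities.
#' @return One-row tibble: `mean_control`, `mean_treatment`, `fold`,
#'   `p_value`, `flat_variance`.
#' @export
de_test <- function(control, treatment) {
  n <- length(control)
  if (n < 2 || length(treatment) != n) {
    abort("de_test: needs equal replicate counts with n >= 2")
  }
  mc <- mean(control); mt <- mean(treatment)
  d <- treatment - control
  flat <- stats::sd(d) == 0
  p <- if (flat) {
    if (mean(d) > 0) 0 else 1
  } else {
    t.test(treatment, control, paired = TRUE, alternative = "greater")$p.value
  }
  tibble(mean_control = mc, mean_treatment = mt, fold = mt / mc,
         p_value = p, flat_variance = flat)
}

#' Differential expression over an expression table
#'
#' Runs [de_test()] for every gene of a replicate table.
#'
#' @param expr Tibble with one row per gene: `gene_id`, control replicate
#'   columns and treatment replicate columns.
#' @param control_cols,treatment_cols Column names of the replicates, paired
#'   by position.
#' @param fold_threshold Induction threshold on the fold change (inclusive,
#'   default 1.5).
#' @return Tibble of class `de_result`: `gene_id`, `mean_control`,
#'   `mean_treatment`, `fold`, `p_value`, `flat_variance`, `induced`.
#' @export
differential_expression <- function(expr, control_cols, treatment_cols,
                                    fold_threshold = 1.5) {
  stopifnot(all(control_cols %in% names(expr)), all(treatment_cols %in% names(expr)))
  rows <- map(seq_len(nrow(expr)), function(i) {
    res <- de_test(as.numeric(expr[i, control_cols]),
                   as.numeric(expr[i, treatment_cols]))
    mutate(res, gene_id = expr$gene_id[i], .before = 1)
  })
  out <- bind_rows(rows)
  out$induced <- out$fold >= fold_threshold & out$mean_treatment > out$mean_control
  class(out) <- c("de_result", class(out))
  out
}

#' Select induced genes
#'
#' Induction requires fold >= `fold_threshold` (inclusive) and a treatment
#' mean above the control mean. The p-value is reported but not filtered on,
#' matching the fold-change-based convention of microarray family surveys.
#'
#' @param results A [differential_expression()] table.
#' @param fold_threshold Inclusive threshold (default 1.5).
#' @return Character vector of induced gene ids.
#' @export
select_induced <- function(results, fold_threshold = 1.5) {
  sort(unique(results$gene_id[
    results$fold >= fold_threshold & results$mean_treatment > results$mean_control
  ]))
}

#' Union of induced genes over timepoints
#'
#' @param per_timepoint A list of character vectors (induced genes per
#'   contrast/timepoint).
#' @return Sorted distinct union.
#' @export
union_induced <- function(per_timepoint) {
  if (length(per_timepoint) == 0) abort("union_induced: needs at least one list")
  sort(unique(unlist(per_timepoint, use.names = FALSE)))
}

#' Format a differential-expression table for publication
#'
#' Rounds means, fold and p half-up to 2 decimals (the usual table
#' precision); full precision is retained in the input object.
#'
#' @param results A [differential_expression()] table.
#' @return Tibble with rounded columns.
#' @export
format_de_table <- function(results) {
  mutate(results,
         mean_control = round_half_up(.data$mean_control, 2),
         mean_treatment = round_half_up(.data$mean_treatment, 2),
         fold = round_half_up(.data$fold, 2),
         p_value = round_half_up(.data$p_value, 2))
}

#' Export a heatmap-ready matrix
#'
#' Genes-by-samples table in raw or log2 scale with the requested row
#' order, for external heatmap tools.
#'
#' @param expr Tibble `gene_id` + intensity columns.
#' @param gene_order Character vector of genes (must all be present).
#' @param scale `"raw"` or `"log2"`.
#' @return Tibble in the requested order/scale.
#' @export
export_heatmap_matrix <- function(expr, gene_order = expr$gene_id,
                                  scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  missing <- setdiff(gene_order, expr$gene_id)
  if (length(missing)) {
    abort(sprintf("export_heatmap_matrix: unknown gene(s): %s",
                  paste(missing, collapse = ", ")))
  }
  out <- expr[match(gene_order, expr$gene_id), ]
  if (scale == "log2") out <- log2_matrix(out)
  out
}

#' Published cold-stress replicate intensities for the grape bHLH family
#'
#' The RMA-normalized control/cold replicate intensities (accession
#' GSE31594) for the differentially expressed grape bHLH genes at 1 h, 4 h
#' and 8 h of cold treatment, as published, together with the published
#' means, fold changes and p-values for comparison.
#'
#' @return Tibble with `timepoint`, `gene_id`, `ck1..ck3`, `cold1..cold3`
#'   and the `_published` reference columns.
#' @export
grape_cold_bhlh <- function() {
  path <- system.file("extdata", "gse31594_cold_bhlh.tsv", package = "genefam")
  as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' @export
tidy.de_result <- function(x, ...) {
  as_tibble(x)[, c("gene_id", "fold", "p_value", "induced")]
}

#' @export
glance.de_result <- function(x, ...) {
  tibble(n_genes = nrow(x), n_induced = sum(x$induced),
         median_fold = stats::median(x$fold))
}

#' Fold-change plot for a differential-expression result
#'
#' Fold change per gene with the induction threshold marked.
#'
#' @param object A [differential_expression()] result.
#' @param fold_threshold Threshold line (default 1.5).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.de_result <- function(object, fold_threshold = 1.5, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$gene_id, .data$fold),
                                   y = .data$fold, fill = .data$induced)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = fold_threshold, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Fold change (treatment / control)") +
    ggplot2::theme_minimal()
}
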