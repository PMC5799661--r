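# Synthetic replicate expression matrices with planted fold changes and
# paired multiplicative noise, emulating RMA-normalized microarray
# intensities with a control condition and one or more treatments.

#' Generate a replicate expression matrix with planted folds
#'
#' Each gene draws a base intensity uniformly from `base_range`; control
#' replicate i is `base * noise`, and treatment replicate i derives from
#' control replicate i times the planted fold times fresh noise — the
#' paired structure the paired differential-expression test assumes. Noise
#' is multiplicative mean-1 log-normal with coefficient of variation
#' `noise_cv` (intensities are positive and fold statistics are
#' ratio-based); `noise_cv = 0` makes replicates exact, so a planted fold
#' of 1.5 sits exactly on the inclusive induction threshold.
#'
#' @param genes Character vector of gene ids.
#' @param conditions Character vector of treatment condition names; the
#'   control is always generated and named `"ck"`.
#' @param fold_map Tibble `gene_id`, `condition`, `fold` (genes/conditions
#'   absent from the map default to fold 1).
#' @param n_reps Replicates per condition (>= 2, default 3).
#' @param base_range Positive intensity range for the per-gene base
#'   (default `c(50, 500)`).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (>= 0, default 0.2).
#' @param seed Integer seed.
#' @return List: `expr` (tibble `gene_id` + columns `ck_r1..`, then
#'   `<condition>_r1..` per treatment), `truth` (the full fold map), and
#'   `samples` (tibble `sample`, `condition`, `replicate`).
#' @export
generate_expression <- function(genes, conditions, fold_map = NULL,
                                n_reps = 3, base_range = c(50, 500),
                                noise_cv = 0.2, seed = 1) {
  if (n_reps < 2) abort("generate_expression: n_reps must be >= 2")
  if (noise_cv < 0) abort("generate_expression: noise_cv must be >= 0")
  if (any(base_range <= 0)) abort("generate_expression: base_range must be positive")
  fold_map <- fold_map %||% tibble(gene_id = character(0), condition = character(0),
                                   fold = numeric(0))
  sigma <- sqrt(log(1 + noise_cv^2))
  noise <- function(n) {
    if (sigma == 0) rep(1, n) else rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)
  }
  fold_of <- function(g, cond) {
    hit <- fold_map$fold[fold_map$gene_id == g & fold_map$condition == cond]
    if (length(hit)) hit[1] else 1
  }
  with_local_seed(seed, {
    expr <- tibble(gene_id = genes)
    ctrl <- matrix(0, length(genes), n_reps)
    for (i in seq_along(genes)) {
      base <- runif(1, base_range[1], base_range[2])
      ctrl[i, ] <- base * noise(n_reps)
    }
    for (r in seq_len(n_reps)) expr[[sprintf("ck_r%d", r)]] <- ctrl[, r]
    for (cond in conditions) {
      trt <- matrix(0, length(genes), n_reps)
      for (i in seq_along(genes)) {
        trt[i, ] <- ctrl[i, ] * fold_of(genes[i], cond) * noise(n_reps)
      }
      for (r in seq_len(n_reps)) expr[[sprintf("%s_r%d", cond, r)]] <- trt[, r]
    }
    truth <- tidyr::expand_grid(gene_id = genes, condition = conditions) |>
      mutate(fold = map2_dbl(.data$gene_id, .data$condition, fold_of))
    samples <- bind_rows(
      tibble(sample = sprintf("ck_r%d", seq_len(n_reps)),
             condition = "ck", replicate = seq_len(n_reps)),
      bind_rows(map(conditions, function(cond) {
        tibble(sample = sprintf("%s_r%d", cond, seq_len(n_reps)),
               condition = cond, replicate = seq_len(n_reps))
      }))
    )
    list(expr = expr, truth = truth, samples = samples)
  })
}
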