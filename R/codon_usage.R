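# Codon-usage-bias statistics: per-gene GC/GC3s, RSCU, Wright's effective
# number of codons (observed and expected from GC3s), and the reference-set
# indices CAI, FOP and CBI.

#' Count codons in a coding sequence
#'
#' Tallies the 61 sense codons of a CDS. A trailing stop codon (and any
#' internal stop, which is also flagged) is tracked separately and never
#' enters the sense-codon total. Codons containing ambiguous bases (anything
#' outside A/C/G/T) are skipped and counted in `n_skipped`.
#'
#' @param cds A single coding sequence (character or `DNAString`), length
#'   divisible by 3.
#' @param gene_id Optional identifier stored with the counts.
#' @return An object of class `codon_counts`: a list with `gene_id`,
#'   `counts` (named integer over the 61 sense codons), `stop_counts`
#'   (named integer over the 3 stop codons), `n_skipped` and
#'   `total_codons` (sum of sense counts).
#' @examples
#' count_codons("ATGTTTTAA")
#' @export
count_codons <- function(cds, gene_id = NULL) {
  tab <- codon_table()
  codons <- split_codons(cds)
  ok <- grepl("^[ACGT]{3}$", codons)
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    inform(sprintf("count_codons: skipped %d codon(s) with ambiguous bases", n_skipped))
  }
  codons <- codons[ok]
  is_stop <- codons %in% tab$stop_codons
  sense <- table(factor(codons[!is_stop], levels = tab$sense_codons))
  stops <- table(factor(codons[is_stop], levels = tab$stop_codons))
  structure(
    list(
      gene_id = gene_id %||% NA_character_,
      counts = setNames(as.integer(sense), tab$sense_codons),
      stop_counts = setNames(as.integer(stops), tab$stop_codons),
      n_skipped = n_skipped,
      total_codons = sum(sense)
    ),
    class = "codon_counts"
  )
}

as_codon_counts <- function(x, gene_id = NULL) {
  if (inherits(x, "codon_counts")) x else count_codons(x, gene_id = gene_id)
}

#' @export
print.codon_counts <- function(x, ...) {
  cat(sprintf("<codon_counts> gene %s: %d sense codons, %d stop(s), %d skipped\n",
              x$gene_id, x$total_codons, sum(x$stop_counts), x$n_skipped))
  invisible(x)
}

#' Relative synonymous codon usage
#'
#' RSCU of codon *j* in a synonymous family of size *k* is `k * x_j / sum(x)`
#' over the family's observed counts. Codons of families never observed in
#' the gene are reported as `NA` (undefined), not 0. Within every observed
#' family the RSCU values average to 1.
#'
#' @param counts A `codon_counts` object or a CDS passed through
#'   [count_codons()].
#' @return A tibble with columns `codon`, `amino_acid`, `count`, `rscu`.
#' @export
rscu <- function(counts) {
  counts <- as_codon_counts(counts)
  tab <- codon_table()
  out <- map(names(tab$families), function(aa) {
    cods <- tab$families[[aa]]
    x <- counts$counts[cods]
    k <- length(cods)
    tot <- sum(x)
    val <- if (tot == 0) rep(NA_real_, k) else k * x / tot
    tibble(codon = cods, amino_acid = aa, count = as.integer(x), rscu = unname(val))
  })
  arrange(bind_rows(out), .data$amino_acid, .data$codon)
}

#' GC content of a coding sequence
#'
#' @param cds Coding sequence (character or `DNAString`).
#' @return Fraction of G+C bases.
#' @export
gc_content <- function(cds) {
  s <- toupper(as.character(cds))
  bases <- strsplit(s, "")[[1]]
  bases <- bases[bases %in% c("A", "C", "G", "T")]
  if (length(bases) == 0) return(NA_real_)
  mean(bases %in% c("G", "C"))
}

#' GC content at synonymous third codon positions (GC3s)
#'
#' Third-position G+C fraction computed over synonymously degenerate codons
#' only: Met (ATG), Trp (TGG) and stop codons carry no synonymous third
#' position and are excluded. Returns `NA` (with a message) when the gene
#' has no eligible codons.
#'
#' @param x A CDS or a `codon_counts` object.
#' @return Fraction in `[0, 1]`, or `NA` if undefined.
#' @export
gc3s <- function(x) {
  counts <- as_codon_counts(x)
  tab <- codon_table()
  eligible <- unlist(tab$degenerate_families, use.names = FALSE)
  n <- counts$counts[eligible]
  tot <- sum(n)
  if (tot == 0) {
    inform("gc3s: no synonymously degenerate codons; GC3s undefined")
    return(NA_real_)
  }
  third <- substr(eligible, 3, 3)
  sum(n[third %in% c("G", "C")]) / tot
}

# Family homozygosity F = (n * sum(p^2) - 1) / (n - 1); NA when n < 2.
.family_homozygosity <- function(x) {
  n <- sum(x)
  if (n < 2) return(NA_real_)
  p <- x / n
  (n * sum(p^2) - 1) / (n - 1)
}

#' Wright's effective number of codons (observed)
#'
#' ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6, where Fk is the mean codon
#' homozygosity of the synonymous families with degeneracy k. Families with
#' fewer than 2 observed codons, and families whose homozygosity estimate is
#' 0, are omitted from their class mean; if a whole degeneracy class is
#' missing its mean is imputed from the neighbouring classes (Wright's
#' recommendation). The result is clamped to `[20, 61]`.
#'
#' @param counts A CDS or `codon_counts` object.
#' @return Effective number of codons in `[20, 61]`; `NA` if no class mean
#'   can be formed. Genes shorter than 30 codons carry a
#'   `low_confidence` attribute.
#' @export
enc_observed <- function(counts) {
  counts <- as_codon_counts(counts)
  tab <- codon_table()
  fams <- tab$degenerate_families
  deg <- lengths(fams)
  fvals <- map_dbl(fams, function(cods) .family_homozygosity(counts$counts[cods]))
  fvals[!is.na(fvals) & fvals == 0] <- NA_real_  # would contribute infinitely

  classes <- c(2L, 3L, 4L, 6L)
  fbar <- map_dbl(classes, function(k) {
    v <- fvals[deg == k]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  names(fbar) <- as.character(classes)

  # impute a missing class mean from its nearest available neighbours
  if (anyNA(fbar) && !all(is.na(fbar))) {
    for (i in seq_along(fbar)) {
      if (is.na(fbar[i])) {
        left <- rev(which(!is.na(fbar[seq_len(i - 1)])))
        right <- which(!is.na(fbar)) ; right <- right[right > i]
        nb <- c(if (length(left)) fbar[left[1]], if (length(right)) fbar[right[1]])
        fbar[i] <- mean(nb)
      }
    }
  }
  if (all(is.na(fbar))) return(NA_real_)

  enc <- 2 + 9 / fbar[["2"]] + 1 / fbar[["3"]] + 5 / fbar[["4"]] + 3 / fbar[["6"]]
  enc <- min(61, max(20, enc))
  if (counts$total_codons < 30) attr(enc, "low_confidence") <- TRUE
  enc
}

#' Expected ENC from GC3s
#'
#' Wright (1990)'s null curve relating the effective number of codons to the
#' synonymous third-position G+C frequency `s`:
#' `ENC_exp = 2 + s + 29 / (s^2 + (1 - s)^2)`.
#' Under no selection a gene falls on this curve; points below it indicate
#' codon-usage bias beyond the GC3s composition effect.
#'
#' @param s GC3s fraction, strictly between 0 and 1 (vectorized).
#' @return Expected effective number of codons.
#' @export
enc_expected <- function(s) {
  if (any(!is.finite(s)) || any(s <= 0) || any(s >= 1)) {
    abort("`s` must lie strictly between 0 and 1")
  }
  2 + s + 29 / (s^2 + (1 - s)^2)
}

#' Reference codon-adaptiveness weights
#'
#' Builds the relative-adaptiveness table used by [cai()], [fop()] and
#' [cbi()] from a reference gene set (ordinarily highly expressed genes).
#' Within each synonymous family, `w = (count + pseudocount) / max(count +
#' pseudocount)`, so the most used codon has weight 1. The optimal set holds
#' the argmax-RSCU codon of each degenerate family; ties are broken
#' lexicographically (and reported).
#'
#' There is deliberately no built-in default reference: weights are
#' organism- and expression-set-specific and must be supplied explicitly.
#'
#' @param reference A tibble with columns `gene_id`, `cds`, a character
#'   vector of CDS, or a single `codon_counts` object.
#' @param pseudocount Added to every sense-codon count before normalization
#'   (default 0.5) so unobserved codons keep a positive weight.
#' @return An object of class `reference_weights` with elements `w` (named
#'   numeric over the 61 sense codons, in (0, 1]) and `optimal_set`
#'   (one codon per degenerate family).
#' @export
reference_weights <- function(reference, pseudocount = 0.5) {
  tab <- codon_table()
  total <- setNames(numeric(length(tab$sense_codons)), tab$sense_codons)
  add_counts <- function(cc) total + cc$counts
  if (inherits(reference, "codon_counts")) {
    total <- add_counts(reference)
  } else if (is.data.frame(reference)) {
    for (s in reference$cds) total <- total + count_codons(s)$counts
  } else {
    for (s in reference) total <- total + count_codons(s)$counts
  }
  total <- total + pseudocount
  w <- total
  optimal <- character(0)
  for (aa in names(tab$families)) {
    cods <- tab$families[[aa]]
    w[cods] <- total[cods] / max(total[cods])
    if (length(cods) >= 2) {
      best <- cods[total[cods] == max(total[cods])]
      if (length(best) > 1) {
        inform(sprintf("reference_weights: RSCU tie in %s family broken lexicographically (%s)",
                       aa, paste(best, collapse = ", ")))
      }
      optimal <- c(optimal, sort(best)[1])
    }
  }
  structure(list(w = w, optimal_set = sort(optimal), pseudocount = pseudocount),
            class = "reference_weights")
}

#' @export
print.reference_weights <- function(x, ...) {
  cat(sprintf("<reference_weights> 61 sense-codon weights, %d optimal codons\n",
              length(x$optimal_set)))
  invisible(x)
}

#' Codon adaptation index
#'
#' Geometric mean of the reference relative-adaptiveness weights over the
#' gene's codons, excluding Met, Trp and stop codons (which admit no
#' synonymous choice).
#'
#' @param counts A CDS or `codon_counts` object.
#' @param ref A [reference_weights()] object.
#' @return CAI in `(0, 1]`; `NA` (with a message) if the gene has no
#'   eligible codons.
#' @export
cai <- function(counts, ref) {
  stopifnot(inherits(ref, "reference_weights"))
  counts <- as_codon_counts(counts)
  tab <- codon_table()
  eligible <- unlist(tab$degenerate_families, use.names = FALSE)
  n <- counts$counts[eligible]
  tot <- sum(n)
  if (tot == 0) {
    inform("cai: no eligible codons; CAI undefined")
    return(NA_real_)
  }
  exp(sum(n * log(ref$w[eligible])) / tot)
}

#' Frequency of optimal codons
#'
#' Fraction of codons (over amino acids with at least two synonymous codons)
#' that are the family's optimal codon in the reference set.
#'
#' @inheritParams cai
#' @return FOP in `[0, 1]`; `NA` if the gene has no eligible codons.
#' @export
fop <- function(counts, ref) {
  stopifnot(inherits(ref, "reference_weights"))
  counts <- as_codon_counts(counts)
  tab <- codon_table()
  eligible <- unlist(tab$degenerate_families, use.names = FALSE)
  n_tot <- sum(counts$counts[eligible])
  if (n_tot == 0) {
    inform("fop: no eligible codons; FOP undefined")
    return(NA_real_)
  }
  sum(counts$counts[ref$optimal_set]) / n_tot
}

#' Codon bias index
#'
#' `CBI = (N_opt - N_ran) / (N_tot - N_ran)`, where `N_opt` is the number of
#' optimal codons used, `N_tot` the number of codons of degenerate amino
#' acids, and `N_ran` the expected optimal count under uniform synonymous
#' usage (one optimal codon per family, so `N_ran = sum(n_family / k_family)`).
#' 1 means exclusively optimal codons, 0 random usage, negative values
#' avoidance of optimal codons.
#'
#' @inheritParams cai
#' @return CBI in `[-1, 1]`; `NA` if undefined.
#' @export
cbi <- function(counts, ref) {
  stopifnot(inherits(ref, "reference_weights"))
  counts <- as_codon_counts(counts)
  tab <- codon_table()
  fams <- tab$degenerate_families
  n_fam <- map_dbl(fams, function(cods) sum(counts$counts[cods]))
  n_tot <- sum(n_fam)
  if (n_tot == 0) {
    inform("cbi: no eligible codons; CBI undefined")
    return(NA_real_)
  }
  n_ran <- sum(n_fam / lengths(fams))
  n_opt <- sum(counts$counts[ref$optimal_set])
  (n_opt - n_ran) / (n_tot - n_ran)
}

#' Per-gene codon-usage statistics table
#'
#' Computes, for every gene in a CDS table, the full set of codon-usage-bias
#' statistics: GC, GC3s, observed and expected ENC, FOP, CBI, CAI and
#' lengths.
#'
#' @param cds_tbl Tibble with columns `gene_id` and `cds`. An optional
#'   `exon_length_mean` column (mean CDS-exon length in nt, from
#'   [summarize_structures()]) is carried through for the correlation
#'   analysis.
#' @param ref A [reference_weights()] object (required; there is no default
#'   reference set).
#' @return A tibble with one row per gene and columns `gene_id`, `gc`,
#'   `gc3s`, `enc_obs`, `enc_exp`, `fop`, `cbi`, `cai`, `length_nt`,
#'   `n_codons` (+ `exon_length_mean` when supplied).
#' @export
codon_usage_stats <- function(cds_tbl, ref) {
  stopifnot(is.data.frame(cds_tbl), all(c("gene_id", "cds") %in% names(cds_tbl)))
  stopifnot(inherits(ref, "reference_weights"))
  rows <- pmap(list(cds_tbl$gene_id, cds_tbl$cds), function(id, s) {
    cc <- count_codons(s, gene_id = id)
    g3 <- suppressMessages(gc3s(cc))
    tibble(
      gene_id = id,
      gc = gc_content(s),
      gc3s = g3,
      enc_obs = as.numeric(suppressMessages(enc_observed(cc))),
      enc_exp = if (is.na(g3) || g3 <= 0 || g3 >= 1) NA_real_ else enc_expected(g3),
      fop = suppressMessages(fop(cc, ref)),
      cbi = suppressMessages(cbi(cc, ref)),
      cai = suppressMessages(cai(cc, ref)),
      length_nt = nchar(s),
      n_codons = cc$total_codons
    )
  })
  out <- bind_rows(rows)
  if ("exon_length_mean" %in% names(cds_tbl)) {
    out$exon_length_mean <- cds_tbl$exon_length_mean
  }
  out
}

#' Correlate sequence features with codon-bias indices
#'
#' Pearson (or Spearman) correlation of each available feature among
#' GC, GC3s, gene length and mean exon length against each of FOP, CBI and
#' CAI, with two-sided p-values and a significance flag at `alpha`.
#' `r_rounded` reports the coefficient at 1 decimal, the precision at which
#' such family-survey tables are typically printed.
#'
#' @param stats_tbl Output of [codon_usage_stats()].
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param alpha Significance level for the flag (default 0.01).
#' @return Tibble with columns `feature`, `index`, `r`, `r_rounded`,
#'   `p_value`, `significant`. Constant columns yield `NA` with a warning.
#' @export
correlate_features <- function(stats_tbl, method = c("pearson", "spearman"),
                               alpha = 0.01) {
  method <- match.arg(method)
  if (nrow(stats_tbl) < 3) abort("correlate_features needs at least 3 genes")
  features <- intersect(c("gc", "gc3s", "length_nt", "exon_length_mean"),
                        names(stats_tbl))
  indices <- intersect(c("fop", "cbi", "cai"), names(stats_tbl))
  grid <- expand.grid(feature = features, index = indices,
                      stringsAsFactors = FALSE)
  rows <- pmap(grid, function(feature, index) {
    x <- stats_tbl[[feature]]; y <- stats_tbl[[index]]
    keep <- is.finite(x) & is.finite(y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      warn(sprintf("correlation %s ~ %s undefined (constant or too few values)",
                   feature, index))
      return(tibble(feature = feature, index = index, r = NA_real_,
                    r_rounded = NA_real_, p_value = NA_real_, significant = NA))
    }
    ct <- suppressWarnings(cor.test(x, y, method = method))
    tibble(feature = feature, index = index,
           r = unname(ct$estimate),
           r_rounded = round_half_up(unname(ct$estimate), 1),
           p_value = ct$p.value,
           significant = ct$p.value < alpha)
  })
  bind_rows(rows)
}

#' ENC-plot table
#'
#' One row per gene with defined GC3s: observed ENC, the expected ENC at the
#' gene's GC3s, and the residual `enc_obs - enc_expected(gc3s)`. Sorted by
#' GC3s, ready for plotting against Wright's null curve.
#'
#' @param stats_tbl Output of [codon_usage_stats()].
#' @return Tibble `gene_id`, `gc3s`, `enc_obs`, `enc_exp`, `residual`.
#' @export
enc_plot_table <- function(stats_tbl) {
  bad <- !is.finite(stats_tbl$gc3s) | stats_tbl$gc3s <= 0 | stats_tbl$gc3s >= 1
  if (any(bad)) {
    inform(sprintf("enc_plot_table: excluded %d gene(s) with undefined GC3s (%s)",
                   sum(bad), paste(stats_tbl$gene_id[bad], collapse = ", ")))
  }
  tb <- stats_tbl[!bad, ]
  tibble(
    gene_id = tb$gene_id,
    gc3s = tb$gc3s,
    enc_obs = tb$enc_obs,
    enc_exp = enc_expected(tb$gc3s),
    residual = tb$enc_obs - enc_expected(tb$gc3s)
  ) |> arrange(.data$gc3s)
}

#' ENC plot
#'
#' Observed ENC against GC3s with Wright's expected curve overlaid. Genes on
#' the curve use codons as expected from their base composition; genes below
#' it show additional codon-usage bias.
#'
#' @param stats_tbl Output of [codon_usage_stats()] (or an
#'   [enc_plot_table()]).
#' @return A ggplot object.
#' @export
plot_enc <- function(stats_tbl) {
  tb <- if ("residual" %in% names(stats_tbl)) stats_tbl else enc_plot_table(stats_tbl)
  s <- seq(0.01, 0.99, by = 0.01)
  curve <- tibble(gc3s = s, enc = enc_expected(s))
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$gc3s, y = .data$enc_obs)) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$enc), linetype = 2,
                       colour = "grey40") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::coord_cartesian(ylim = c(20, 61), xlim = c(0, 1)) +
    ggplot2::labs(x = "GC3s", y = "Effective number of codons (ENC)") +
    ggplot2::theme_minimal()
}
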