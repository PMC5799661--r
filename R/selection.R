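# Ka/Ks estimation for paralog pairs: codon-aware back-translation of a
# protein alignment onto the CDS pair, Nei-Gojobori (1986) site and
# difference counting with Jukes-Cantor correction, and selection-regime
# classification.

#' Back-translate a pairwise protein alignment to codons
#'
#' Threads each CDS through its gapped protein row: every residue column
#' carries its source codon and every protein gap becomes a `---` triplet,
#' so gaps occur only in whole-codon units. Each CDS must translate exactly
#' to its ungapped protein row (a trailing stop codon on the CDS is
#' allowed and dropped).
#'
#' @param aligned_a,aligned_b Gapped protein rows of equal length.
#' @param cds_a,cds_b The corresponding coding sequences.
#' @param gene_a,gene_b Identifiers carried into the result.
#' @return An object of class `codon_alignment`: list with `gene_a`,
#'   `gene_b` and `codons` (tibble `codon_a`, `codon_b`, one row per
#'   alignment column).
#' @export
backtranslate_alignment <- function(aligned_a, aligned_b, cds_a, cds_b,
                                    gene_a = "a", gene_b = "b") {
  if (nchar(aligned_a) != nchar(aligned_b)) {
    abort("aligned protein rows must have equal length")
  }
  thread <- function(aligned, cds, label) {
    tab <- codon_table()
    codons <- split_codons(cds)
    if (length(codons) > 0 && tab$aa[codons[length(codons)]] == "*") {
      codons <- codons[-length(codons)]
    }
    res <- strsplit(toupper(aligned), "")[[1]]
    out <- character(length(res))
    j <- 0L
    for (i in seq_along(res)) {
      if (res[i] == "-") {
        out[i] <- "---"
      } else {
        j <- j + 1L
        if (j > length(codons)) {
          abort(sprintf("%s: protein row longer than CDS at column %d", label, i))
        }
        if (tab$aa[codons[j]] != res[i]) {
          abort(sprintf("%s: CDS codon %d (%s -> %s) does not translate to protein residue %d (%s)",
                        label, j, codons[j], tab$aa[codons[j]], i, res[i]))
        }
        out[i] <- codons[j]
      }
    }
    if (j != length(codons)) {
      abort(sprintf("%s: CDS has %d codons but protein row uses %d", label,
                    length(codons), j))
    }
    out
  }
  structure(
    list(gene_a = gene_a, gene_b = gene_b,
         codons = tibble(codon_a = thread(aligned_a, cds_a, "cds_a"),
                         codon_b = thread(aligned_b, cds_b, "cds_b"))),
    class = "codon_alignment"
  )
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment> %s vs %s: %d columns\n",
              x$gene_a, x$gene_b, nrow(x$codons)))
  invisible(x)
}

# Fractional synonymous sites of one codon: per position, the fraction of
# the three possible single-base changes that are synonymous. Changes to
# stop codons count as nonsynonymous, so s + n = 3 exactly.
.ng_sites <- function(codon) {
  tab <- codon_table()
  aa0 <- tab$aa[codon]
  bases <- c("A", "C", "G", "T")
  s <- 0
  chars <- strsplit(codon, "")[[1]]
  for (pos in 1:3) {
    for (b in setdiff(bases, chars[pos])) {
      mut <- chars; mut[pos] <- b
      if (tab$aa[paste(mut, collapse = "")] == aa0) s <- s + 1 / 3
    }
  }
  c(s = s, n = 3 - s)
}

# Pathway-averaged synonymous/nonsynonymous difference counts between two
# codons. All orderings of the differing positions are enumerated with equal
# weight; pathways crossing a stop codon are excluded (if every pathway is
# blocked, all are used).
.ng_differences <- function(codon_a, codon_b) {
  tab <- codon_table()
  ca <- strsplit(codon_a, "")[[1]]
  cb <- strsplit(codon_b, "")[[1]]
  diff_pos <- which(ca != cb)
  k <- length(diff_pos)
  if (k == 0) return(c(sd = 0, nd = 0))
  perms <- if (k == 1) list(diff_pos) else {
    asplit(do.call(rbind, lapply(combinat_perms(k), function(p) diff_pos[p])), 1)
  }
  tally <- function(order, allow_stop) {
    cur <- ca; sd <- 0; nd <- 0
    for (pos in order) {
      nxt <- cur; nxt[pos] <- cb[pos]
      aa_cur <- unname(tab$aa[paste(cur, collapse = "")])
      aa_nxt <- unname(tab$aa[paste(nxt, collapse = "")])
      if (!allow_stop && aa_nxt == "*") return(NULL)
      if (aa_cur == aa_nxt) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- lapply(perms, tally, allow_stop = FALSE)
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0) res <- lapply(perms, tally, allow_stop = TRUE)
  m <- do.call(rbind, res)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

# all permutations of 1..k (k <= 3 here)
combinat_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in asplit(permutations_matrix(k), 1)) out <- c(out, list(as.integer(p)))
  out
}

permutations_matrix <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations_matrix(k - 1L)
  out <- NULL
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), k - 1L)))
  }
  out
}

#' Nei-Gojobori Ka/Ks estimate for a codon alignment
#'
#' Classic NG86: synonymous (S) and nonsynonymous (N) site counts are
#' fractional per codon and averaged over the two sequences; synonymous and
#' nonsynonymous differences are averaged with equal weight over the minimal
#' mutational pathways of each multi-hit codon (pathways through stop codons
#' excluded); the proportions `pS = Sd/S` and `pN = Nd/N` are corrected with
#' the Jukes-Cantor formula `d = -(3/4) log(1 - 4p/3)`. Columns containing a
#' gap or a stop codon are dropped before counting.
#'
#' @param caln A [backtranslate_alignment()] result, or a list/tibble with
#'   `codon_a`, `codon_b` columns.
#' @return One-row tibble of class `ng_result`: `gene_a`, `gene_b`, `ka`,
#'   `ks`, `omega`, `n_sites`, `s_sites`, `n_diffs`, `s_diffs`,
#'   `n_codons_used`, `regime`. `omega` is `NA` when `ks` is 0 or undefined;
#'   saturation (`p >= 3/4`) leaves the corresponding distance `NA`.
#' @export
nei_gojobori <- function(caln) {
  tab <- codon_table()
  codons <- if (inherits(caln, "codon_alignment")) caln$codons else as_tibble(caln)
  ga <- if (inherits(caln, "codon_alignment")) caln$gene_a else "a"
  gb <- if (inherits(caln, "codon_alignment")) caln$gene_b else "b"
  ok <- grepl("^[ACGT]{3}$", codons$codon_a) & grepl("^[ACGT]{3}$", codons$codon_b)
  ok <- ok & !(codons$codon_a %in% tab$stop_codons) &
    !(codons$codon_b %in% tab$stop_codons)
  ca <- codons$codon_a[ok]; cb <- codons$codon_b[ok]
  if (length(ca) == 0) abort("nei_gojobori: no ungapped codon columns")

  sites_a <- vapply(ca, .ng_sites, numeric(2))
  sites_b <- vapply(cb, .ng_sites, numeric(2))
  s_sites <- (sum(sites_a["s", ]) + sum(sites_b["s", ])) / 2
  n_sites <- (sum(sites_a["n", ]) + sum(sites_b["n", ])) / 2

  diffs <- vapply(seq_along(ca), function(i) .ng_differences(ca[i], cb[i]),
                  numeric(2))
  sd <- sum(diffs["sd", ]); nd <- sum(diffs["nd", ])

  jc <- function(p) {
    if (!is.finite(p)) return(NA_real_)
    if (p >= 0.75) {
      warn(sprintf("nei_gojobori: proportion %.3f >= 3/4, distance saturated", p))
      return(NA_real_)
    }
    -0.75 * log(1 - 4 * p / 3)
  }
  ks <- if (s_sites > 0) jc(sd / s_sites) else NA_real_
  ka <- if (n_sites > 0) jc(nd / n_sites) else NA_real_
  omega <- if (is.finite(ka) && is.finite(ks) && ks > 0) ka / ks else NA_real_

  out <- tibble(
    gene_a = ga, gene_b = gb,
    ka = ka, ks = ks, omega = omega,
    n_sites = n_sites, s_sites = s_sites,
    n_diffs = nd, s_diffs = sd,
    n_codons_used = length(ca),
    regime = classify_selection(omega)
  )
  class(out) <- c("ng_result", class(out))
  out
}

#' Classify the selection regime from omega
#'
#' Purifying if `omega < 1 - neutral_band`, positive if
#' `omega > 1 + neutral_band`, neutral inside the band, undefined when
#' omega is `NA`. The default band of 0 gives the strict `omega < 1 =>
#' purifying` reading.
#'
#' @param omega Ka/Ks ratio (vectorized).
#' @param neutral_band Half-width of the neutral band around 1 (default 0).
#' @return Character vector: `"purifying"`, `"neutral"`, `"positive"` or
#'   `"undefined"`.
#' @export
classify_selection <- function(omega, neutral_band = 0) {
  dplyr::case_when(
    !is.finite(omega) ~ "undefined",
    omega < 1 - neutral_band ~ "purifying",
    omega > 1 + neutral_band ~ "positive",
    TRUE ~ "neutral"
  )
}

#' Ka/Ks for a set of pairs
#'
#' Convenience wrapper: for each pair, aligns the proteins globally,
#' back-translates onto the CDS pair and runs [nei_gojobori()].
#'
#' @param pairs Tibble with `gene_a`, `gene_b`.
#' @param cds_tbl Tibble with `gene_id`, `cds` (and optionally `protein`;
#'   otherwise proteins are translated from the CDS).
#' @param ... Passed to [global_align()].
#' @return Tibble of [nei_gojobori()] rows.
#' @export
pair_selection <- function(pairs, cds_tbl, ...) {
  get_cds <- setNames(cds_tbl$cds, cds_tbl$gene_id)
  prot <- if ("protein" %in% names(cds_tbl)) {
    setNames(cds_tbl$protein, cds_tbl$gene_id)
  } else {
    setNames(map_chr(cds_tbl$cds, function(s) sub("\\*$", "", translate_cds(s))),
             cds_tbl$gene_id)
  }
  rows <- map(seq_len(nrow(pairs)), function(k) {
    ga <- pairs$gene_a[k]; gb <- pairs$gene_b[k]
    aln <- global_align(prot[[ga]], prot[[gb]], gene_a = ga, gene_b = gb, ...)
    caln <- backtranslate_alignment(aln$aligned_a, aln$aligned_b,
                                    get_cds[[ga]], get_cds[[gb]],
                                    gene_a = ga, gene_b = gb)
    nei_gojobori(caln)
  })
  bind_rows(rows)
}

#' Per-group selection table for triplicate groups
#'
#' One row per requested member pair of each triplicate group, in the layout
#' of a published group/pair/omega table. Pairs without a computed result
#' are flagged.
#'
#' @param groups Tibble from [find_triplicates()] (`gene_1..gene_3`).
#' @param results Tibble of [nei_gojobori()] rows (or [pair_selection()]
#'   output).
#' @param pairs_per_group How many member pairs to list per group (default 2,
#'   the common reporting convention; 3 lists the full triangle).
#' @return Tibble `group`, `gene_a`, `gene_b`, `omega`, `regime`, `missing`.
#' @export
group_selection_table <- function(groups, results, pairs_per_group = 2) {
  if (nrow(groups) == 0) {
    return(tibble(group = integer(0), gene_a = character(0), gene_b = character(0),
                  omega = numeric(0), regime = character(0), missing = logical(0)))
  }
  key <- paste(pmin(results$gene_a, results$gene_b),
               pmax(results$gene_a, results$gene_b), sep = "\r")
  rows <- map(seq_len(nrow(groups)), function(g) {
    genes <- sort(c(groups$gene_1[g], groups$gene_2[g], groups$gene_3[g]))
    prs <- combn(genes, 2)
    take <- seq_len(min(pairs_per_group, ncol(prs)))
    bind_rows(map(take, function(k) {
      ga <- prs[1, k]; gb <- prs[2, k]
      hit <- match(paste(ga, gb, sep = "\r"), key)
      if (is.na(hit)) {
        tibble(group = g, gene_a = ga, gene_b = gb, omega = NA_real_,
               regime = "undefined", missing = TRUE)
      } else {
        tibble(group = g, gene_a = ga, gene_b = gb,
               omega = results$omega[hit], regime = results$regime[hit],
               missing = FALSE)
      }
    }))
  })
  bind_rows(rows)
}

#' Published Ka/Ks ratios for grape bHLH triplicate-group member pairs
#'
#' The published omega (Ka/Ks) values for the two reported member pairs of
#' each of the nine triplicate gene groups in the grape bHLH family, used
#' as reference inputs for selection-regime classification.
#'
#' @return Tibble `group`, `gene_a`, `gene_b`, `omega`.
#' @export
grape_triplicate_omega <- function() {
  path <- system.file("extdata", "grape_triplicate_omega.tsv", package = "genefam")
  as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' @export
tidy.ng_result <- function(x, ...) {
  as_tibble(x)[, c("gene_a", "gene_b", "ka", "ks", "omega", "regime")]
}

#' @export
glance.ng_result <- function(x, ...) {
  tibble(n_codons_used = x$n_codons_used,
         n_sites = x$n_sites, s_sites = x$s_sites,
         omega = x$omega, regime = x$regime)
}
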