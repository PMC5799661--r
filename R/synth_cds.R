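# Synthetic CDS generation with controllable GC3s, and controlled
# divergence of paralog copies at a target omega and Ks on the
# Nei-Gojobori counting scale.

# Expected GC3s given the logistic third-position weight eta, under uniform
# amino-acid usage across the synonymously degenerate families.
.expected_gc3_at <- function(eta) {
  tab <- codon_table()
  fams <- tab$degenerate_families
  mean(map_dbl(fams, function(cods) {
    gc3 <- substr(cods, 3, 3) %in% c("G", "C")
    w <- exp(eta * gc3)
    sum(w[gc3]) / sum(w)
  }))
}

# Solve for the weight eta achieving a target expected GC3s.
.solve_eta <- function(target) {
  if (target <= 0) return(-Inf)
  if (target >= 1) return(Inf)
  stats::uniroot(function(e) .expected_gc3_at(e) - target,
                 lower = -40, upper = 40, tol = 1e-10)$root
}

#' Generate synthetic coding sequences with a target GC3s
#'
#' Each CDS starts with ATG, is a whole number of sense codons (no internal
#' stops by construction) and ends without a stop codon. Codons are drawn by
#' sampling an amino acid uniformly and then a synonymous codon with a
#' single logistic weight on third-position G/C, calibrated so the expected
#' GC3s equals `gc3_target`; realized mean GC3s is within about +-0.05 of
#' the target for 50 or more genes. Targets of exactly 0 or 1 restrict the
#' synonymous choice to A/T-only or G/C-only third positions.
#'
#' @param n Number of genes (>= 1).
#' @param length_range Length range in codons, `c(min, max)`, min >= 10
#'   (includes the ATG).
#' @param gc3_target Target GC3s fraction in `[0, 1]`.
#' @param seed Integer seed; identical calls are byte-identical.
#' @return Tibble `gene_id`, `cds` with attribute `eta` (the solved weight).
#' @export
generate_cds <- function(n, length_range, gc3_target, seed) {
  stopifnot(n >= 1, length(length_range) == 2, length_range[1] >= 10,
            length_range[2] >= length_range[1])
  if (gc3_target < 0 || gc3_target > 1) abort("gc3_target must lie in [0, 1]")
  tab <- codon_table()
  eta <- .solve_eta(gc3_target)
  fam_names <- names(tab$families)
  # per-family sampling weights
  fam_weights <- map(tab$families, function(cods) {
    gc3 <- substr(cods, 3, 3) %in% c("G", "C")
    if (is.infinite(eta)) {
      w <- as.numeric(if (eta > 0) gc3 else !gc3)
      if (sum(w) == 0) w <- rep(1, length(cods))  # Met/Trp have one codon
    } else {
      w <- exp(eta * gc3)
    }
    w / sum(w)
  })
  out <- with_local_seed(seed, {
    map(seq_len(n), function(i) {
      pool <- seq(length_range[1], length_range[2])
      len <- if (length(pool) == 1) pool else sample(pool, 1)
      aas <- sample(fam_names, len - 1, replace = TRUE)
      codons <- map_chr(aas, function(aa) {
        cods <- tab$families[[aa]]
        if (length(cods) == 1) cods else sample(cods, 1, prob = fam_weights[[aa]])
      })
      tibble(gene_id = sprintf("gene%03d", i),
             cds = paste(c("ATG", codons), collapse = ""))
    })
  })
  out <- bind_rows(out)
  attr(out, "eta") <- eta
  out
}

#' Diverge a CDS at a target omega and Ks
#'
#' Produces a paralog copy by proposing random point mutations and
#' accepting synonymous and nonsynonymous changes until their counts reach
#' the quotas implied by `target_ks` and `target_omega` on the Nei-Gojobori
#' scale: with S and N the fractional synonymous/nonsynonymous site counts
#' of the input, the quotas are `Sd = round(pS * S)` and `Nd = round(pN *
#' N)` where pS/pN invert the Jukes-Cantor correction of Ks and Ka =
#' omega * Ks. Each position mutates at most once, no stop codon is ever
#' introduced, and every accepted change is logged, so the log length
#' equals the number of positions at which input and output differ.
#'
#' @param cds Coding sequence.
#' @param target_omega Ka/Ks target (>= 0).
#' @param target_ks Synonymous divergence target (> 0).
#' @param seed Integer seed.
#' @return List: `cds` (diverged sequence), `log` (tibble `position`,
#'   `from`, `to`, `type`), `target_omega`, `target_ks`.
#' @export
diverge_cds <- function(cds, target_omega, target_ks, seed) {
  if (target_ks <= 0) abort("target_ks must be > 0")
  if (target_omega < 0) abort("target_omega must be >= 0")
  tab <- codon_table()
  codons <- split_codons(cds)
  if (any(tab$aa[codons] == "*")) abort("diverge_cds: input contains a stop codon")

  sites <- vapply(codons, .ng_sites, numeric(2))
  S <- sum(sites["s", ]); N <- sum(sites["n", ])
  if (S == 0) {
    abort("diverge_cds: no synonymous sites, requested divergence not reachable (achieved Ks = 0)")
  }
  inv_jc <- function(d) 0.75 * (1 - exp(-4 * d / 3))
  sd_quota <- round(inv_jc(target_ks) * S)
  nd_quota <- round(inv_jc(target_omega * target_ks) * N)

  bases <- c("A", "C", "G", "T")
  chars <- strsplit(paste(codons, collapse = ""), "")[[1]]
  len <- length(chars)
  mutated <- logical(len)
  log_rows <- list()
  sd_done <- 0; nd_done <- 0
  with_local_seed(seed, {
    attempts <- 0; max_attempts <- 300 * len
    while ((sd_done < sd_quota || nd_done < nd_quota) && attempts < max_attempts) {
      attempts <- attempts + 1
      pos <- sample.int(len, 1)
      if (mutated[pos]) next
      new_base <- sample(setdiff(bases, chars[pos]), 1)
      ci <- (pos - 1) %/% 3 + 1
      old_codon <- paste(chars[(ci - 1) * 3 + 1:3], collapse = "")
      new_chars <- chars[(ci - 1) * 3 + 1:3]
      new_chars[(pos - 1) %% 3 + 1] <- new_base
      new_codon <- paste(new_chars, collapse = "")
      if (tab$aa[new_codon] == "*") next
      syn <- tab$aa[new_codon] == tab$aa[old_codon]
      if (syn && sd_done >= sd_quota) next
      if (!syn && nd_done >= nd_quota) next
      log_rows[[length(log_rows) + 1]] <- tibble(
        position = pos, from = chars[pos], to = new_base,
        type = if (syn) "synonymous" else "nonsynonymous"
      )
      chars[pos] <- new_base
      mutated[pos] <- TRUE
      if (syn) sd_done <- sd_done + 1 else nd_done <- nd_done + 1
    }
  })
  if (sd_done < sd_quota || nd_done < nd_quota) {
    achieved_ks <- if (sd_done / S < 0.75) -0.75 * log(1 - 4 * (sd_done / S) / 3) else Inf
    abort(sprintf("diverge_cds: requested divergence not reachable (achieved Ks = %.4f of target %.4f)",
                  achieved_ks, target_ks))
  }
  list(cds = paste(chars, collapse = ""),
       log = if (length(log_rows)) arrange(bind_rows(log_rows), .data$position) else
         tibble(position = integer(0), from = character(0), to = character(0),
                type = character(0)),
       target_omega = target_omega, target_ks = target_ks)
}
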