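test_that("codon counting matches a positional oracle and handles stops and Ns", {
  cc <- count_codons("ATGATG")
  expect_equal(unname(cc$counts["ATG"]), 2L)
  expect_equal(cc$total_codons, 2L)

  cc <- count_codons("ATGTTTTAA")
  expect_equal(cc$total_codons, 2L)
  expect_equal(unname(cc$stop_counts["TAA"]), 1L)

  expect_message(cc <- count_codons("ATGNNNTTT"), "skipped")
  expect_equal(cc$total_codons, 2L)
  expect_equal(cc$n_skipped, 1L)

  for (seed in 1:20) {
    cds <- random_cds(300, seed)
    cc <- count_codons(cds)
    oc <- oracle_codon_counts(cds)
    expect_equal(cc$counts, oc[SENSE])
  }
})

test_that("RSCU follows the k*x/sum(x) formula with undefined unobserved families", {
  # Asp family (GAT, GAC) with counts 3 and 1
  cds <- paste(c("ATG", rep("GAT", 3), "GAC"), collapse = "")
  r <- rscu(cds)
  expect_equal(r$rscu[r$codon == "GAT"], 1.5)
  expect_equal(r$rscu[r$codon == "GAC"], 0.5)

  # Leu entirely as CTG
  r <- rscu(paste(rep("CTG", 10), collapse = ""))
  leu <- r[r$amino_acid == "L", ]
  expect_equal(leu$rscu[leu$codon == "CTG"], 6)
  expect_equal(sum(leu$rscu[leu$codon != "CTG"]), 0)
  # unobserved family undefined, not zero
  expect_true(all(is.na(r$rscu[r$amino_acid == "K"])))

  # uniform usage in every family -> all RSCU 1
  cds <- paste(unlist(FAMS), collapse = "")
  r <- rscu(cds)
  expect_true(all(abs(r$rscu - 1) < 1e-12))
})

test_that("RSCU sums to family size and matches the oracle on random genes", {
  for (seed in 1:10) {
    cds <- random_cds(200, seed)
    r <- rscu(cds)
    by_fam <- split(r$rscu, r$amino_acid)
    for (aa in names(by_fam)) {
      v <- by_fam[[aa]]
      if (!anyNA(v)) expect_equal(sum(v), length(v), tolerance = 1e-9)
    }
    expect_equal(setNames(r$rscu, r$codon)[SENSE], oracle_rscu(cds))
  }
})

test_that("GC3s is computed over synonymous third positions only", {
  expect_message(v <- gc3s(paste(rep(c("ATG", "TGG"), 5), collapse = "")),
                 "undefined")
  expect_true(is.na(v))
  # all third positions G/C outside ATG/TGG
  expect_equal(gc3s("ATGTTCGGCAAG"), 1)
  for (seed in 1:20) {
    cds <- random_cds(150, seed)
    expect_equal(suppressMessages(gc3s(cds)), oracle_gc3s(cds))
  }
})

test_that("observed ENC hits the one-codon-per-family floor and stays in range", {
  # two copies of one codon per family, all families present
  cds <- paste(rep(vapply(FAMS, `[`, character(1), 1), each = 2), collapse = "")
  expect_equal(as.numeric(enc_observed(cds)), 20)

  for (seed in 1:10) {
    enc <- as.numeric(enc_observed(random_cds(80, seed)))
    expect_gte(enc, 20); expect_lte(enc, 61)
  }
})

test_that("uniform synonymous usage gives ENC near 61", {
  withr::with_seed(99, {
    for (rep in 1:20) {
      codons <- unlist(lapply(FAMS, function(cods) {
        sample(cods, 1000 %/% 20, replace = TRUE)
      }))
      enc <- as.numeric(enc_observed(paste(codons, collapse = "")))
      expect_gte(enc, 58); expect_lte(enc, 61)
    }
  })
})

test_that("ENC is invariant under codon-order permutation", {
  cds <- random_cds(200, 42)
  codons <- substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
  shuffled <- withr::with_seed(7, paste(sample(codons), collapse = ""))
  expect_equal(as.numeric(enc_observed(cds)), as.numeric(enc_observed(shuffled)))
})

test_that("the expected-ENC curve has the right values, symmetry and maximum", {
  expect_equal(enc_expected(0.5), 60.5)
  expect_equal(enc_expected(1 - 1e-9), 32, tolerance = 1e-6)
  # the linear term makes the curve near- but not exactly symmetric:
  # enc(s) - enc(1 - s) = 2s - 1 exactly
  s <- seq(0.05, 0.95, by = 0.05)
  expect_equal(enc_expected(s) - enc_expected(1 - s), 2 * s - 1, tolerance = 1e-9)
  grid <- seq(0.01, 0.99, by = 0.001)
  expect_lt(abs(grid[which.max(enc_expected(grid))] - 0.5), 0.01)
  expect_error(enc_expected(0), "between 0 and 1")
  expect_error(enc_expected(1.2), "between 0 and 1")
})

test_that("CAI, FOP and CBI behave at the bounds and exclude Met/Trp", {
  ref_cds <- paste(rep(unlist(FAMS), 3), collapse = "")  # uniform reference
  ref <- suppressMessages(reference_weights(list(ref_cds)))
  # build an all-optimal gene from the reference optimal set
  gene <- paste(rep(ref$optimal_set, 2), collapse = "")
  expect_equal(cai(gene, ref), 1, tolerance = 1e-9)
  expect_equal(fop(gene, ref), 1)
  expect_equal(cbi(gene, ref), 1)

  # appending a Met codon leaves CAI unchanged
  expect_equal(cai(paste0(gene, "ATG"), ref), cai(gene, ref))

  # zero optimal codons used -> FOP 0, CBI negative
  non_opt <- vapply(FAMS, function(cods) {
    alt <- setdiff(cods, ref$optimal_set)
    if (length(alt)) alt[1] else cods[1]
  }, character(1))
  non_opt <- non_opt[!non_opt %in% ref$optimal_set]
  gene0 <- paste(rep(non_opt, 2), collapse = "")
  expect_equal(fop(gene0, ref), 0)
  expect_lt(cbi(gene0, ref), 0)
})

test_that("CAI equals the log-domain oracle with a self reference", {
  for (seed in 1:5) {
    cds <- random_cds(300, seed)
    ref <- reference_weights(list(cds), pseudocount = 0.5)
    v <- cai(cds, ref)
    # independent log-domain computation
    cnt <- oracle_codon_counts(cds)
    elig <- unlist(FAMS[lengths(FAMS) >= 2])
    w <- ref$w[elig]; n <- cnt[elig]
    expect_equal(v, exp(sum(n * log(w)) / sum(n)), tolerance = 1e-12)
  }
})

test_that("uniform within-family usage gives CBI near zero", {
  withr::with_seed(123, {
    for (rep in 1:5) {
      codons <- unlist(lapply(FAMS[lengths(FAMS) >= 2], function(cods) {
        sample(cods, 55, replace = TRUE)
      }))
      cds <- paste(sample(codons), collapse = "")
      ref_cds <- paste(rep(unlist(FAMS), 2), collapse = "")
      ref <- suppressMessages(reference_weights(list(ref_cds)))
      expect_lt(abs(cbi(cds, ref)), 0.1)
    }
  })
})

test_that("swapping a non-optimal codon for the optimal one never lowers the indices", {
  cds <- random_cds(200, 11)
  ref <- reference_weights(list(random_cds(500, 12)))
  codons <- substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
  non_opt_idx <- which(!codons %in% c(ref$optimal_set, "ATG", "TGG") &
                         GENCODE[codons] != "*")
  withr::with_seed(5, {
    for (i in sample(non_opt_idx, 10)) {
      aa <- GENCODE[codons[i]]
      opt <- intersect(FAMS[[aa]], ref$optimal_set)
      if (length(opt) == 0) next
      mutated <- codons; mutated[i] <- opt[1]
      cds2 <- paste(mutated, collapse = "")
      expect_gte(fop(cds2, ref), fop(cds, ref))
      expect_gte(cbi(cds2, ref), cbi(cds, ref))
      expect_gte(cai(cds2, ref), cai(cds, ref))
    }
  })
})

test_that("feature correlations flag perfect relationships and calibrate type-I error", {
  # FOP an exact linear function of GC3s
  st <- tibble::tibble(gene_id = paste0("g", 1:20),
                       gc3s = seq(0.3, 0.7, length.out = 20))
  st$fop <- 0.2 + 0.5 * st$gc3s
  out <- correlate_features(st)
  row <- out[out$feature == "gc3s" & out$index == "fop", ]
  expect_equal(row$r, 1, tolerance = 1e-12)
  expect_true(row$significant)

  # constant column -> NA with warning
  st$cbi <- 0.5
  expect_warning(out <- correlate_features(st), "undefined")
  expect_true(is.na(out$r[out$index == "cbi"][1]))

  # independent columns: flag rate at p < 0.01 is ~1%
  flags <- withr::with_seed(2024, {
    unlist(lapply(1:100, function(i) {
      st <- tibble::tibble(gene_id = paste0("g", 1:100),
                           gc = rnorm(100), gc3s = rnorm(100),
                           fop = rnorm(100), cbi = rnorm(100), cai = rnorm(100))
      correlate_features(st)$significant
    }))
  })
  expect_lt(abs(mean(flags) - 0.01), 0.02)
})

test_that("the ENC-plot table filters undefined GC3s and centres residuals under the null", {
  ref <- reference_weights(list(random_cds(500, 3)))
  withr::with_seed(17, {
    genes <- lapply(1:10, function(i) {
      codons <- unlist(lapply(FAMS, function(cods) sample(cods, 50, replace = TRUE)))
      paste(sample(codons), collapse = "")
    })
  })
  tb <- codon_usage_stats(tibble::tibble(gene_id = paste0("g", 1:10),
                                         cds = unlist(genes)), ref)
  ep <- enc_plot_table(tb)
  expect_equal(nrow(ep), sum(is.finite(tb$gc3s)))
  expect_true(all(abs(ep$residual) < 3))
  expect_false(is.unsorted(ep$gc3s))

  # undefined GC3s genes are excluded with a message
  tb2 <- dplyr::bind_rows(tb, tibble::tibble(gene_id = "gNA", gc3s = NA_real_,
                                             enc_obs = 45))
  expect_message(ep2 <- enc_plot_table(tb2), "excluded")
  expect_equal(nrow(ep2), nrow(ep))
})
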