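test_that("consensus matching honours IUPAC degeneracy and never matches sequence Ns", {
  hits <- scan_motifs(c(s = "CACGTG"))
  expect_true(any(hits$motif == "G-box" & hits$position == 1))
  expect_true(any(hits$motif == "E-box" & hits$position == 1))

  hits <- scan_motifs(c(s = "CAGTTG"))
  expect_true(any(hits$motif == "E-box" & hits$position == 1))
  expect_false(any(hits$motif == "G-box"))

  # N in the sequence never matches
  hits <- scan_motifs(c(s = "CANGTG"))
  expect_false(any(hits$motif %in% c("G-box", "E-box") & hits$position == 1))
})

test_that("motif tables are validated at load", {
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("name\tconsensus\tboth_strands", "bad\tCAXGTG\tTRUE"), bad)
  expect_error(load_motifs(bad), "invalid IUPAC")
  short <- tempfile(fileext = ".tsv")
  writeLines(c("name\tconsensus\tboth_strands", "short\tCAG\tTRUE"), short)
  expect_error(load_motifs(short), "at least 4")
})

test_that("scans agree with a regex oracle on random sequence, both strands", {
  withr::with_seed(55, {
    seq10k <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                    collapse = "")
  })
  motifs <- load_motifs()
  hits <- scan_motifs(c(s = seq10k), motifs)
  for (m in motifs$name) {
    cons <- motifs$consensus[motifs$name == m]
    o <- oracle_motif_scan(seq10k, cons)
    got_fwd <- sort(hits$position[hits$motif == m & hits$strand == "+"])
    expect_equal(got_fwd, sort(o$fwd), label = paste(m, "fwd"))
    is_palindrome <- cons == genefam:::revcomp(cons)
    if (!is_palindrome) {
      got_rev <- sort(hits$position[hits$motif == m & hits$strand == "-"])
      expect_equal(got_rev, sort(o$rev), label = paste(m, "rev"))
    } else {
      # palindromes are deduplicated to a single + record per site
      expect_equal(sum(hits$motif == m & hits$strand == "-"), 0L)
    }
  }
})

test_that("reverse-complement scans mirror forward scans", {
  withr::with_seed(56, {
    s <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE), collapse = "")
  })
  motifs <- load_motifs()
  fwd <- scan_motifs(c(x = s), motifs)
  rev <- scan_motifs(c(x = genefam:::revcomp(s)), motifs)
  L <- nchar(s)
  for (m in motifs$name) {
    w <- nchar(motifs$consensus[motifs$name == m])
    pos_f <- sort(c(fwd$position[fwd$motif == m]))
    # a hit at p on either strand of s corresponds to a hit at L - p - w + 2
    # on the reverse complement
    pos_r <- sort(L - rev$position[rev$motif == m] - w + 2)
    expect_equal(sort(pos_f), sort(pos_r), label = m)
  }
})

test_that("hit counts on random sequence match the analytic expectation", {
  # E-box CANNTG on GC=0.5 background: per-position match probability
  # (1/4)^4 (both strands coincide: CANNTG's complement class is itself)
  withr::with_seed(57, {
    s <- paste(sample(c("A", "C", "G", "T"), 50000, replace = TRUE), collapse = "")
  })
  hits <- scan_motifs(c(x = s), load_motifs())
  n_ebox <- sum(hits$motif == "E-box")
  L <- 50000; w <- 6
  # + strand expectation; CANNTG is not palindromic as a degenerate class?
  # it is: revcomp(CANNTG) = CANNTG, so only + hits are recorded
  p <- (1 / 4)^4
  expected <- (L - w + 1) * p
  sd3 <- 3 * sqrt((L - w + 1) * p * (1 - p))
  expect_lt(abs(n_ebox - expected), sd3)
})

test_that("promoters are extracted strand-aware with clipping flags", {
  withr::with_seed(58, {
    contig <- paste(sample(c("A", "C", "G", "T"), 6000, replace = TRUE),
                    collapse = "")
  })
  models <- tibble::tibble(
    gene_id = c("plus", "edge"),
    chromosome = "chr1", strand = "+",
    n_exons = 1L, cds_length = 300L, valid = TRUE,
    exons = list(tibble::tibble(start = 5001, end = 5300),
                 tibble::tibble(start = 500, end = 799)))
  pr <- extract_promoters(c(chr1 = contig), models, length = 2000)
  expect_equal(pr$promoter[1], substr(contig, 3001, 5000))
  expect_false(pr$clipped[1])
  expect_equal(pr$length[2], 499L)
  expect_true(pr$clipped[2])

  # minus strand: promoter is downstream in genomic coordinates, reverse
  # complemented, position 1 most distal
  mmodels <- tibble::tibble(
    gene_id = "minus", chromosome = "chr1", strand = "-",
    n_exons = 1L, cds_length = 300L, valid = TRUE,
    exons = list(tibble::tibble(start = 1000, end = 1299)))
  pm <- extract_promoters(c(chr1 = contig), mmodels, length = 500)
  expect_equal(pm$promoter, genefam:::revcomp(substr(contig, 1300, 1799)))

  # absent contig skipped with a message
  gone <- dplyr::mutate(mmodels, chromosome = "chrX")
  expect_message(out <- extract_promoters(c(chr1 = contig), gone), "skipped")
  expect_equal(nrow(out), 0)
})

test_that("planted promoter fixtures round-trip through extraction and scanning", {
  pr <- generate_promoter(1000, tibble::tibble(motif = c("G-box", "CRT/DRE"),
                                               position = c(200L, 700L),
                                               strand = c("+", "-")),
                          background_gc = 0.4, seed = 59)
  # embed the promoter upstream of a plus-strand gene
  cds <- generate_cds(1, c(50, 50), 0.5, seed = 60)$cds
  contig <- paste0(pr$sequence, cds)
  models <- tibble::tibble(gene_id = "g", chromosome = "c", strand = "+",
                           n_exons = 1L, cds_length = nchar(cds), valid = TRUE,
                           exons = list(tibble::tibble(start = 1001,
                                                       end = 1000 + nchar(cds))))
  got <- extract_promoters(c(c = contig), models, length = 1000)
  expect_equal(got$promoter, pr$sequence)
  hits <- scan_motifs(got)
  expect_true(any(hits$motif == "G-box" & hits$position == 200 & hits$strand == "+"))
  expect_true(any(hits$motif == "CRT/DRE" & hits$position == 700 & hits$strand == "-"))
})

test_that("element summaries report presence booleans and any-of fractions", {
  genes <- sprintf("g%02d", 1:64)
  hits <- tibble::tibble(
    gene_id = c(genes[1:40], genes[41:60], genes[1]),
    motif = c(rep("G-box", 40), rep("E-box", 20), "G-box"),
    position = 1L, strand = "+", matched_sequence = "CACGTG")
  s <- summarize_elements(hits, genes,
                          list(gbox_or_ebox = c("G-box", "E-box")))
  expect_equal(s$group_fractions$n_with, 60L)
  expect_equal(s$group_fractions$fraction, 60 / 64)
  # presence is idempotent in hit multiplicity
  expect_equal(sum(s$presence[["G-box"]]), 40L)

  none <- summarize_elements(hits[0, ], genes, list(gbox = "G-box"))
  expect_equal(ncol(none$presence), 1L)  # no motif observed anywhere
  expect_equal(none$group_fractions$fraction, 0)

  expect_error(summarize_elements(hits, character(0), list()), "empty gene set")
})
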