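mk_dm <- function(v, taxa) {
  n <- length(taxa)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  d[lower.tri(d)] <- v
  d + t(d)
}

test_that("p-distances use pairwise gap deletion", {
  aln <- c(a = "AAAAA", b = "AAAAA")
  expect_equal(unname(p_distance(aln)["a", "b"]), 0)

  a <- paste(rep("A", 100), collapse = "")
  b <- paste(c(rep("A", 95), rep("C", 5)), collapse = "")
  expect_equal(unname(p_distance(c(a = a, b = b))["a", "b"]), 0.05)

  # gap-containing columns excluded per pair: column-walk oracle
  withr::with_seed(77, {
    rows <- vapply(1:4, function(i) {
      paste(sample(c("A", "C", "D", "E", "-"), 60, replace = TRUE,
                   prob = c(0.2, 0.2, 0.2, 0.2, 0.2)), collapse = "")
    }, character(1))
  })
  names(rows) <- paste0("t", 1:4)
  d <- p_distance(rows)
  mat <- do.call(rbind, strsplit(rows, ""))
  for (i in 1:3) for (j in (i + 1):4) {
    num <- 0; den <- 0
    for (k in 1:60) {
      if (mat[i, k] != "-" && mat[j, k] != "-") {
        den <- den + 1
        if (mat[i, k] != mat[j, k]) num <- num + 1
      }
    }
    expect_equal(unname(d[i, j]), num / den)
  }

  expect_error(p_distance(c(a = "A-", b = "-A")), "no comparable columns")
})

test_that("NJ solves the 3-taxon case in closed form", {
  d <- mk_dm(c(2, 4, 4), c("A", "B", "C"))
  tr <- neighbor_joining(d)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl[c("A", "B", "C")]), c(1, 1, 3))
})

test_that("NJ recovers trees exactly from additive metrics", {
  # fixed 4-taxon additive metric from tree ((A:1,B:2):1,(C:3,D:1));
  d <- mk_dm(c(3, 5, 3, 6, 4, 4), c("A", "B", "C", "D"))
  tr <- neighbor_joining(d)
  # the AB|CD split must be present with internal edge length 1
  bp <- genefam:::tree_bipartitions(tr)
  expect_true("C|D" %in% bp || "A|B" %in% bp)
  expect_equal(sum(tr$edge.length), 1 + 2 + 1 + 3 + 1)

  # random additive metrics up to 8 taxa round-trip topologically
  withr::with_seed(88, {
    for (n in c(5, 6, 8)) {
      gen <- ape::rtree(n, br = function(k) runif(k, 0.5, 2))
      gen <- ape::unroot(gen)
      dm <- cophenetic(gen)
      dm <- dm[sort(rownames(dm)), sort(colnames(dm))]
      rec <- neighbor_joining(dm)
      expect_equal(as.numeric(ape::dist.topo(ape::unroot(rec), gen)), 0)
      # and matches ape's independent NJ implementation
      expect_equal(as.numeric(ape::dist.topo(ape::unroot(ape::nj(dm)),
                                            ape::unroot(rec))), 0)
    }
  })
})

test_that("NJ is invariant to taxon input order", {
  withr::with_seed(89, {
    gen <- ape::unroot(ape::rtree(7))
    dm <- cophenetic(gen)
    perm <- sample(rownames(dm))
  })
  t1 <- neighbor_joining(dm)
  t2 <- neighbor_joining(dm[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(t1, t2)), 0)
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "at least 3")
  bad <- mk_dm(c(1, 2, 3), c("a", "b", "c")); bad[1, 2] <- 9
  expect_error(neighbor_joining(bad), "symmetric")
})

test_that("bootstrap support is deterministic and finds unambiguous cherries", {
  aln <- c(A1 = "AAAAAAAAAACCCCC", A2 = "AAAAAAAAAACCCCG",
           B1 = "TTTTTTTTTTCCCCC", B2 = "TTTTTTTTTTCCCCG",
           C1 = "GGGGGGGGGGCCCCC", C2 = "GGGGGGGGGGCCCCG")
  bs <- bootstrap_support(aln, n_replicates = 100, seed = 5)
  cherries <- bs$support[bs$support$n_taxa_in_clade == 2, ]
  expect_true(all(cherries$support == 100))

  bs2 <- bootstrap_support(aln, n_replicates = 100, seed = 5)
  expect_equal(bs$support, bs2$support)

  one <- bootstrap_support(aln, n_replicates = 1, seed = 9)
  expect_true(all(one$support$support %in% c(0, 100)))

  expect_error(bootstrap_support(aln, n_replicates = 0, seed = 1), "n_replicates")
})

test_that("bipartition supports are invariant under taxon relabeling", {
  withr::with_seed(90, {
    rows <- vapply(1:6, function(i) {
      paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
    }, character(1))
  })
  names(rows) <- paste0("x", 1:6)
  bs1 <- bootstrap_support(rows, n_replicates = 50, seed = 3)
  relabeled <- rows
  names(relabeled) <- paste0("y", 1:6)
  bs2 <- bootstrap_support(relabeled, n_replicates = 50, seed = 3)
  expect_equal(sort(bs1$support$support), sort(bs2$support$support))
})

test_that("clade calling partitions taxa at the threshold", {
  # three strongly separated groups + 2 random taxa
  withr::with_seed(91, {
    block <- function(ch, n) {
      vapply(1:n, function(i) {
        s <- rep(ch, 60)
        flip <- sample(60, 3)
        s[flip] <- sample(c("A", "C", "G", "T"), 3, replace = TRUE)
        paste(s, collapse = "")
      }, character(1))
    }
    aln <- c(block("A", 6), block("C", 6), block("G", 6),
             vapply(1:2, function(i) {
               paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                     collapse = "")
             }, character(1)))
    names(aln) <- c(paste0("grpA_", 1:6), paste0("grpC_", 1:6),
                    paste0("grpG_", 1:6), c("rand1", "rand2"))
  })
  bs <- bootstrap_support(aln, n_replicates = 100, seed = 6)
  cc <- call_clades(bs, threshold = 70)
  grp_clades <- Filter(function(cl) length(cl) == 6, cc$clades)
  prefixes <- sort(vapply(grp_clades, function(cl) {
    unique(substr(cl, 1, 4))
  }, character(1)))
  expect_equal(prefixes, c("grpA", "grpC", "grpG"))
  expect_true(all(c("rand1", "rand2") %in%
                    c(cc$orphans, unlist(Filter(function(cl) length(cl) < 6,
                                                cc$clades)))))

  # all supports below threshold: everything orphaned
  none <- bs
  none$support$support <- 0
  cc0 <- call_clades(none, threshold = 70)
  expect_equal(length(cc0$clades), 0)
  expect_equal(sort(cc0$orphans), sort(names(aln)))

  # a balanced 4-taxon tree with full support leaves no orphans
  four <- c(A = "AAAAAAAAGG", B = "AAAAAAAACC", C = "TTTTTTTTGG", D = "TTTTTTTTCC")
  bs4 <- bootstrap_support(four, n_replicates = 50, seed = 7)
  bs4$support$support <- 100
  cc4 <- call_clades(bs4, threshold = 70)
  expect_equal(length(cc4$orphans), 0)
})
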