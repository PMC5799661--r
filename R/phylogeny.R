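# Neighbor-joining phylogeny from a protein alignment: p-distances with
# pairwise gap deletion, Saitou-Nei NJ with a documented tie-break,
# bootstrap bipartition support, and clade calling at a support threshold.

#' Protein p-distance matrix with pairwise gap deletion
#'
#' For each pair of rows, the fraction of differing residues over columns
#' where both rows are ungapped. A Poisson correction
#' (`-log(1 - p)`) is available for deeper divergences.
#'
#' @param alignment Named character vector (or tibble with `gene_id` and
#'   `aligned` columns, or `AAStringSet`) of equal-length gapped rows.
#' @param model `"p"` (default) or `"poisson"`.
#' @return Symmetric numeric matrix with taxon dimnames.
#' @export
p_distance <- function(alignment, model = c("p", "poisson")) {
  model <- match.arg(model)
  if (is.data.frame(alignment)) {
    alignment <- setNames(alignment$aligned, alignment$gene_id)
  } else if (inherits(alignment, "AAStringSet")) {
    alignment <- setNames(as.character(alignment), names(alignment))
  }
  if (length(unique(nchar(alignment))) != 1) {
    abort("p_distance: alignment rows must have equal length")
  }
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  taxa <- names(alignment)
  n <- nrow(mat)
  gap <- mat == "-" | mat == "."
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      use <- !gap[i, ] & !gap[j, ]
      if (!any(use)) {
        abort(sprintf("p_distance: no comparable columns for pair %s / %s",
                      taxa[i], taxa[j]))
      }
      p <- mean(mat[i, use] != mat[j, use])
      d[i, j] <- d[j, i] <- if (model == "p") p else {
        if (p >= 1) abort("p_distance: Poisson correction undefined at p = 1")
        -log(1 - p)
      }
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei NJ with the Studier-Keppler Q criterion. At each step the pair
#' minimizing `Q(i,j) = (r - 2) d(i,j) - R_i - R_j` is joined; ties are
#' broken by the lowest (row, column) index pair for reproducibility.
#' Branch lengths use the standard formulas; negative lengths are clamped
#' to 0 and the clamped deficit is reported as an attribute.
#'
#' @param dm Symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return An unrooted `ape::phylo` tree. Attribute `negative_deficit`
#'   holds the total branch length removed by clamping.
#' @export
neighbor_joining <- function(dm) {
  n <- nrow(dm)
  if (n < 3) abort("neighbor_joining: needs at least 3 taxa")
  if (!isSymmetric(unname(dm), tol = 1e-8)) abort("neighbor_joining: matrix must be symmetric")
  labels <- rownames(dm)
  # working state: each active node is a newick subtree string
  sub <- labels
  d <- dm
  deficit <- 0
  clamp <- function(x) {
    if (x < 0) { deficit <<- deficit + (-x); 0 } else x
  }
  while (nrow(d) > 3) {
    r <- nrow(d)
    R <- rowSums(d)
    q <- (r - 2) * d - outer(R, R, `+`)
    diag(q) <- Inf
    # lowest (row, col) pair among minima, scanning column-major on the
    # upper triangle in (row, col) order
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- best[1]; j <- best[2]
    vi <- clamp(d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2)))
    vj <- clamp(d[i, j] - (d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))))
    new_sub <- sprintf("(%s:%.10g,%s:%.10g)", sub[i], vi, sub[j], vj)
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d_new <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    sub <- c(sub[keep], new_sub)
    dimnames(d_new) <- list(seq_len(r - 1), seq_len(r - 1))
    d <- d_new
  }
  # final three-way join
  la <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  lb <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  lc <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  newick <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", sub[1], la, sub[2], lb, sub[3], lc)
  tree <- ape::read.tree(text = newick)
  attr(tree, "negative_deficit") <- deficit
  tree
}

# Non-trivial bipartitions of an unrooted phylo as canonical keys: for each
# internal edge, the tip set on the side NOT containing the reference taxon
# (lexicographically first label), sorted and collapsed to a string.
tree_bipartitions <- function(tree) {
  tips <- tree$tip.label
  ref <- sort(tips)[1]
  n <- length(tips)
  internal <- tree$edge[, 2] > n
  keys <- character(0)
  for (node in unique(tree$edge[internal, 2])) {
    desc <- tips[phangorn_descendants(tree, node)]
    side <- if (ref %in% desc) setdiff(tips, desc) else desc
    if (length(side) >= 2 && length(side) <= n - 2) {
      keys <- c(keys, paste(sort(side), collapse = "|"))
    }
  }
  unique(keys)
}

# tip indices below an internal node (iterative, no recursion limits)
phangorn_descendants <- function(tree, node) {
  n <- length(tree$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    cur <- stack[length(stack)]; stack <- stack[-length(stack)]
    kids <- tree$edge[tree$edge[, 1] == cur, 2]
    out <- c(out, kids[kids <= n])
    stack <- c(stack, kids[kids > n])
  }
  out
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and scores every internal edge of the original tree by the
#' percentage of replicate trees containing the same bipartition.
#'
#' @param alignment As in [p_distance()].
#' @param n_replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed for the resampling.
#' @param model Distance model, passed to [p_distance()].
#' @return Object of class `support_tree`: list with `tree` (`phylo`),
#'   `support` (tibble `bipartition`, `n_taxa_in_clade`, `support` in
#'   percent) and `n_replicates`.
#' @export
bootstrap_support <- function(alignment, n_replicates = 1000, seed = 1,
                              model = "p") {
  if (n_replicates < 1) abort("bootstrap_support: n_replicates must be >= 1")
  if (is.data.frame(alignment)) {
    alignment <- setNames(alignment$aligned, alignment$gene_id)
  }
  tree <- neighbor_joining(p_distance(alignment, model = model))
  orig <- tree_bipartitions(tree)
  counts <- setNames(numeric(length(orig)), orig)
  len <- nchar(alignment[[1]])
  rows <- strsplit(toupper(alignment), "")
  with_local_seed(seed, {
    for (b in seq_len(n_replicates)) {
      cols <- sample.int(len, len, replace = TRUE)
      res <- setNames(
        vapply(rows, function(r) paste(r[cols], collapse = ""), character(1)),
        names(alignment)
      )
      bt <- try(neighbor_joining(p_distance(res, model = model)), silent = TRUE)
      if (inherits(bt, "try-error")) next
      bp <- tree_bipartitions(bt)
      hit <- orig %in% bp
      counts[hit] <- counts[hit] + 1
    }
  })
  support <- tibble(
    bipartition = orig,
    n_taxa_in_clade = map_int(strsplit(orig, "\\|"), length),
    support = 100 * unname(counts) / n_replicates
  )
  structure(list(tree = tree, support = support, n_replicates = n_replicates),
            class = "support_tree")
}

#' @export
print.support_tree <- function(x, ...) {
  cat(sprintf("<support_tree> %d taxa, %d internal bipartitions, %d bootstrap replicates\n",
              length(x$tree$tip.label), nrow(x$support), x$n_replicates))
  invisible(x)
}

#' @export
tidy.support_tree <- function(x, ...) x$support

#' @export
glance.support_tree <- function(x, ...) {
  tibble(n_taxa = length(x$tree$tip.label),
         n_bipartitions = nrow(x$support),
         n_replicates = x$n_replicates,
         mean_support = mean(x$support$support))
}

#' Call clades at a bootstrap-support threshold
#'
#' A bipartition with support >= `threshold` defines a candidate clade: the
#' minority side of the split (both sides for an even split). Maximal
#' candidates under set inclusion are reported as the called clades; taxa
#' outside every called clade are orphans.
#'
#' @param st A [bootstrap_support()] result.
#' @param threshold Support threshold in percent (default 70).
#' @return List of class `clade_call`: `clades` (list of character
#'   vectors), `orphans` (character vector), `threshold`.
#' @export
call_clades <- function(st, threshold = 70) {
  stopifnot(inherits(st, "support_tree"))
  taxa <- st$tree$tip.label
  n <- length(taxa)
  passed <- st$support[st$support$support >= threshold, ]
  cands <- list()
  for (bp in passed$bipartition) {
    side <- strsplit(bp, "\\|")[[1]]
    other <- setdiff(taxa, side)
    if (length(side) < length(other)) {
      cands <- c(cands, list(side))
    } else if (length(side) > length(other)) {
      cands <- c(cands, list(other))
    } else {
      cands <- c(cands, list(side), list(other))
    }
  }
  cands <- unique(map(cands, sort))
  keep <- map_lgl(seq_along(cands), function(i) {
    !any(map_lgl(seq_along(cands), function(j) {
      i != j && all(cands[[i]] %in% cands[[j]])
    }))
  })
  clades <- cands[keep]
  orphans <- setdiff(taxa, unique(unlist(clades)))
  structure(list(clades = clades, orphans = sort(orphans), threshold = threshold),
            class = "clade_call")
}

#' @export
print.clade_call <- function(x, ...) {
  cat(sprintf("<clade_call> %d clade(s) at support >= %g, %d orphan(s)\n",
              length(x$clades), x$threshold, length(x$orphans)))
  for (i in seq_along(x$clades)) {
    cat(sprintf("  clade %d: %s\n", i, paste(x$clades[[i]], collapse = ", ")))
  }
  if (length(x$orphans)) cat("  orphans:", paste(x$orphans, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.clade_call <- function(x, ...) {
  bind_rows(
    imap(x$clades, function(members, i) {
      tibble(clade = as.integer(i), gene_id = members)
    }),
    if (length(x$orphans)) tibble(clade = NA_integer_, gene_id = x$orphans)
  )
}

#' Write a support-annotated tree to Newick
#'
#' Internal-node bootstrap supports are attached as node labels.
#'
#' @param st A [bootstrap_support()] result.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_support_tree <- function(st, path) {
  tree <- st$tree
  n <- length(tree$tip.label)
  n_nodes <- tree$Nnode
  labels <- rep("", n_nodes)
  key_of <- setNames(st$support$support, st$support$bipartition)
  tips <- tree$tip.label
  ref <- sort(tips)[1]
  for (node in seq_len(n_nodes) + n) {
    desc <- tips[phangorn_descendants(tree, node)]
    side <- if (ref %in% desc) setdiff(tips, desc) else desc
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(key_of)) labels[node - n] <- format(key_of[[key]])
  }
  tree$node.label <- labels
  ape::write.tree(tree, file = path)
  invisible(path)
}
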