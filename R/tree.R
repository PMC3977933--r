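# Stage 2: neighbor-joining guide tree, midpoint rooting,
# branch-proportional sequence weights and the progressive merge schedule.
# Trees are ape `phylo` objects throughout.

#' Neighbor-joining guide tree from a distance matrix
#'
#' Saitou-Nei neighbor joining: the pair minimizing the Q criterion is
#' joined iteratively (ties broken to the smallest index pair), branch
#' lengths follow the standard NJ formulas, and a negative branch length
#' is clamped to zero with the deficit transferred to its sister branch so
#' the joined pair's path length is preserved.  The result is the usual
#' unrooted tree, represented with a trifurcating root node (for `n = 2`,
#' a single edge split evenly).
#'
#' @param dm Symmetric, non-negative, zero-diagonal distance matrix with
#'   id dimnames (`n >= 2`).
#' @return A `phylo` tree whose leaves are the matrix ids.
#' @examples
#' d <- matrix(c(0, .4, .4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
#' nj_build(d)$edge.length
#' @export
nj_build <- function(dm) {
  validate_distance_matrix(dm)
  n <- nrow(dm)
  ids <- rownames(dm)
  fmt <- function(x) sprintf("%.10g", x)
  if (n == 2L) {
    nwk <- paste0("(", ids[1], ":", fmt(dm[1, 2] / 2), ",",
                  ids[2], ":", fmt(dm[1, 2] / 2), ");")
    return(ape::read.tree(text = nwk))
  }
  labels <- ids            # newick fragment per active node
  d <- dm
  active <- seq_len(n)
  while (length(active) > 3L) {
    m <- length(active)
    rs <- rowSums(d)
    best <- NULL; bestq <- Inf
    for (i in 1:(m - 1L)) {
      for (j in (i + 1L):m) {
        q <- (m - 2) * d[i, j] - rs[i] - rs[j]
        if (q < bestq - 1e-12) { bestq <- q; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    li <- d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- max(0, lj + li); li <- 0 }
    else if (lj < 0) { li <- max(0, li + lj); lj <- 0 }
    newlab <- paste0("(", labels[i], ":", fmt(li), ",",
                     labels[j], ":", fmt(lj), ")")
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    labels <- c(labels[keep], newlab)
    active <- seq_len(m - 1L)
  }
  if (length(labels) == 3L) {
    la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
    lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
    lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
    nwk <- paste0("(", labels[1], ":", fmt(max(0, la)), ",",
                  labels[2], ":", fmt(max(0, lb)), ",",
                  labels[3], ":", fmt(max(0, lc)), ");")
  } else {  # started from n == 3 is handled above; n shrank to 2
    nwk <- paste0("(", labels[1], ":", fmt(d[1, 2] / 2), ",",
                  labels[2], ":", fmt(d[1, 2] / 2), ");")
  }
  ape::read.tree(text = nwk)
}

#' Midpoint rooting of a guide tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path, the
#' Clustal-family convention for orienting the unrooted NJ tree before
#' progressive alignment.  Leaf-to-leaf path lengths are preserved.
#'
#' @param tree A `phylo` tree with at least two leaves.
#' @return A rooted `phylo` tree.
#' @export
midpoint_root <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object")
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stop("tree must have at least two leaves")
  if (ntip == 2L) {
    total <- sum(tree$edge.length)
    tree$edge.length <- rep(total / 2, length(tree$edge.length))
    return(tree)
  }
  phangorn::midpoint(tree)
}

#' Tree-derived sequence weights
#'
#' Branch-proportional weights: each leaf's weight is the sum, over the
#' branches on its root-to-leaf path, of the branch length divided by the
#' number of leaves sharing that branch; weights are then normalized so
#' the largest is 1.  Diverged sequences are up-weighted, redundant
#' near-duplicates down-weighted.  A tree with zero total length yields
#' equal weights of 1.
#'
#' @param tree A rooted `phylo` tree with non-negative branch lengths.
#' @return Named numeric vector of positive weights, maximum 1.
#' @export
compute_weights <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object")
  ntip <- length(tree$tip.label)
  nleaves_below <- edge_leaf_counts(tree)
  parent_edge <- integer(max(tree$edge))  # edge index leading into node
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  root <- ntip + 1L
  w <- numeric(ntip)
  for (tip in seq_len(ntip)) {
    node <- tip
    acc <- 0
    while (node != root) {
      e <- parent_edge[node]
      acc <- acc + tree$edge.length[e] / nleaves_below[e]
      node <- tree$edge[e, 1]
    }
    w[tip] <- acc
  }
  if (max(w) <= 0) w <- rep(1, ntip) else w <- w / max(w)
  if (any(w <= 0)) w[w <= 0] <- min(w[w > 0]) * 1e-3  # keep weights positive
  stats::setNames(w, tree$tip.label)
}

# number of leaves below each edge (below its child node)
edge_leaf_counts <- function(tree) {
  ntip <- length(tree$tip.label)
  counts <- integer(max(tree$edge))
  counts[seq_len(ntip)] <- 1L
  ord <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(ord$edge))) {
    counts[ord$edge[e, 1]] <- counts[ord$edge[e, 1]] + counts[ord$edge[e, 2]]
  }
  counts[tree$edge[, 2]]
}

#' Progressive merge schedule from a rooted guide tree
#'
#' Post-order list of the internal nodes: each step names the two leaf
#' groups it merges.  Steps are annotated with their dependency level
#' (leaves are level 0, a step is one above the deeper of its children),
#' and a step is flagged parallel-eligible when its level contains more
#' than one step, i.e. when another merge with a disjoint subtree can run
#' at the same time.  Polytomies are resolved deterministically,
#' smallest leaf id first, before scheduling.
#'
#' @param tree A rooted `phylo` tree.
#' @return Object of class `merge_schedule`: a list of steps, each with
#'   `left`, `right` (character vectors of sequence ids), `level` and
#'   `parallel` flag.  For `n` leaves there are exactly `n - 1` steps.
#' @export
traversal_schedule <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object")
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  steps <- list()
  # returns list(tips, level)
  recurse <- function(node) {
    if (node <= ntip)
      return(list(tips = tree$tip.label[node], level = 0L))
    ch <- kids[[as.character(node)]]
    groups <- lapply(ch, recurse)
    # deterministic order: by smallest leaf id
    ord <- order(vapply(groups, function(g) min(g$tips), ""))
    groups <- groups[ord]
    acc <- groups[[1]]
    for (g in groups[-1]) {
      lvl <- max(acc$level, g$level) + 1L
      steps[[length(steps) + 1L]] <<- list(left = acc$tips, right = g$tips,
                                           level = lvl)
      acc <- list(tips = c(acc$tips, g$tips), level = lvl)
    }
    acc
  }
  recurse(ntip + 1L)
  levels <- vapply(steps, `[[`, 0L, "level")
  tab <- table(levels)
  for (s in seq_along(steps))
    steps[[s]]$parallel <- tab[[as.character(steps[[s]]$level)]] > 1L
  structure(steps, class = "merge_schedule")
}

#' @export
print.merge_schedule <- function(x, ...) {
  cat("Merge schedule:", length(x), "steps\n")
  for (s in seq_along(x)) {
    cat(sprintf("  %2d. [%s] + [%s] (level %d%s)\n", s,
                paste(x[[s]]$left, collapse = ","),
                paste(x[[s]]$right, collapse = ","),
                x[[s]]$level,
                if (x[[s]]$parallel) ", parallel-eligible" else ""))
  }
  invisible(x)
}
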