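# Stage 2: neighbor joining, midpoint rooting, sequence weights and the
# merge schedule.

additive_matrix <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

test_that("two- and three-leaf NJ trees use the closed-form branch lengths", {
  d2 <- matrix(c(0, .4, .4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- nj_build(d2)
  expect_equal(sort(t2$edge.length), c(0.2, 0.2))
  ids <- c("A", "B", "C")
  d3 <- matrix(c(0, .3, .5, .3, 0, .6, .5, .6, 0), 3,
               dimnames = list(ids, ids))
  t3 <- nj_build(d3)
  la <- (d3["A", "B"] + d3["A", "C"] - d3["B", "C"]) / 2
  lb <- (d3["A", "B"] + d3["B", "C"] - d3["A", "C"]) / 2
  lc <- (d3["A", "C"] + d3["B", "C"] - d3["A", "B"]) / 2
  lens <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(unname(lens[ids]), c(la, lb, lc))
})

test_that("NJ recovers the topology of additive matrices", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    true <- ape::rtree(n, rooted = FALSE)
    true$edge.length <- runif(length(true$edge.length), 0.05, 1)
    got <- nj_build(additive_matrix(true))
    expect_equal(phangorn::RF.dist(ape::unroot(got), true), 0)
    # cross-check against an independent NJ implementation
    ref <- ape::nj(additive_matrix(true))
    expect_equal(phangorn::RF.dist(ape::unroot(got), ape::unroot(ref)), 0)
  }
})

test_that("negative NJ branch lengths are clamped, pair path preserved", {
  ids <- letters[1:4]
  # matrix engineered to give one negative branch at the first join
  d <- matrix(c(0, 0.1, 0.45, 0.50,
                0.1, 0, 0.35, 0.40,
                0.45, 0.35, 0, 0.7,
                0.50, 0.40, 0.7, 0), 4, dimnames = list(ids, ids))
  tr <- nj_build(d)
  expect_true(all(tr$edge.length >= 0))
})

test_that("NJ rejects malformed matrices", {
  m <- matrix(c(0, .2, .3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_build(m), "symmetric")
  m2 <- matrix(c(0, -.2, -.2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_build(m2), "non-negative")
})

test_that("midpoint rooting splits the longest leaf-to-leaf path", {
  d2 <- matrix(c(0, .4, .4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  r2 <- midpoint_root(nj_build(d2))
  expect_equal(r2$edge.length, c(0.2, 0.2))
  # chain A -0.1- x -0.5- B (plus a short C): root lands on the x-B branch
  tr <- ape::read.tree(text = "(A:0.1,C:0.05,B:0.5);")
  rooted <- midpoint_root(tr)
  dd <- additive_matrix(rooted)
  expect_equal(dd["A", "B"], 0.6)
  root_children <- rooted$edge[rooted$edge[, 1] == length(rooted$tip.label) + 1L, 2]
  b_tip <- which(rooted$tip.label == "B")
  expect_true(b_tip %in% root_children)  # B sits alone on its side of the root
  b_edge <- which(rooted$edge[, 2] == b_tip)
  expect_equal(rooted$edge.length[b_edge], 0.3)
  # a symmetric tree is unchanged topologically
  sym <- ape::read.tree(text = "((A:0.1,B:0.1):0.2,(C:0.1,D:0.1):0.2);")
  expect_equal(phangorn::RF.dist(midpoint_root(ape::unroot(sym)), sym), 0)
})

test_that("weights follow the shared-branch rule and normalize to max 1", {
  sym <- ape::read.tree(text = "(A:0.3,B:0.3);")
  expect_equal(unname(compute_weights(sym)), c(1, 1))
  star <- ape::read.tree(text = "(A:0.1,B:0.1,C:0.4);")
  w <- compute_weights(star)
  expect_identical(names(which.max(w)), "C")
  expect_equal(unname(w[c("A", "B", "C")]), c(0.25, 0.25, 1))
  # nested tree: hand computation of the branch-sharing sums
  tr <- ape::read.tree(text = "((A:0.2,B:0.4):0.1,C:0.8);")
  w2 <- compute_weights(tr)
  expect_equal(unname(w2[c("A", "B", "C")]),
               c(0.2 + 0.05, 0.4 + 0.05, 0.8) / 0.8)
  # zero-length tree falls back to equal weights of 1
  z <- ape::read.tree(text = "((A:0,B:0):0,C:0);")
  expect_equal(unname(compute_weights(z)), c(1, 1, 1))
})

test_that("weights are invariant under leaf reordering of the matrix", {
  fam <- generate_family(n = 6, length = 80, seed = 17)
  d <- build_distance_matrix(fam)$d
  w1 <- compute_weights(midpoint_root(nj_build(d)))
  perm <- c(4, 2, 6, 1, 5, 3)
  w2 <- compute_weights(midpoint_root(nj_build(d[perm, perm])))
  expect_equal(w2[names(w1)], w1, tolerance = 1e-12)
})

test_that("merge schedule is post-order with n-1 steps and parallel flags", {
  bal <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  sb <- traversal_schedule(bal)
  expect_length(sb, 3L)
  expect_true(sb[[1]]$parallel && sb[[2]]$parallel)
  expect_false(sb[[3]]$parallel)
  # the two level-1 merges touch disjoint leaf sets
  expect_length(intersect(c(sb[[1]]$left, sb[[1]]$right),
                          c(sb[[2]]$left, sb[[2]]$right)), 0L)
  cat4 <- ape::read.tree(text = "(((A:1,B:1):1,C:1):1,D:1);")
  sc <- traversal_schedule(cat4)
  expect_length(sc, 3L)
  expect_false(any(vapply(sc, `[[`, NA, "parallel")))
  # every prefix of the schedule merges children before parents
  seen <- list()
  for (st in sc) {
    for (grp in list(st$left, st$right)) {
      if (length(grp) > 1L)
        expect_true(any(vapply(seen, function(s)
          setequal(s, grp), NA)))
    }
    seen[[length(seen) + 1L]] <- c(st$left, st$right)
  }
  d2 <- matrix(c(0, .4, .4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_length(traversal_schedule(midpoint_root(nj_build(d2))), 1L)
})

test_that("polytomies are resolved deterministically before scheduling", {
  poly <- ape::read.tree(text = "(D:1,B:1,A:1,C:1);")
  s <- traversal_schedule(poly)
  expect_length(s, 3L)
  # smallest-id-first folding: A+B, then +C, then +D
  expect_identical(sort(c(s[[1]]$left, s[[1]]$right)), c("A", "B"))
  expect_identical(s[[2]]$right, "C")
  expect_identical(s[[3]]$right, "D")
})
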