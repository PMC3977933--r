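# Stage 3 primitives: profile structure, column scores, profile-profile
# alignment.

single_profile <- function(seq, id, scheme, w = 1) {
  build_profile(msa(stats::setNames(seq, id), alphabet = scheme$alphabet),
                stats::setNames(w, id), scheme)
}

test_that("profiles always have 35 rows and the group's column count", {
  s <- scoring_scheme("dna")
  p <- single_profile("ACGT", "x", s)
  expect_identical(dim(p$mat), c(35L, 4L))
  sp <- scoring_scheme("protein")
  pp <- single_profile("MKLVW", "y", sp)
  expect_identical(nrow(pp$mat), 35L)
  fam <- generate_family(n = 5, length = 60, seed = 23)
  fit <- align_sequences(fam)
  pg <- build_profile(fit$msa, fit$weights, scoring_scheme("dna"))
  expect_identical(dim(pg$mat), c(35L, msa_ncol(fit$msa)))
})

test_that("a single-sequence column expands to its substitution-matrix row", {
  s <- scoring_scheme("dna", match = 5, mismatch = -4)
  p <- single_profile("ACGT", "x", s)
  ncat <- s$ncat
  expect_equal(p$mat[seq_len(ncat), 1], unname(s$matrix[, "A"]))
  expect_equal(p$mat[seq_len(ncat), 3], unname(s$matrix[, "G"]))
  # rows beyond the category count stay zero
  expect_true(all(p$mat[(ncat + 1):33, ] == 0))
  # base gap penalties for an ungapped column
  expect_equal(p$mat[34, ], rep(s$gap_open, 4))
  expect_equal(p$mat[35, ], rep(s$gap_extend, 4))
})

test_that("all-gap columns are zero and gappy columns reduce penalties", {
  s <- scoring_scheme("dna")
  g <- msa(c(a = "A-C", b = "A-C"), alphabet = "dna")
  p <- build_profile(g, c(a = 1, b = 1), s)
  expect_true(all(p$mat[1:33, 2] == 0))
  expect_equal(p$mat[34, 2], s$gap_open * (1 - 0.7))
  half <- build_profile(msa(c(a = "AC", b = "A-"), alphabet = "dna"),
                        c(a = 1, b = 1), s)
  expect_equal(half$mat[34, 2], s$gap_open * (1 - 0.35))
})

test_that("missing member weights are rejected", {
  s <- scoring_scheme("dna")
  g <- msa(c(a = "AC", b = "AC"), alphabet = "dna")
  expect_error(build_profile(g, c(a = 1), s), "weight missing.*b")
})

test_that("prfscore reduces to substitution scores and is symmetric", {
  s <- scoring_scheme("protein")
  p1 <- single_profile("MKLVW", "x", s)
  p2 <- single_profile("WAKEM", "y", s)
  for (i in 1:5) for (j in 1:5) {
    expect_equal(prfscore(p1, p2, i, j),
                 unname(s$matrix[substr("MKLVW", i, i), substr("WAKEM", j, j)]))
  }
  # symmetry on weighted multi-sequence profiles
  fam <- generate_family(n = 6, length = 40, seed = 29)
  fit <- align_sequences(fam)
  grp1 <- msa(fit$msa$seq[1:3], ids = fit$msa$ids[1:3], alphabet = "dna")
  grp2 <- msa(fit$msa$seq[4:6], ids = fit$msa$ids[4:6], alphabet = "dna")
  sch <- scoring_scheme("dna")
  q1 <- build_profile(grp1, fit$weights, sch)
  q2 <- build_profile(grp2, fit$weights, sch)
  set.seed(1)
  for (t in 1:100) {
    i <- sample(q1$m, 1); j <- sample(q2$m, 1)
    expect_equal(prfscore(q1, q2, i, j), prfscore(q2, q1, j, i))
  }
  # an all-gap column scores zero against anything
  gp <- build_profile(msa(c(a = "A-", b = "A-"), alphabet = "dna"),
                      c(a = 1, b = 1), sch)
  expect_identical(prfscore(gp, q2, 2, 1), 0)
  expect_error(prfscore(q1, q2, 0, 1), "out of range")
})

test_that("two single-sequence profiles align exactly like global Gotoh", {
  set.seed(41)
  s <- scoring_scheme("dna", match = 1, mismatch = -1,
                      gap_open = 4, gap_extend = 1)
  for (rep in 1:8) {
    sa <- random_dna(sample(10:50, 1)); sb <- random_dna(sample(10:50, 1))
    p1 <- single_profile(sa, "a", s); p2 <- single_profile(sb, "b", s)
    got <- profile_align(p1, p2, k = 3)
    ref <- oracle_align(sa, sb, s, local = FALSE)
    expect_equal(got$score, ref$score)
    expect_identical(unname(got$msa$seq[1]), ref$aligned_a)
    expect_identical(unname(got$msa$seq[2]), ref$aligned_b)
  }
})

test_that("aligning a profile with a copy of itself adds no gap columns", {
  fam <- generate_family(n = 4, length = 80, seed = 47)
  fit <- align_sequences(fam)
  s <- scoring_scheme("dna")
  p <- build_profile(fit$msa, fit$weights, s)
  p2 <- build_profile(msa(stats::setNames(fit$msa$seq, paste0(fit$msa$ids, "_2")),
                          alphabet = "dna"),
                      stats::setNames(fit$weights, paste0(fit$msa$ids, "_2")), s)
  merged <- profile_align(p, p2, k = 2)
  expect_identical(msa_ncol(merged$msa), msa_ncol(fit$msa))
  expect_identical(unname(merged$msa$seq[1]), unname(fit$msa$seq[1]))
})

test_that("fragment policy changes data movement only, never the result", {
  fam <- generate_family(n = 6, length = 100, seed = 53)
  d <- build_distance_matrix(fam)$d
  tree <- midpoint_root(nj_build(d))
  on_ <- progressive_align(fam, tree, fragment = TRUE, k = 4)
  off <- progressive_align(fam, tree, fragment = FALSE, k = 4)
  expect_identical(on_$seq, off$seq)
})

test_that("merge scores equal independent column-wise rescoring", {
  set.seed(59)
  s <- scoring_scheme("dna")
  fam <- generate_family(n = 4, length = 120, seed = 61)
  fit <- align_sequences(fam)
  g1 <- msa(fit$msa$seq[1:2], ids = fit$msa$ids[1:2], alphabet = "dna")
  g2 <- msa(fit$msa$seq[3:4], ids = fit$msa$ids[3:4], alphabet = "dna")
  p1 <- build_profile(g1, fit$weights, s)
  p2 <- build_profile(g2, fit$weights, s)
  for (k in c(1L, 3L)) {
    res <- profile_align(p1, p2, k = k)
    expect_equal(rescore_merge(p1, p2, res$pos_a, res$pos_b), res$score)
  }
})
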