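# Blocked-engine core: partitioning, k selection, equivalence with the
# full-matrix oracle, cross-k invariance, and the grid-cache codecs.

test_that("block partitioning balances sizes with longer blocks first", {
  g <- partition_blocks(10, 10, 2)
  expect_identical(g$row_cuts, c(0L, 5L, 10L))
  expect_identical(g$col_cuts, c(0L, 5L, 10L))
  g1 <- partition_blocks(10, 10, 1)
  expect_identical(g1$row_cuts, c(0L, 10L))
  g2 <- partition_blocks(7, 5, 3)
  expect_identical(diff(g2$row_cuts), c(3L, 2L, 2L))
  expect_identical(diff(g2$col_cuts), c(2L, 2L, 1L))
  expect_error(partition_blocks(7, 5, 6), "k must be")
})

test_that("k selection interpolates calibration tables and clamps", {
  tab <- data.frame(length = c(100, 200), k = c(4, 8))
  expect_identical(select_k(150, 150, tab), 6L)
  expect_identical(select_k(100, 100, tab), 4L)
  expect_identical(select_k(1000, 1000, tab), 8L)   # clamped to last point
  expect_identical(select_k(50, 50, data.frame(length = 100, k = 4)), 4L)
  expect_identical(select_k(3, 3, data.frame(length = 100, k = 8)), 3L)
  expect_identical(select_k(64, 64), 1L)            # portable default
  expect_true(select_k(2000, 2000) > 1L)
})

test_that("global blocked DP equals the oracle for every k and both alphabets", {
  set.seed(101)
  schemes <- list(scoring_scheme("dna", match = 1, mismatch = -1,
                                 gap_open = 4, gap_extend = 1),
                  scoring_scheme("protein"))
  for (rep in 1:12) {
    scheme <- schemes[[rep %% 2 + 1]]
    rnd <- if (scheme$alphabet == "dna") random_dna else random_protein
    sa <- rnd(sample(5:60, 1)); sb <- rnd(sample(5:60, 1))
    ref <- oracle_align(sa, sb, scheme, local = FALSE)
    for (k in c(1L, 2L, 3L, 5L)) {
      got <- global_affine_align(sa, sb, scheme,
                                 k = min(k, nchar(sa), nchar(sb)))
      expect_equal(got$score, ref$score, info = paste("k =", k))
      expect_identical(got$aligned_a, ref$aligned_a, info = paste("k =", k))
      expect_identical(got$aligned_b, ref$aligned_b, info = paste("k =", k))
    }
  }
})

test_that("local blocked DP equals the oracle, including the empty case", {
  set.seed(202)
  scheme <- scoring_scheme("dna", match = 2, mismatch = -3,
                           gap_open = 5, gap_extend = 2)
  for (rep in 1:12) {
    sa <- random_dna(sample(5:60, 1)); sb <- random_dna(sample(5:60, 1))
    ref <- oracle_align(sa, sb, scheme, local = TRUE)
    for (k in c(1L, 2L, 5L)) {
      got <- local_affine_align(sa, sb, scheme,
                                k = min(k, nchar(sa), nchar(sb)))
      expect_equal(got$score, ref$score)
      expect_identical(got$aligned_a, ref$aligned_a)
      expect_identical(got$aligned_b, ref$aligned_b)
    }
  }
  none <- local_affine_align("AAAA", "GGGG",
                             scoring_scheme("dna", match = 1, mismatch = -1,
                                            gap_open = 2, gap_extend = 0.5))
  expect_identical(none$score, 0)
  expect_identical(none$aligned_a, "")
})

test_that("global self-alignment is gapless and score equals rescoring", {
  set.seed(7)
  scheme <- scoring_scheme("dna", match = 1, mismatch = -1,
                           gap_open = 4, gap_extend = 1)
  x <- random_dna(40)
  got <- global_affine_align(x, x, scheme, k = 4)
  expect_identical(got$aligned_a, x)
  expect_identical(got$aligned_b, x)
  # column-wise rescoring oracle on a diverged pair
  y <- random_dna(55)
  g <- global_affine_align(x, y, scheme, k = 3)
  ca <- gridalign:::alpha_encode(x, "dna"); cb <- gridalign:::alpha_encode(y, "dna")
  sub <- round(100 * scheme$matrix)
  expect_equal(rescore_pair_path(g$pos_a, g$pos_b, ca, cb, sub, 400, 100) / 100,
               g$score)
})

test_that("forward fill is invariant to the block execution order", {
  set.seed(33)
  scheme <- scoring_scheme("dna", match = 1, mismatch = -1,
                           gap_open = 4, gap_extend = 1)
  ca <- gridalign:::alpha_encode(random_dna(60), "dna")
  cb <- gridalign:::alpha_encode(random_dna(80), "dna")
  input <- gridalign:::seq_scorer_input(ca, cb, scheme)
  k <- 4L
  grid <- partition_blocks(length(ca), length(cb), k)
  base <- gridalign:::forward_fill(input, grid, "global", workers = 1L)
  for (w in c(2L, 4L, 8L)) {
    alt <- gridalign:::forward_fill(input, grid, "global", workers = w)
    expect_identical(serialize_grid_cache(alt), serialize_grid_cache(base))
  }
  # an order violating the wave-front dependency is rejected
  bad <- wavefront_order(k, 1L)[rev(seq_len(k * k)), ]
  expect_error(gridalign:::forward_fill(input, grid, "global", order = bad),
               "wave-front dependency")
})

test_that("cell codecs have the stated sizes and round-trip exactly", {
  expect_length(encode_cell(list(h = 0, e = 0, f = 0), "absolute12"), 12L)
  expect_length(encode_cell(list(h = 1000, e = 990, f = 995), "relative6"), 6L)
  expect_identical(decode_cell(encode_cell(list(h = 1000, e = 990, f = 995),
                                           "relative6"), "relative6"),
                   list(h = 1000L, e = 990L, f = 995L))
  expect_error(encode_cell(list(h = 1000, e = 800, f = 1000), "relative6"),
               "overflow")
  set.seed(99)
  n <- 10000
  h <- sample(-2e6:2e6, n, replace = TRUE)
  e <- h + sample(-127:127, n, replace = TRUE)
  f <- h + sample(-127:127, n, replace = TRUE)
  for (codec in c("absolute12", "relative6")) {
    enc <- gridalign:::encode_cells(h, e, f, codec)
    expect_length(enc, n * if (codec == "absolute12") 12L else 6L)
    dec <- gridalign:::decode_cells(enc, codec)
    expect_identical(dec$h, as.integer(h))
    expect_identical(dec$e, as.integer(e))
    expect_identical(dec$f, as.integer(f))
  }
  # absolute codec also covers values far outside the relative range
  big <- c(-536870912L, 0L, 2147480000L %/% 4L)
  dec <- gridalign:::decode_cells(gridalign:::encode_cells(big, rev(big), big,
                                                           "absolute12"),
                                  "absolute12")
  expect_identical(dec$h, big)
})

test_that("grid-cache streams restore losslessly and stay boundary-sized", {
  set.seed(55)
  scheme <- scoring_scheme("dna")
  ca <- gridalign:::alpha_encode(random_dna(70), "dna")
  cb <- gridalign:::alpha_encode(random_dna(50), "dna")
  input <- gridalign:::seq_scorer_input(ca, cb, scheme)
  k <- 5L
  grid <- partition_blocks(length(ca), length(cb), k)
  cache <- gridalign:::forward_fill(input, grid, "local")
  stream <- serialize_grid_cache(cache)
  back <- deserialize_grid_cache(stream)
  expect_identical(back[names(back)], cache[names(cache)])
  # cache stores only boundary cells: <= (k+1) * (len_a + len_b + 2)
  ncells <- (length(stream) - 40) / 12
  expect_lte(ncells, (k + 1) * (length(ca) + length(cb) + 2))
  # traceback from the restored cache matches the direct one
  p1 <- gridalign:::traceback_path(input, cache)
  p2 <- gridalign:::traceback_path(input, back)
  expect_identical(p1, p2)
  expect_error(deserialize_grid_cache(stream[1:30]), "grid-cache")
})

test_that("cache/input mismatch is detected", {
  scheme <- scoring_scheme("dna")
  ca <- gridalign:::alpha_encode("ACGTACGT", "dna")
  cb <- gridalign:::alpha_encode("ACGTAC", "dna")
  input <- gridalign:::seq_scorer_input(ca, cb, scheme)
  grid <- partition_blocks(8, 6, 2)
  cache <- gridalign:::forward_fill(input, grid, "global")
  other <- gridalign:::seq_scorer_input(ca[1:5], cb, scheme)
  expect_error(gridalign:::traceback_path(other, cache), "does not match")
})
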