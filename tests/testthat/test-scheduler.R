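# Geometry layout policy, job ledger conservation and the wave-front
# worker model.

test_that("the 60-worker pool uses the published layout rules", {
  # default: four forward 7x2 geometries plus two backward 2x1
  lay <- select_geometry_layout(45, 60)
  fwd <- Filter(function(g) g$cls == "forward", lay$geometries)
  bwd <- Filter(function(g) g$cls == "backward", lay$geometries)
  expect_length(fwd, 4L)
  expect_length(bwd, 2L)
  expect_true(all(vapply(fwd, function(g) g$rows == 7 && g$cols == 2, NA)))
  expect_true(all(vapply(bwd, function(g) g$rows == 2 && g$cols == 1, NA)))
  # forward:backward worker split is 56:4 -- the forward stage dominates
  expect_identical(gridalign:::layout_class_workers(lay, "forward"), 56L)
  expect_identical(gridalign:::layout_class_workers(lay, "backward"), 4L)
  # 5..8 pending jobs: eight 7x1 forward geometries, no idle second batch
  for (nj in c(5, 6, 8)) {
    sp <- select_geometry_layout(nj, 60)
    fwd <- Filter(function(g) g$cls == "forward", sp$geometries)
    expect_length(fwd, 8L)
    expect_true(all(vapply(fwd, function(g) g$rows == 7 && g$cols == 1, NA)))
  }
  expect_length(Filter(function(g) g$cls == "forward",
                       select_geometry_layout(4, 60)$geometries), 4L)
})

test_that("layouts never oversubscribe the pool and scale down", {
  for (pool in c(2, 5, 10, 24, 59, 60, 64)) {
    for (nj in c(1, 6, 45)) {
      lay <- select_geometry_layout(nj, pool)
      used <- sum(vapply(lay$geometries, `[[`, 0L, "worker_count"))
      expect_lte(used, max(pool, 60))
      expect_true(all(vapply(lay$geometries,
                             function(g) g$worker_count >= 2, NA)))
    }
  }
  # minimum configuration: controller plus one worker
  tiny <- select_geometry_layout(1, 2)
  expect_length(tiny$geometries, 1L)
  expect_identical(tiny$geometries[[1]]$cls, "forward")
  expect_identical(tiny$geometries[[1]]$worker_count, 2L)
  expect_error(select_geometry_layout(1, 1), "pool too small")
  expect_error(geometry(1, 1), "at least two")
})

test_that("the job ledger conserves jobs and logs both phases", {
  fam <- generate_family(n = 6, length = 50, seed = 97)
  res <- build_distance_matrix(fam, layout = select_geometry_layout(15, 60))
  expect_length(res$ledger$done, 15L)
  expect_length(res$ledger$pending, 0L)
  expect_length(res$ledger$running, 0L)
  expect_false(anyDuplicated(res$ledger$done) > 0)
  phases <- vapply(res$log, `[[`, "", "phase")
  jobs <- vapply(res$log, `[[`, "", "job")
  # each job passes through exactly one forward and one backward dispatch
  for (j in unique(jobs)) {
    expect_identical(sum(jobs == j & phases == "forward" &
                           vapply(res$log, `[[`, "", "event") == "start"), 1L)
    expect_identical(sum(jobs == j & phases == "backward" &
                           vapply(res$log, `[[`, "", "event") == "start"), 1L)
  }
  # forward jobs land on forward geometries
  geoms <- vapply(res$log, `[[`, 0L, "geometry")
  cls <- vapply(res$layout$geometries, `[[`, "", "cls")
  expect_true(all(cls[geoms[phases == "forward"]] == "forward"))
  expect_true(all(cls[geoms[phases == "backward"]] == "backward"))
})

test_that("wave-front anti-diagonal widths follow min(d+1, k, 2k-1-d)", {
  expect_identical(wavefront_widths(1), 1L)
  expect_identical(wavefront_widths(3), c(1L, 2L, 3L, 2L, 1L))
  expect_identical(wavefront_widths(5), c(1L, 2L, 3L, 4L, 5L, 4L, 3L, 2L, 1L))
  expect_identical(sum(wavefront_widths(7)), 49L)
})

test_that("block orders are topological for any worker count", {
  for (k in c(1L, 3L, 5L)) {
    for (w in c(1L, 2L, 4L, 16L)) {
      ord <- wavefront_order(k, w)
      expect_identical(nrow(ord), k * k)
      seen <- matrix(FALSE, k, k)
      for (t in seq_len(nrow(ord))) {
        bi <- ord[t, 1] + 1L; bj <- ord[t, 2] + 1L
        expect_false(seen[bi, bj])
        if (bi > 1L) expect_true(seen[bi - 1L, bj])
        if (bj > 1L) expect_true(seen[bi, bj - 1L])
        seen[bi, bj] <- TRUE
      }
    }
  }
  # one worker walks the grid in serial row-major order
  expect_identical(wavefront_order(2, 1),
                   cbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L)))
})

test_that("grid caches are byte-identical across worker counts", {
  set.seed(107)
  scheme <- scoring_scheme("dna")
  ca <- gridalign:::alpha_encode(random_dna(90), "dna")
  cb <- gridalign:::alpha_encode(random_dna(70), "dna")
  input <- gridalign:::seq_scorer_input(ca, cb, scheme)
  grid <- partition_blocks(90, 70, 6)
  base <- serialize_grid_cache(gridalign:::run_wavefront(input, grid, "global", 1L))
  for (w in c(2L, 8L))
    expect_identical(serialize_grid_cache(
      gridalign:::run_wavefront(input, grid, "global", w)), base)
})

test_that("a failing job is retried once and then aborts with its id", {
  calls <- 0L
  layout <- serial_layout()
  jobs <- list(bad = list(input = structure(list(), class = "boom"),
                          grid = partition_blocks(4, 4, 1), mode = "global"))
  # malformed input fails in the engine both times
  expect_error(gridalign:::run_pairwise_stage(jobs, layout), "'bad' failed")
})
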