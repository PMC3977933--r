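# Two-level scheduling model: a fixed worker pool is partitioned into
# rectangular forward (F) and backward (B) geometries; an overseer
# distributes pairwise jobs across geometries, and inside one geometry the
# DP blocks of a single alignment run in wave-front order.  Geometries are
# modelled as named sub-pools with a capacity (one worker of each acts as
# its controller); the contract is capacity plus mutual exclusivity, and
# every user-visible result is independent of the layout.

#' Create a rectangular worker geometry
#'
#' @param rows,cols Shape of the geometry; `rows * cols` workers, one of
#'   which is the controller, so a runnable geometry has at least two.
#' @param class `"forward"` (computes the full DP matrix) or `"backward"`
#'   (runs the decoupled traceback with a single working tile).
#' @return An object of class `geometry`.
#' @export
geometry <- function(rows, cols, class = c("forward", "backward")) {
  class <- match.arg(class)
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1L || cols < 1L) stop("geometry shape must be positive")
  if (rows * cols < 2L)
    stop("a runnable geometry needs at least two workers (one is the controller)")
  structure(list(rows = rows, cols = cols, cls = class,
                 worker_count = rows * cols),
            class = "geometry")
}

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf("%s geometry %dx%d (%d workers)\n",
              x$cls, x$rows, x$cols, x$worker_count))
  invisible(x)
}

#' Choose a geometry layout for a batch of pairwise jobs
#'
#' On the reference 60-worker pool the layout follows two empirical rules:
#' the default is four forward geometries of 7x2 workers plus two backward
#' geometries of 2x1 (a 56:4 split reflecting that the forward stage
#' dominates the cost), and when between five and eight jobs are pending
#' eight 7x1 forward geometries are used instead so no geometry sits idle
#' on a second batch; backward work then reuses freed forward geometries.
#' Smaller pools scale the same pattern down proportionally.
#'
#' @param n_jobs Number of pending pairwise jobs (>= 1).
#' @param pool_size Workers available for geometries (default 60).
#' @param reserved Workers set aside for pool management (default 4; not
#'   part of `pool_size`).
#' @return An object of class `geometry_layout` with fields `pool_size`,
#'   `reserved` and `geometries`.
#' @examples
#' select_geometry_layout(45, 60)
#' select_geometry_layout(6, 60)
#' @export
select_geometry_layout <- function(n_jobs, pool_size = 60L, reserved = 4L) {
  n_jobs <- as.integer(n_jobs); pool_size <- as.integer(pool_size)
  if (n_jobs < 1L) stop("n_jobs must be at least 1")
  if (pool_size < 2L) stop("pool too small: no runnable geometry fits")
  special <- n_jobs >= 5L && n_jobs <= 8L
  if (pool_size >= 60L) {
    geoms <- if (special) {
      replicate(8L, geometry(7L, 1L, "forward"), simplify = FALSE)
    } else {
      c(replicate(4L, geometry(7L, 2L, "forward"), simplify = FALSE),
        replicate(2L, geometry(2L, 1L, "backward"), simplify = FALSE))
    }
  } else {
    # proportional scale-down: keep ~14/15 of the pool in forward geometries
    fw <- max(2L, as.integer(floor(pool_size * 14 / 15)))
    nf <- if (special) min(8L, max(1L, fw %/% 2L)) else min(4L, max(1L, fw %/% 2L))
    per <- max(2L, fw %/% nf)
    nf <- min(nf, pool_size %/% per)
    shape <- if (per %% 2L == 0L && per > 2L) c(per %/% 2L, 2L) else c(per, 1L)
    geoms <- replicate(nf, geometry(shape[1], shape[2], "forward"),
                       simplify = FALSE)
    nb <- (pool_size - nf * per) %/% 2L
    if (!special && nb > 0L)
      geoms <- c(geoms,
                 replicate(nb, geometry(2L, 1L, "backward"), simplify = FALSE))
  }
  used <- sum(vapply(geoms, `[[`, 0L, "worker_count"))
  stopifnot(used <= pool_size)
  structure(list(pool_size = pool_size, reserved = as.integer(reserved),
                 geometries = geoms),
            class = "geometry_layout")
}

#' @export
print.geometry_layout <- function(x, ...) {
  cat("Geometry layout over", x$pool_size, "workers (",
      x$reserved, "reserved for management ):\n")
  for (g in x$geometries) print(g)
  invisible(x)
}

layout_class_count <- function(layout, cls) {
  sum(vapply(layout$geometries, function(g) g$cls == cls, NA))
}

layout_class_workers <- function(layout, cls) {
  sum(vapply(layout$geometries,
             function(g) if (g$cls == cls) g$worker_count else 0L, 0L))
}

#' A serial fallback layout: one minimal forward geometry
#' @param pool_size Workers available.
#' @return A `geometry_layout` with a single 2x1 forward geometry.
#' @export
serial_layout <- function(pool_size = 2L) {
  structure(list(pool_size = as.integer(pool_size), reserved = 0L,
                 geometries = list(geometry(2L, 1L, "forward"))),
            class = "geometry_layout")
}

# --- job ledger ------------------------------------------------------------

#' Create a job ledger
#'
#' Tracks the pending / running / done state of every job plus a dispatch
#' log of (job, phase, geometry) events.  Every job must end in the done
#' set exactly once, and each forward job's grid cache is consumed by
#' exactly one backward job.
#'
#' @param job_ids Character vector of job identifiers.
#' @return An environment of class `job_ledger`.
#' @export
new_job_ledger <- function(job_ids) {
  if (anyDuplicated(job_ids)) stop("duplicate job ids")
  env <- new.env(parent = emptyenv())
  env$pending <- as.character(job_ids)
  env$running <- character()
  env$done <- character()
  env$log <- list()
  class(env) <- "job_ledger"
  env
}

ledger_start <- function(ledger, job, phase, geometry_id) {
  if (!(job %in% ledger$pending) && phase == "forward")
    stop("job '", job, "' is not pending")
  ledger$pending <- setdiff(ledger$pending, job)
  ledger$running <- union(ledger$running, job)
  ledger$log[[length(ledger$log) + 1L]] <-
    list(job = job, phase = phase, geometry = geometry_id, event = "start")
  invisible(ledger)
}

ledger_finish <- function(ledger, job, phase, geometry_id) {
  ledger$log[[length(ledger$log) + 1L]] <-
    list(job = job, phase = phase, geometry = geometry_id, event = "finish")
  if (phase == "backward") {
    if (job %in% ledger$done) stop("job '", job, "' finished twice")
    ledger$running <- setdiff(ledger$running, job)
    ledger$done <- c(ledger$done, job)
  }
  invisible(ledger)
}

#' @export
print.job_ledger <- function(x, ...) {
  cat("Job ledger:", length(x$pending), "pending,", length(x$running),
      "running,", length(x$done), "done\n")
  invisible(x)
}

# --- wave-front block ordering --------------------------------------------

#' Block execution order for one blocked alignment
#'
#' Models a geometry of `workers` workers executing the k x k block grid:
#' block `(bi, bj)` becomes runnable once `(bi-1, bj)` and `(bi, bj-1)`
#' are done, so runnable blocks lie on one anti-diagonal front.  With one
#' worker the serial row-major order is used; with more, each tick takes
#' up to `workers` runnable blocks in `(bi, bj)` order.  Every order this
#' produces is a legal topological order and yields bit-identical engine
#' results.
#'
#' @param k Blocks per axis.
#' @param workers Worker count (>= 1).
#' @return Integer matrix (k^2 x 2) of 0-based block indices.
#' @export
wavefront_order <- function(k, workers = 1L) {
  k <- as.integer(k); workers <- as.integer(workers)
  if (workers < 1L) stop("workers must be >= 1")
  if (workers == 1L) {
    return(cbind(rep(0:(k - 1L), each = k), rep(0:(k - 1L), times = k)))
  }
  done <- matrix(FALSE, k, k)
  out <- matrix(0L, 0L, 2L)
  while (!all(done)) {
    ready <- which(!done &
                     rbind(TRUE, done[-k, , drop = FALSE]) &
                     cbind(TRUE, done[, -k, drop = FALSE]), arr.ind = TRUE)
    ready <- ready[order(ready[, 1], ready[, 2]), , drop = FALSE]
    take <- ready[seq_len(min(workers, nrow(ready))), , drop = FALSE]
    out <- rbind(out, take - 1L)
    done[take] <- TRUE
  }
  dimnames(out) <- NULL
  out
}

#' Number of runnable blocks on each anti-diagonal
#'
#' For a k x k grid, anti-diagonal `d` (0-based) holds
#' `min(d + 1, k, 2k - 1 - d)` blocks, the quantity that bounds how many
#' workers a wave-front can keep busy.
#'
#' @param k Blocks per axis.
#' @return Integer vector of length `2k - 1`.
#' @export
wavefront_widths <- function(k) {
  k <- as.integer(k)
  d <- 0:(2L * k - 2L)
  pmin(d + 1L, k, 2L * k - 1L - d)
}

# --- pairwise stage execution ---------------------------------------------

#' Run a batch of pairwise alignment jobs through a geometry layout
#'
#' Each job's forward stage is dispatched to a forward geometry
#' (round-robin), its grid cache is serialized to the byte-stream handoff
#' format, and the backward stage deserializes it on a backward geometry
#' (or on a freed forward geometry when the layout has none).  A failing
#' job is retried once before aborting.  Results are bit-identical to
#' serial execution for every layout.
#'
#' @param jobs Named list of jobs, each a list with fields `input` (scorer
#'   input), `grid` and `mode`.
#' @param layout A `geometry_layout`.
#' @return List with `results` (per job: the grid cache and traceback
#'   path), `ledger` and the dispatch `log`.
#' @keywords internal
run_pairwise_stage <- function(jobs, layout = serial_layout()) {
  fgeoms <- which(vapply(layout$geometries, function(g) g$cls == "forward", NA))
  bgeoms <- which(vapply(layout$geometries, function(g) g$cls == "backward", NA))
  if (!length(fgeoms)) stop("layout has no forward geometry")
  if (!length(bgeoms)) bgeoms <- fgeoms  # backward reuses freed forward geometries
  ledger <- new_job_ledger(names(jobs))
  results <- vector("list", length(jobs))
  names(results) <- names(jobs)
  run_once <- function(job, fg, bg, id) {
    g <- layout$geometries[[fg]]
    ledger_start(ledger, id, "forward", fg)
    cache <- forward_fill(job$input, job$grid, job$mode,
                          workers = g$worker_count - 1L)
    stream <- serialize_grid_cache(cache)
    ledger_finish(ledger, id, "forward", fg)
    ledger_start(ledger, id, "backward", bg)
    cache2 <- deserialize_grid_cache(stream)
    path <- if (cache2$mode == "local" && cache2$best <= 0L) {
      list(pos_a = integer(), pos_b = integer(),
           origin_i = 0L, origin_j = 0L)
    } else {
      traceback_path(job$input, cache2)
    }
    ledger_finish(ledger, id, "backward", bg)
    list(cache = cache2, path = path)
  }
  for (idx in seq_along(jobs)) {
    id <- names(jobs)[idx]
    fg <- fgeoms[(idx - 1L) %% length(fgeoms) + 1L]
    bg <- bgeoms[(idx - 1L) %% length(bgeoms) + 1L]
    results[[idx]] <- tryCatch(
      run_once(jobs[[idx]], fg, bg, id),
      error = function(e) {
        # one retry, then abort with the job identity
        ledger$pending <- union(ledger$pending, id)
        ledger$running <- setdiff(ledger$running, id)
        tryCatch(run_once(jobs[[idx]], fg, bg, id),
                 error = function(e2)
                   stop("pairwise job '", id, "' failed: ",
                        conditionMessage(e2), call. = FALSE))
      })
  }
  list(results = results, ledger = ledger, log = ledger$log)
}

#' Run one blocked DP task with a wave-front worker model
#'
#' @param input Scorer input list.
#' @param grid Block grid from [partition_blocks()].
#' @param mode `"global"` or `"local"`.
#' @param workers Workers available inside the geometry.
#' @return A `grid_cache`; identical for every worker count.
#' @keywords internal
run_wavefront <- function(input, grid, mode = "global", workers = 1L) {
  forward_fill(input, grid, mode, workers = workers)
}
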