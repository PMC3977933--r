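# R surface of the blocked dynamic-programming engine: block partitioning,
# k selection, forward fill / traceback wrappers, and the grid-cache cell
# codecs with their byte-stream persistence format.

#' Engine parameters for blocked alignment
#'
#' @param k Blocks per axis (`NULL` selects one with [select_k()]).
#' @param mode `"global"` or `"local"`.
#' @param cell_codec `"absolute12"` (three signed 32-bit values, 12 bytes
#'   per cell) or `"relative6"` (32-bit main value plus two signed 8-bit
#'   differences, 6 bytes per cell, valid while both differences stay
#'   below 128 in magnitude).
#' @return An object of class `fastlsa_params`.
#' @export
fastlsa_params <- function(k = NULL, mode = c("global", "local"),
                           cell_codec = c("absolute12", "relative6")) {
  mode <- match.arg(mode)
  cell_codec <- match.arg(cell_codec)
  if (!is.null(k)) {
    k <- as.integer(k)
    if (length(k) != 1L || is.na(k) || k < 1L) stop("k must be a positive integer")
  }
  structure(list(k = k, mode = mode, cell_codec = cell_codec),
            class = "fastlsa_params")
}

#' Partition a DP matrix into a k x k block grid
#'
#' Rows `[0, len_a)` and columns `[0, len_b)` are split into `k` contiguous
#' half-open ranges per axis whose sizes differ by at most one; longer
#' ranges come first.
#'
#' @param len_a,len_b Sequence (or profile) lengths, both at least 1.
#' @param k Blocks per axis, `1 <= k <= min(len_a, len_b)`; `k = 1` is
#'   plain full-matrix DP.
#' @return List with `row_cuts` and `col_cuts`, integer vectors of k+1
#'   boundaries from 0 to the axis length.
#' @examples
#' partition_blocks(7, 5, 3)
#' @export
partition_blocks <- function(len_a, len_b, k) {
  len_a <- as.integer(len_a); len_b <- as.integer(len_b); k <- as.integer(k)
  if (len_a < 1L || len_b < 1L) stop("lengths must be at least 1")
  if (k < 1L || k > min(len_a, len_b))
    stop("k must be in [1, min(len_a, len_b)]")
  cuts <- function(len) {
    base <- len %/% k; rem <- len %% k
    sizes <- c(rep(base + 1L, rem), rep(base, k - rem))
    cumsum(c(0L, sizes))
  }
  list(row_cuts = cuts(len_a), col_cuts = cuts(len_b))
}

#' Choose a block count from a calibration table
#'
#' Optimal block counts are hardware-dependent, so they are supplied as
#' calibration points `(length, k)` and interpolated piecewise-linearly on
#' `max(len_a, len_b)`, rounded to the nearest integer and clamped to
#' `[1, min(len_a, len_b)]`.  Without a table a portable default
#' `ceiling(sqrt(max_len / 64))`, clamped to `[1, 16]`, is used.
#'
#' @param len_a,len_b Input lengths.
#' @param table Optional data frame or matrix with columns `length` and
#'   `k`, sorted by length.
#' @return Integer block count.
#' @examples
#' select_k(150, 150, data.frame(length = c(100, 200), k = c(4, 8)))
#' @export
select_k <- function(len_a, len_b, table = NULL) {
  maxlen <- max(len_a, len_b)
  if (is.null(table)) {
    k <- ceiling(sqrt(maxlen / 64))
    k <- min(max(k, 1), 16)
  } else {
    table <- as.data.frame(table)
    if (!all(c("length", "k") %in% names(table)) || nrow(table) < 1L)
      stop("calibration table needs columns 'length' and 'k'")
    if (nrow(table) == 1L) {
      k <- table$k[1]
    } else {
      k <- stats::approx(table$length, table$k, xout = maxlen, rule = 2)$y
    }
    k <- round(k)
  }
  as.integer(min(max(k, 1), min(len_a, len_b)))
}

# --- engine invocation -----------------------------------------------------

# Build the scorer input list for sequence mode.  Scores are scaled to
# integers (x 100) so all DP arithmetic is exact.
seq_scorer_input <- function(a_codes, b_codes, scheme) {
  list(mode = "seq",
       a = as.integer(a_codes), b = as.integer(b_codes),
       sub = matrix(as.integer(round(SCORE_SCALE * scheme$matrix)),
                    nrow(scheme$matrix)),
       gap_open = as.integer(round(SCORE_SCALE * scheme$gap_open)),
       gap_ext = as.integer(round(SCORE_SCALE * scheme$gap_extend)))
}

#' Forward fill of the blocked DP matrix
#'
#' Runs the affine-gap (Gotoh) recurrences over the k x k block grid in a
#' wave-front-compatible order and returns the grid cache: the H/E/F
#' values on every block-boundary row and column, plus the best score
#' (matrix corner in global mode; the maximum cell and its position, ties
#' to the smallest `(i, j)`, in local mode).  The result is identical for
#' every legal block execution order and worker count.
#'
#' @param input Scorer input list (internal; see [local_affine_align()]
#'   and [profile_align()] for the public entry points).
#' @param grid Block grid from [partition_blocks()].
#' @param mode `"global"` or `"local"`.
#' @param workers Worker count used to shape the block execution order
#'   (results are independent of it).
#' @param order Optional explicit block order matrix (k^2 x 2, 0-based),
#'   overriding `workers`.
#' @return A `grid_cache` object.
#' @keywords internal
forward_fill <- function(input, grid, mode = "global", workers = 1L,
                         order = NULL) {
  k <- length(grid$row_cuts) - 1L
  if (is.null(order)) order <- wavefront_order(k, workers)
  res <- .fl_forward_cpp(input, grid$row_cuts, grid$col_cuts,
                         mode == "local", order)
  structure(list(version = 1L,
                 k = k,
                 len_a = grid$row_cuts[k + 1L],
                 len_b = grid$col_cuts[k + 1L],
                 mode = mode,
                 row_cuts = grid$row_cuts,
                 col_cuts = grid$col_cuts,
                 rows_h = res$rows_h, rows_e = res$rows_e, rows_f = res$rows_f,
                 cols_h = res$cols_h, cols_e = res$cols_e, cols_f = res$cols_f,
                 best = res$best, best_i = res$best_i, best_j = res$best_j),
            class = "grid_cache")
}

#' @export
print.grid_cache <- function(x, ...) {
  cat("Grid cache: ", x$len_a, " x ", x$len_b, " DP matrix, k = ", x$k,
      ", mode = ", x$mode, ", best = ", x$best / SCORE_SCALE, "\n", sep = "")
  invisible(x)
}

#' Traceback through a grid cache
#'
#' Walks from `start` back to the origin (global mode) or to the first
#' zero cell (local mode), recomputing each visited block interior from
#' its cached boundary.  The reconstructed path attains exactly the score
#' reported by [forward_fill()].
#'
#' @param input The same scorer input the cache was built from.
#' @param cache A `grid_cache`.
#' @param start Optional `c(i, j)` start cell; defaults to the cache's
#'   best position.
#' @return List with `pos_a`, `pos_b` (1-based consumed positions, 0 for
#'   gap) and the 0-based origin cell.
#' @keywords internal
traceback_path <- function(input, cache, start = NULL) {
  if (is.null(start)) start <- c(cache$best_i, cache$best_j)
  len_a <- if (input$mode == "seq") length(input$a) else ncol(input$score_a)
  len_b <- if (input$mode == "seq") length(input$b) else ncol(input$score_b)
  if (len_a != cache$len_a || len_b != cache$len_b)
    stop("grid cache does not match the supplied inputs")
  res <- .fl_traceback_cpp(input, cache$row_cuts, cache$col_cuts,
                           cache[c("rows_h", "rows_e", "rows_f",
                                   "cols_h", "cols_e", "cols_f")],
                           cache$mode == "local",
                           as.integer(start[1]), as.integer(start[2]))
  res
}

# --- grid-cache cell codecs ------------------------------------------------

codec_id <- function(codec) {
  switch(codec, absolute12 = 1L, relative6 = 2L,
         stop("unknown cell codec '", codec, "'"))
}

codec_name <- function(id) c("absolute12", "relative6")[id]

# Vectorized encoders.  h, e, f are integer vectors of equal length.
encode_cells <- function(h, e, f, codec) {
  h <- as.integer(h); e <- as.integer(e); f <- as.integer(f)
  if (codec == "absolute12") {
    v <- as.integer(rbind(h, e, f))
    writeBin(v, raw(), size = 4L, endian = "little")
  } else if (codec == "relative6") {
    de <- e - h; df <- f - h
    if (any(abs(de) >= 128) || any(abs(df) >= 128))
      stop("relative6 codec overflow: |h-e| or |h-f| >= 128; ",
           "use the absolute12 codec for these values")
    hb <- matrix(writeBin(h, raw(), size = 4L, endian = "little"), nrow = 4L)
    eb <- as.raw(ifelse(de < 0, de + 256L, de))
    fb <- as.raw(ifelse(df < 0, df + 256L, df))
    as.vector(rbind(hb, matrix(eb, nrow = 1L), matrix(fb, nrow = 1L)))
  } else stop("unknown cell codec '", codec, "'")
}

decode_cells <- function(bytes, codec) {
  if (codec == "absolute12") {
    if (length(bytes) %% 12L != 0L) stop("byte stream length not a multiple of 12")
    v <- readBin(bytes, integer(), n = length(bytes) %/% 4L,
                 size = 4L, endian = "little")
    m <- matrix(v, nrow = 3L)
    list(h = m[1, ], e = m[2, ], f = m[3, ])
  } else if (codec == "relative6") {
    if (length(bytes) %% 6L != 0L) stop("byte stream length not a multiple of 6")
    m <- matrix(bytes, nrow = 6L)
    h <- readBin(as.vector(m[1:4, , drop = FALSE]), integer(),
                 n = ncol(m), size = 4L, endian = "little")
    tosigned <- function(r) { x <- as.integer(r); ifelse(x > 127L, x - 256L, x) }
    list(h = h, e = h + tosigned(m[5, ]), f = h + tosigned(m[6, ]))
  } else stop("unknown cell codec '", codec, "'")
}

#' Encode one grid-cache cell
#'
#' A cell holds the three affine-gap DP values `h` (main), `e`
#' (horizontal-gap state) and `f` (vertical-gap state).  The
#' `"absolute12"` codec stores three signed 32-bit values (12 bytes); the
#' `"relative6"` codec stores `h` as 32 bits plus `e` and `f` as signed
#' 8-bit differences from `h` (6 bytes), and signals an overflow error,
#' instructing a codec upgrade, when either difference reaches 128.
#'
#' @param cell List with integer fields `h`, `e`, `f`.
#' @param codec `"absolute12"` or `"relative6"`.
#' @return Raw vector of exactly 12 or 6 bytes.
#' @examples
#' length(encode_cell(list(h = 0, e = 0, f = 0), "absolute12"))
#' decode_cell(encode_cell(list(h = 1000, e = 990, f = 995), "relative6"),
#'             "relative6")
#' @export
encode_cell <- function(cell, codec = c("absolute12", "relative6")) {
  codec <- match.arg(codec)
  encode_cells(cell$h, cell$e, cell$f, codec)
}

#' Decode one grid-cache cell
#' @param bytes Raw vector produced by [encode_cell()].
#' @param codec The codec used to encode it.
#' @return List with integer fields `h`, `e`, `f`.
#' @rdname encode_cell
#' @export
decode_cell <- function(bytes, codec = c("absolute12", "relative6")) {
  codec <- match.arg(codec)
  cells <- decode_cells(bytes, codec)
  list(h = cells$h[1], e = cells$e[1], f = cells$f[1])
}

# --- grid-cache persistence ------------------------------------------------

GRID_CACHE_MAGIC <- charToRaw("GACH")

#' Serialize a grid cache to a byte stream
#'
#' The stream is little-endian: a header (magic `GACH`, version, codec id,
#' mode, `k`, `len_a`, `len_b`, best score and position) followed by the
#' boundary-row cells then boundary-column cells in row-major order, each
#' encoded with the chosen cell codec.  This is the handoff format between
#' a forward job and its decoupled backward (traceback) job.
#'
#' @param cache A `grid_cache` from [forward_fill()].
#' @param codec Cell codec; the default 12-byte absolute codec is always
#'   safe, while the 6-byte relative codec requires every cached cell's
#'   gap-state differences to stay below 128.
#' @return A raw vector.
#' @export
serialize_grid_cache <- function(cache, codec = c("absolute12", "relative6")) {
  codec <- match.arg(codec)
  header <- c(GRID_CACHE_MAGIC,
              writeBin(c(cache$version, codec_id(codec),
                         if (cache$mode == "local") 1L else 0L,
                         cache$k, cache$len_a, cache$len_b,
                         cache$best, cache$best_i, cache$best_j),
                       raw(), size = 4L, endian = "little"))
  rows <- encode_cells(t(cache$rows_h), t(cache$rows_e), t(cache$rows_f), codec)
  cols <- encode_cells(t(cache$cols_h), t(cache$cols_e), t(cache$cols_f), codec)
  c(header, rows, cols)
}

#' Restore a grid cache from a byte stream
#' @param bytes Raw vector from [serialize_grid_cache()].
#' @return A `grid_cache`, bit-identical to the serialized one.
#' @export
deserialize_grid_cache <- function(bytes) {
  if (length(bytes) < 40L || !identical(bytes[1:4], GRID_CACHE_MAGIC))
    stop("not a grid-cache byte stream")
  hdr <- readBin(bytes[5:40], integer(), n = 9L, size = 4L, endian = "little")
  version <- hdr[1]; codec <- codec_name(hdr[2]); mode <- hdr[3]
  k <- hdr[4]; len_a <- hdr[5]; len_b <- hdr[6]
  if (version != 1L) stop("unsupported grid-cache version ", version)
  grid <- partition_blocks(len_a, len_b, k)
  cellsize <- if (codec == "absolute12") 12L else 6L
  nrowcells <- (k + 1L) * (len_b + 1L)
  ncolcells <- (k + 1L) * (len_a + 1L)
  body <- bytes[-(1:40)]
  if (length(body) != cellsize * (nrowcells + ncolcells))
    stop("grid-cache byte stream truncated")
  rows <- decode_cells(body[seq_len(cellsize * nrowcells)], codec)
  cols <- decode_cells(body[-seq_len(cellsize * nrowcells)], codec)
  shape <- function(v, nc) matrix(v, nrow = k + 1L, ncol = nc, byrow = TRUE)
  structure(list(version = version, k = k, len_a = len_a, len_b = len_b,
                 mode = if (mode == 1L) "local" else "global",
                 row_cuts = grid$row_cuts, col_cuts = grid$col_cuts,
                 rows_h = shape(rows$h, len_b + 1L),
                 rows_e = shape(rows$e, len_b + 1L),
                 rows_f = shape(rows$f, len_b + 1L),
                 cols_h = shape(cols$h, len_a + 1L),
                 cols_e = shape(cols$e, len_a + 1L),
                 cols_f = shape(cols$f, len_a + 1L),
                 best = hdr[7], best_i = hdr[8], best_j = hdr[9]),
            class = "grid_cache")
}
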