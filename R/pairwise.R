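# Stage 1: all-against-all local affine-gap alignments and the
# percent-identity distance matrix that drives guide-tree clustering.

#' Local affine-gap alignment of two sequences
#'
#' Computes the maximum Smith-Waterman score under the Gotoh affine-gap
#' recurrences on the blocked engine and reconstructs one optimal local
#' alignment.  Traceback is deterministic: diagonal moves are preferred
#' over vertical (gap in `b`) over horizontal (gap in `a`), gap states
#' close as early as possible, and among equal-scoring local maxima the
#' cell with the smallest `(i, j)` wins, so the result is identical for
#' every block count and worker count.
#'
#' @param a,b Residue strings, or single-sequence [sequence_set()]s,
#'   sharing one alphabet.
#' @param scheme A [scoring_scheme()]; defaults to the alphabet's
#'   standard scheme.
#' @param k Blocks per axis (`NULL`: chosen by [select_k()]).
#' @param workers Worker count for the wave-front model (does not affect
#'   the result).
#' @return An object of class `pairwise_alignment` with the score (on the
#'   input score scale), the gapped aligned strings, 1-based inclusive
#'   alignment bounds `start_a`/`end_a`/`start_b`/`end_b`, and
#'   `identity_fraction` over residue-residue columns.
#' @examples
#' s <- scoring_scheme("dna", match = 1, mismatch = -1,
#'                     gap_open = 2, gap_extend = 0.5)
#' local_affine_align("ACGT", "ACGT", s)$score
#' @export
local_affine_align <- function(a, b, scheme = NULL, k = NULL, workers = 1L) {
  pa <- as_single_sequence(a)
  pb <- as_single_sequence(b)
  if (!is.null(pa$alphabet) && !is.null(pb$alphabet) &&
      pa$alphabet != pb$alphabet)
    stop("sequences have different alphabets: ", pa$alphabet, " vs ", pb$alphabet)
  alphabet <- pa$alphabet %||% pb$alphabet %||%
    detect_alphabet(c(pa$seq, pb$seq))
  if (is.null(scheme)) scheme <- scoring_scheme(alphabet)
  if (scheme$alphabet != alphabet)
    stop("scoring scheme alphabet (", scheme$alphabet,
         ") does not match the sequences (", alphabet, ")")
  align_pair(pa$seq, pb$seq, scheme, mode = "local", k = k,
             workers = workers, id_a = pa$id, id_b = pb$id)
}

#' Global affine-gap alignment of two sequences
#'
#' Needleman-Wunsch/Gotoh alignment on the same engine and tie-break
#' rules as [local_affine_align()].
#'
#' @inheritParams local_affine_align
#' @return A `pairwise_alignment` covering both sequences end to end.
#' @export
global_affine_align <- function(a, b, scheme = NULL, k = NULL, workers = 1L) {
  pa <- as_single_sequence(a)
  pb <- as_single_sequence(b)
  alphabet <- pa$alphabet %||% pb$alphabet %||%
    detect_alphabet(c(pa$seq, pb$seq))
  if (is.null(scheme)) scheme <- scoring_scheme(alphabet)
  align_pair(pa$seq, pb$seq, scheme, mode = "global", k = k,
             workers = workers, id_a = pa$id, id_b = pb$id)
}

as_single_sequence <- function(x) {
  if (inherits(x, "sequence_set")) {
    if (length(x) != 1L) stop("expected a single sequence")
    list(seq = x$seq[1], id = x$ids[1], alphabet = x$alphabet)
  } else {
    list(seq = toupper(as.character(x)), id = NULL, alphabet = NULL)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

align_pair <- function(sa, sb, scheme, mode, k = NULL, workers = 1L,
                       id_a = NULL, id_b = NULL) {
  if (!nzchar(sa) || !nzchar(sb)) stop("sequences must be non-empty")
  ca <- alpha_encode(sa, scheme$alphabet)
  cb <- alpha_encode(sb, scheme$alphabet)
  if (is.null(k)) k <- select_k(length(ca), length(cb))
  grid <- partition_blocks(length(ca), length(cb), k)
  input <- seq_scorer_input(ca, cb, scheme)
  cache <- forward_fill(input, grid, mode, workers = workers)
  build_pairwise_result(input, cache, sa, sb, ca, cb, mode,
                        id_a = id_a, id_b = id_b)
}

build_pairwise_result <- function(input, cache, sa, sb, ca, cb, mode,
                                  id_a = NULL, id_b = NULL, path = NULL) {
  if (mode == "local" && cache$best <= 0L) {
    return(structure(list(score = 0, aligned_a = "", aligned_b = "",
                          start_a = 0L, end_a = -1L, start_b = 0L, end_b = -1L,
                          identity_fraction = 0, mode = mode,
                          id_a = id_a, id_b = id_b, pos_a = integer(),
                          pos_b = integer()),
                     class = "pairwise_alignment"))
  }
  if (is.null(path)) path <- traceback_path(input, cache)
  chars_a <- strsplit(sa, "", fixed = TRUE)[[1]]
  chars_b <- strsplit(sb, "", fixed = TRUE)[[1]]
  al_a <- ifelse(path$pos_a > 0L, chars_a[pmax(path$pos_a, 1L)], "-")
  al_b <- ifelse(path$pos_b > 0L, chars_b[pmax(path$pos_b, 1L)], "-")
  rr <- path$pos_a > 0L & path$pos_b > 0L
  nid <- sum(rr & ca[pmax(path$pos_a, 1L)] == cb[pmax(path$pos_b, 1L)])
  structure(list(score = cache$best / SCORE_SCALE,
                 aligned_a = paste(al_a, collapse = ""),
                 aligned_b = paste(al_b, collapse = ""),
                 start_a = path$origin_i + 1L, end_a = cache$best_i,
                 start_b = path$origin_j + 1L, end_b = cache$best_j,
                 identity_fraction = if (sum(rr)) nid / sum(rr) else 0,
                 mode = mode, id_a = id_a, id_b = id_b,
                 pos_a = path$pos_a, pos_b = path$pos_b),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("Pairwise ", x$mode, " alignment: score ", x$score,
      ", identity ", round(100 * x$identity_fraction, 1), "%\n", sep = "")
  if (nzchar(x$aligned_a)) {
    w <- min(60L, nchar(x$aligned_a))
    cat(substr(x$aligned_a, 1, w), "\n", substr(x$aligned_b, 1, w), "\n",
        sep = "")
  }
  invisible(x)
}

#' Percent-identity distance of a pairwise alignment
#'
#' `1 - identical residue pairs / residue-residue columns` of the local
#' alignment; an empty alignment (or one without residue-residue columns)
#' has distance 1.  With `kimura = TRUE` the multiple-hit correction
#' `-log(1 - d - d^2/5)` is applied (distances above 0.75 are capped
#' before correcting); the correction is off by default.
#'
#' @param r A `pairwise_alignment`.
#' @param kimura Apply the Kimura multiple-hit correction.
#' @return Distance in `[0, 1]` (uncorrected) or `[0, Inf)` (corrected).
#' @export
percent_identity_distance <- function(r, kimura = FALSE) {
  rr <- r$pos_a > 0L & r$pos_b > 0L
  d <- if (!length(rr) || !sum(rr)) 1 else {
    al_a <- strsplit(r$aligned_a, "", fixed = TRUE)[[1]]
    al_b <- strsplit(r$aligned_b, "", fixed = TRUE)[[1]]
    1 - sum(rr & al_a == al_b) / sum(rr)
  }
  if (kimura && d > 0) {
    dc <- min(d, 0.75)
    d <- -log(1 - dc - dc * dc / 5)
  }
  d
}

#' Distance matrix from all pairwise alignments
#'
#' Submits the `n(n-1)/2` local alignment jobs through the geometry
#' scheduler, converts each alignment to a percent-identity distance, and
#' fills the symmetric zero-diagonal matrix.  The matrix is identical for
#' every scheduler configuration.
#'
#' @param seqs A [sequence_set()] with at least two sequences.
#' @param scheme A [scoring_scheme()] (default: the alphabet's standard
#'   scheme).
#' @param layout A `geometry_layout`; by default one is chosen from the
#'   job count with [select_geometry_layout()].
#' @param k Blocks per axis for each alignment (`NULL`: [select_k()]).
#' @param kimura Apply the Kimura correction to the distances.
#' @return List of class `pairwise_stage_result` with the distance matrix
#'   `d`, the per-pair `alignments`, the job `ledger` and dispatch `log`.
#' @export
build_distance_matrix <- function(seqs, scheme = NULL, layout = NULL,
                                  k = NULL, kimura = FALSE) {
  if (!inherits(seqs, "sequence_set")) stop("seqs must be a sequence_set")
  n <- length(seqs)
  if (n < 2L) stop("need at least two sequences")
  if (is.null(scheme)) scheme <- scoring_scheme(seqs$alphabet)
  if (scheme$alphabet != seqs$alphabet)
    stop("scoring scheme alphabet does not match the sequences")
  pairs <- utils::combn(n, 2L)
  if (is.null(layout))
    layout <- select_geometry_layout(ncol(pairs))
  codes <- lapply(seqs$seq, alpha_encode, alphabet = seqs$alphabet)
  jobs <- vector("list", ncol(pairs))
  ids <- character(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    ids[p] <- paste0(seqs$ids[i], "|", seqs$ids[j])
    kk <- if (is.null(k)) select_k(length(codes[[i]]), length(codes[[j]])) else k
    jobs[[p]] <- list(input = seq_scorer_input(codes[[i]], codes[[j]], scheme),
                      grid = partition_blocks(length(codes[[i]]),
                                              length(codes[[j]]), kk),
                      mode = "local", i = i, j = j)
  }
  names(jobs) <- ids
  stage <- run_pairwise_stage(jobs, layout)
  d <- matrix(0, n, n, dimnames = list(seqs$ids, seqs$ids))
  alignments <- vector("list", ncol(pairs))
  names(alignments) <- ids
  for (p in seq_len(ncol(pairs))) {
    i <- jobs[[p]]$i; j <- jobs[[p]]$j
    res <- stage$results[[p]]
    aln <- build_pairwise_result(jobs[[p]]$input, res$cache,
                                 seqs$seq[i], seqs$seq[j],
                                 codes[[i]], codes[[j]], "local",
                                 id_a = seqs$ids[i], id_b = seqs$ids[j],
                                 path = res$path)
    alignments[[p]] <- aln
    d[i, j] <- d[j, i] <- percent_identity_distance(aln, kimura = kimura)
  }
  structure(list(d = d, alignments = alignments, ledger = stage$ledger,
                 log = stage$log, layout = layout),
            class = "pairwise_stage_result")
}

#' @export
print.pairwise_stage_result <- function(x, ...) {
  cat("Pairwise stage:", length(x$alignments), "alignments,",
      nrow(x$d), "sequences\n")
  invisible(x)
}
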