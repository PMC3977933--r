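# Stage 3 primitives: 35 x m profiles summarizing a partial alignment,
# the column-product score prfscore, and profile-profile global alignment
# on the blocked engine.
#
# Profile layout (an interpretation of the fixed 35-row structure: all
# residue categories plus the gap information): rows 1..33 hold, per
# column, the weight-averaged substitution-matrix scores of the observed
# residues (rows beyond the alphabet's category count stay zero); row 34
# is the position-specific gap-open penalty and row 35 the gap-extend
# penalty, both reduced where the column already contains gaps.  The
# weighted residue frequencies the score rows were built from are kept
# alongside, since the column score is their dual.

#' Build a profile from a group alignment
#'
#' Residue score rows are `M %*% f`, where `M` is the substitution matrix
#' and `f` the column's sequence-weighted residue frequencies (normalized
#' by the total member weight, so gaps dilute the column).  Gap penalty
#' rows scale the base penalties by `1 - 0.7 * gap_fraction`, encouraging
#' new gaps where gaps already exist.  An all-gap column has all residue
#' rows zero.
#'
#' @param group An [msa()] (a single sequence counts as a one-row
#'   alignment).
#' @param weights Named weights covering every group member (see
#'   [compute_weights()]).
#' @param scheme A [scoring_scheme()].
#' @return An object of class `msa_profile` with fields `mat` (35 x m),
#'   `freq` (33 x m weighted frequencies), `member_ids`, `m`, and the
#'   source alignment `aln`.
#' @examples
#' s <- scoring_scheme("dna")
#' p <- build_profile(msa(c(x = "ACGT"), alphabet = "dna"),
#'                    c(x = 1), s)
#' nrow(p$mat)
#' @export
build_profile <- function(group, weights, scheme) {
  if (!inherits(group, "msa")) stop("group must be an msa")
  missing <- setdiff(group$ids, names(weights))
  if (length(missing))
    stop("weight missing for group member '", missing[1], "'")
  w <- as.numeric(weights[group$ids])
  if (any(!is.finite(w)) || any(w <= 0)) stop("weights must be finite and positive")
  m <- msa_ncol(group)
  ncat <- scheme$ncat
  rows <- lapply(group$seq, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  codes <- matrix(NA_integer_, length(rows), m)   # 1-based category or NA = gap
  for (r in seq_along(rows)) {
    ch <- rows[[r]]
    nong <- ch != "-"
    codes[r, nong] <- alpha_encode(paste(ch[nong], collapse = ""),
                                   scheme$alphabet) + 1L
  }
  wsum <- sum(w)
  freq <- matrix(0, PROFILE_RESIDUE_ROWS, m)
  gapw <- numeric(m)
  for (r in seq_along(rows)) {
    cr <- codes[r, ]
    nong <- which(!is.na(cr))
    if (length(nong)) {
      idx <- cbind(cr[nong], nong)
      freq[idx] <- freq[idx] + w[r]
    }
    gapw[is.na(cr)] <- gapw[is.na(cr)] + w[r]
  }
  freq <- freq / wsum
  gapfrac <- gapw / wsum
  score <- matrix(0, PROFILE_RESIDUE_ROWS, m)
  score[seq_len(ncat), ] <- scheme$matrix %*% freq[seq_len(ncat), , drop = FALSE]
  mat <- rbind(score,
               scheme$gap_open * (1 - 0.7 * gapfrac),
               scheme$gap_extend * (1 - 0.7 * gapfrac))
  structure(list(mat = mat, freq = freq, member_ids = group$ids,
                 m = m, alphabet = scheme$alphabet, aln = group),
            class = "msa_profile")
}

#' @export
print.msa_profile <- function(x, ...) {
  cat("Profile: ", nrow(x$mat), " x ", x$m, " (",
      length(x$member_ids), " sequences)\n", sep = "")
  invisible(x)
}

#' Column score of a profile pair
#'
#' The vector product of one column from each profile, symmetrized:
#' `0.5 * (score1[, i] . freq2[, j] + score2[, j] . freq1[, i])`, over the
#' 33 residue rows only (gap-penalty rows are excluded).  For two
#' single-sequence, weight-1 profiles this reduces to the substitution
#' score of the two residues; an all-gap column scores 0.
#'
#' @param p1,p2 Profiles from [build_profile()].
#' @param i,j Column indices (1-based) into `p1` and `p2`.
#' @return The column score (double).
#' @export
prfscore <- function(p1, p2, i, j) {
  if (i < 1 || i > p1$m || j < 1 || j > p2$m) stop("profile column out of range")
  rr <- seq_len(PROFILE_RESIDUE_ROWS)
  0.5 * (sum(p1$mat[rr, i] * p2$freq[, j]) +
           sum(p2$mat[rr, j] * p1$freq[, i]))
}

profile_scorer_input <- function(p1, p2, fragment = TRUE) {
  rr <- seq_len(PROFILE_RESIDUE_ROWS)
  list(mode = "profile",
       score_a = p1$mat[rr, , drop = FALSE], freq_a = p1$freq,
       score_b = p2$mat[rr, , drop = FALSE], freq_b = p2$freq,
       go_a = as.integer(round(SCORE_SCALE * p1$mat[PROFILE_RESIDUE_ROWS + 1L, ])),
       ge_a = as.integer(round(SCORE_SCALE * p1$mat[PROFILE_RESIDUE_ROWS + 2L, ])),
       go_b = as.integer(round(SCORE_SCALE * p2$mat[PROFILE_RESIDUE_ROWS + 1L, ])),
       ge_b = as.integer(round(SCORE_SCALE * p2$mat[PROFILE_RESIDUE_ROWS + 2L, ])),
       fragment = isTRUE(fragment))
}

#' Global profile-profile alignment
#'
#' Runs the blocked engine in global mode with the column-product score
#' and the profiles' position-specific gap penalties, then merges the two
#' group alignments along the optimal path.  Column scores are rounded to
#' integer cell values (x 100) before caching, so DP arithmetic is exact
#' and the result is independent of the worker count, the block count and
#' the fragment-transfer policy.
#'
#' @param p1,p2 Profiles from [build_profile()].
#' @param k Blocks per axis (`NULL`: [select_k()], optionally through
#'   `k_table`).
#' @param workers Worker count for the wave-front model.
#' @param fragment Fragment-transfer policy: when `TRUE` each block job
#'   copies only the profile fragments it needs into worker-local
#'   storage; the policy affects data movement only, never the result.
#' @param k_table Optional calibration table for [select_k()].
#' @return Object of class `profile_merge`: the merged [msa()] (`msa`),
#'   the merge `score`, and the alignment path `pos_a`/`pos_b`.
#' @export
profile_align <- function(p1, p2, k = NULL, workers = 1L, fragment = TRUE,
                          k_table = NULL) {
  if (!inherits(p1, "msa_profile") || !inherits(p2, "msa_profile"))
    stop("p1 and p2 must be profiles")
  if (p1$alphabet != p2$alphabet) stop("profiles have different alphabets")
  if (is.null(k)) k <- select_k(p1$m, p2$m, k_table)
  k <- min(k, p1$m, p2$m)
  grid <- partition_blocks(p1$m, p2$m, k)
  input <- profile_scorer_input(p1, p2, fragment = fragment)
  cache <- forward_fill(input, grid, "global", workers = workers)
  path <- traceback_path(input, cache)
  merged <- merge_groups(p1$aln, p2$aln, path)
  structure(list(msa = merged, score = cache$best / SCORE_SCALE,
                 pos_a = path$pos_a, pos_b = path$pos_b),
            class = "profile_merge")
}

# apply an alignment path to the member rows of the two groups
merge_groups <- function(aln1, aln2, path) {
  expand <- function(aln, pos) {
    out <- character(length(aln$ids))
    for (r in seq_along(aln$ids)) {
      ch <- strsplit(aln$seq[r], "", fixed = TRUE)[[1]]
      out[r] <- paste(ifelse(pos > 0L, ch[pmax(pos, 1L)], "-"), collapse = "")
    }
    stats::setNames(out, aln$ids)
  }
  msa(c(expand(aln1, path$pos_a), expand(aln2, path$pos_b)),
      alphabet = aln1$alphabet)
}

#' @export
print.profile_merge <- function(x, ...) {
  cat("Profile merge: score", x$score, "->", length(x$msa), "rows x",
      msa_ncol(x$msa), "columns\n")
  invisible(x)
}
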