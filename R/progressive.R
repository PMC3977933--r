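# Stage 3 driver and the full three-stage pipeline.

#' Progressive alignment along a guide tree
#'
#' Executes the merge schedule of the rooted guide tree: at each step the
#' two child groups are summarized as profiles and merged by
#' [profile_align()]; every intermediate result feeds the next merge
#' until the final multiple alignment holds all sequences.  With two
#' sequences this reduces exactly to a single global pairwise alignment.
#'
#' @param seqs A [sequence_set()] whose ids match the tree leaves.
#' @param tree A rooted `phylo` guide tree.
#' @param weights Named sequence weights (default: [compute_weights()]
#'   of the tree).
#' @param scheme A [scoring_scheme()].
#' @param k Blocks per axis for each merge (`NULL`: [select_k()]).
#' @param workers Worker count for the wave-front model.
#' @param fragment Fragment-transfer policy flag (see [profile_align()]).
#' @param k_table Optional calibration table for [select_k()].
#' @return An [msa()] with one row per input sequence, in input order;
#'   stripping gaps from any row recovers its input sequence.
#' @export
progressive_align <- function(seqs, tree, weights = NULL, scheme = NULL,
                              k = NULL, workers = 1L, fragment = TRUE,
                              k_table = NULL) {
  if (!inherits(seqs, "sequence_set")) stop("seqs must be a sequence_set")
  if (!setequal(tree$tip.label, seqs$ids))
    stop("tree leaves do not match the sequence ids")
  if (is.null(scheme)) scheme <- scoring_scheme(seqs$alphabet)
  if (is.null(weights)) weights <- compute_weights(tree)
  schedule <- traversal_schedule(tree)
  groups <- new.env(parent = emptyenv())
  gkey <- function(tips) paste(sort(tips), collapse = "\r")
  for (i in seq_along(seqs$ids)) {
    assign(gkey(seqs$ids[i]),
           msa(stats::setNames(seqs$seq[i], seqs$ids[i]),
               alphabet = seqs$alphabet),
           envir = groups)
  }
  merged <- NULL
  for (step in schedule) {
    g1 <- get(gkey(step$left), envir = groups)
    g2 <- get(gkey(step$right), envir = groups)
    p1 <- build_profile(g1, weights, scheme)
    p2 <- build_profile(g2, weights, scheme)
    res <- profile_align(p1, p2, k = k, workers = workers,
                         fragment = fragment, k_table = k_table)
    merged <- res$msa
    assign(gkey(c(step$left, step$right)), merged, envir = groups)
  }
  # rows in input order
  msa(stats::setNames(merged$seq[match(seqs$ids, merged$ids)], seqs$ids),
      alphabet = seqs$alphabet)
}

#' Align a set of sequences (full three-stage pipeline)
#'
#' Stage 1 computes all pairwise local alignments and the
#' percent-identity distance matrix through the geometry scheduler;
#' stage 2 builds the neighbor-joining guide tree, midpoint-roots it and
#' derives sequence weights; stage 3 progressively merges groups by
#' profile-profile alignment along the tree.  The output is independent
#' of the worker count, the block counts and the fragment policy.
#'
#' @param seqs A [sequence_set()] (or a FASTA path) with at least two
#'   sequences.
#' @param scheme A [scoring_scheme()]; defaults to the alphabet's
#'   standard scheme.
#' @param k Blocks per axis (`NULL`: chosen per alignment by
#'   [select_k()]).
#' @param workers Worker count for the wave-front model.
#' @param layout Geometry layout for stage 1 (default: chosen from the
#'   job count).
#' @param fragment Fragment-transfer policy for stage 3.
#' @param kimura Apply the Kimura correction to stage-1 distances.
#' @param k_table Optional `(length, k)` calibration table.
#' @param verbose Print per-stage progress.
#' @return An object of class `gridalign` with components `msa` (the
#'   final alignment), `tree` (rooted guide tree), `unrooted_tree`,
#'   `distances`, `weights`, `schedule`, `scheme` and `stage1` (the
#'   pairwise-stage result with its job ledger).
#' @examples
#' fam <- generate_family(n = 4, length = 120, seed = 1)
#' fit <- align_sequences(fam)
#' fit
#' @export
align_sequences <- function(seqs, scheme = NULL, k = NULL, workers = 1L,
                            layout = NULL, fragment = TRUE, kimura = FALSE,
                            k_table = NULL, verbose = FALSE) {
  if (is.character(seqs) && length(seqs) == 1L) seqs <- read_fasta(seqs)
  if (!inherits(seqs, "sequence_set")) stop("seqs must be a sequence_set")
  if (length(seqs) < 2L) stop("need at least two sequences to align")
  if (is.null(scheme)) scheme <- scoring_scheme(seqs$alphabet)
  t0 <- proc.time()[["elapsed"]]
  say <- function(...) if (verbose)
    message(sprintf("[%6.1fs] ", proc.time()[["elapsed"]] - t0), ...)

  say("stage 1: ", choose(length(seqs), 2), " pairwise alignments")
  stage1 <- build_distance_matrix(seqs, scheme, layout = layout, k = k,
                                  kimura = kimura)
  say("stage 2: neighbor-joining guide tree")
  unrooted <- nj_build(stage1$d)
  rooted <- midpoint_root(unrooted)
  weights <- compute_weights(rooted)
  schedule <- traversal_schedule(rooted)
  say("stage 3: ", length(schedule), " progressive merges")
  aln <- progressive_align(seqs, rooted, weights = weights, scheme = scheme,
                           k = k, workers = workers, fragment = fragment,
                           k_table = k_table)
  say("done: ", length(aln), " rows x ", msa_ncol(aln), " columns")
  structure(list(msa = aln, tree = rooted, unrooted_tree = unrooted,
                 distances = stage1$d, weights = weights,
                 schedule = schedule, scheme = scheme, stage1 = stage1,
                 call = match.call()),
            class = "gridalign")
}

#' @export
print.gridalign <- function(x, ...) {
  cat("Progressive multiple alignment\n")
  cat("  sequences: ", length(x$msa), " (", x$msa$alphabet, ")\n", sep = "")
  cat("  columns:   ", msa_ncol(x$msa), "\n", sep = "")
  cat("  mean pairwise distance: ",
      round(mean(x$distances[upper.tri(x$distances)]), 4), "\n", sep = "")
  invisible(x)
}

#' @export
summary.gridalign <- function(object, ...) {
  d <- object$distances[upper.tri(object$distances)]
  cols <- msa_ncol(object$msa)
  rows <- do.call(rbind, strsplit(object$msa$seq, "", fixed = TRUE))
  gapfrac <- mean(rows == "-")
  ident <- mean(apply(rows, 2, function(col) {
    res <- col[col != "-"]
    if (length(res) < 2) return(NA_real_)
    max(table(res)) / length(res)
  }), na.rm = TRUE)
  out <- list(n = length(object$msa), columns = cols,
              gap_fraction = gapfrac, mean_column_identity = ident,
              mean_distance = mean(d), max_distance = max(d),
              weights = object$weights)
  class(out) <- "summary.gridalign"
  out
}

#' @export
print.summary.gridalign <- function(x, ...) {
  cat("Alignment of ", x$n, " sequences, ", x$columns, " columns\n", sep = "")
  cat("  gap fraction:          ", round(x$gap_fraction, 4), "\n", sep = "")
  cat("  mean column identity:  ", round(x$mean_column_identity, 4), "\n", sep = "")
  cat("  mean pairwise distance:", round(x$mean_distance, 4), "\n")
  invisible(x)
}

#' @export
plot.gridalign <- function(x, ...) {
  ape::plot.phylo(x$tree, main = "Guide tree", ...)
  invisible(x)
}

#' Write all pipeline outputs to files
#'
#' @param x A `gridalign` result.
#' @param alignment,tree,distances Output paths (`NULL` skips a file).
#' @param format Alignment format for [write_alignment()].
#' @export
write_gridalign <- function(x, alignment = NULL, tree = NULL,
                            distances = NULL, format = "fasta") {
  if (!is.null(alignment)) write_alignment(x$msa, alignment, format)
  if (!is.null(tree)) write_newick(x$tree, tree)
  if (!is.null(distances)) write_distance_matrix(x$distances, distances)
  invisible(x)
}
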