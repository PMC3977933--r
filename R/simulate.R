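# Synthetic sequence families: a random ancestor plus descendants mutated
# by point substitutions and geometric-length indels.  These emulate the
# randomly generated test families used to exercise the aligner at
# desk scale, with rates a molecular biologist would call a moderately
# diverged family.

#' Generate a synthetic sequence family
#'
#' One random ancestor of the target length is drawn uniformly over the
#' alphabet; each of the `n` family members is an independent copy mutated
#' by per-site substitutions (probability `sub_rate`, to a different
#' residue chosen uniformly) and per-site indel events (probability
#' `indel_rate`; insertion or deletion with equal probability, lengths
#' geometric with mean 2).
#'
#' @param n Number of sequences (>= 2).
#' @param length Ancestor length.
#' @param sub_rate Per-site substitution probability in `[0, 1)`.
#' @param indel_rate Per-site indel probability in `[0, 1)`.
#' @param alphabet `"dna"` or `"protein"`.
#' @param seed Optional integer seed; the same seed always reproduces the
#'   same family.
#' @param prefix Id prefix (ids are `prefix01`, `prefix02`, ...).
#' @return A [sequence_set()].
#' @examples
#' fam <- generate_family(n = 4, length = 100, seed = 42)
#' fam
#' @export
generate_family <- function(n = 10L, length = 2000L, sub_rate = 0.05,
                            indel_rate = 0.01,
                            alphabet = c("dna", "protein"), seed = NULL,
                            prefix = "seq") {
  alphabet <- match.arg(alphabet)
  n <- as.integer(n); length <- as.integer(length)
  if (n < 2L) stop("n must be at least 2")
  if (length < 1L) stop("length must be positive")
  if (sub_rate < 0 || sub_rate >= 1 || indel_rate < 0 || indel_rate >= 1)
    stop("rates must lie in [0, 1)")
  if (!is.null(seed)) set.seed(as.integer(seed))
  residues <- if (alphabet == "dna") c("A", "C", "G", "T")
              else .protein_cats[1:20]
  ancestor <- sample(residues, length, replace = TRUE)
  seqs <- character(n)
  for (s in seq_len(n)) {
    x <- ancestor
    sub <- stats::runif(length(x)) < sub_rate
    if (any(sub)) {
      x[sub] <- vapply(x[sub], function(r)
        sample(setdiff(residues, r), 1L), "")
    }
    if (indel_rate > 0) {
      events <- which(stats::runif(length(x)) < indel_rate)
      # apply from the right so earlier positions stay valid
      for (pos in rev(events)) {
        len <- stats::rgeom(1L, 0.5) + 1L
        if (stats::runif(1L) < 0.5) {
          ins <- sample(residues, len, replace = TRUE)
          x <- append(x, ins, after = pos)
        } else {
          drop <- pos:min(pos + len - 1L, length(x))
          if (length(drop) < length(x)) x <- x[-drop]
        }
      }
    }
    seqs[s] <- paste(x, collapse = "")
  }
  ids <- sprintf("%s%02d", prefix, seq_len(n))
  sequence_set(seqs, ids = ids, alphabet = alphabet)
}
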