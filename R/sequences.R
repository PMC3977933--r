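# Sequence and alignment containers.

#' Create a set of named, unaligned sequences
#'
#' @param seqs Character vector of residue strings (no gap characters).
#' @param ids Sequence identifiers; defaults to `names(seqs)`.
#' @param descriptions Optional per-sequence descriptions.
#' @param alphabet `"auto"`, `"dna"` or `"protein"`.  With `"auto"` the
#'   alphabet is nucleotide when at least 85% of all residues fall in
#'   `{A,C,G,T,U,N}` and protein otherwise.
#' @return An object of class `sequence_set` with fields `ids`,
#'   `descriptions`, `seq` (upper-cased residue strings) and `alphabet`.
#' @examples
#' ss <- sequence_set(c(a = "acgt", b = "ACGA"))
#' ss$alphabet
#' @export
sequence_set <- function(seqs, ids = names(seqs), descriptions = NULL,
                         alphabet = c("auto", "dna", "protein")) {
  alphabet <- match.arg(alphabet)
  force(ids)
  seqs <- toupper(as.character(seqs))
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  ids <- as.character(ids)
  if (length(ids) != length(seqs)) stop("ids and sequences differ in length")
  if (any(!nzchar(ids))) stop("sequence ids must be non-empty")
  if (anyDuplicated(ids))
    stop("duplicate sequence id: ", ids[anyDuplicated(ids)])
  if (any(!nzchar(seqs))) stop("sequences must be non-empty")
  if (any(grepl("[-.]", seqs)))
    stop("gap characters are not allowed in unaligned input sequences")
  if (alphabet == "auto") alphabet <- detect_alphabet(seqs)
  for (i in seq_along(seqs)) {
    bad <- setdiff(unique(strsplit(seqs[i], "", fixed = TRUE)[[1]]),
                   alphabet_letters(alphabet))
    if (length(bad))
      stop("sequence '", ids[i], "' contains character '", bad[1],
           "' invalid for the ", alphabet, " alphabet")
  }
  if (is.null(descriptions)) descriptions <- character(length(seqs))
  structure(list(ids = ids, descriptions = as.character(descriptions),
                 seq = seqs, alphabet = alphabet),
            class = "sequence_set")
}

detect_alphabet <- function(seqs) {
  chars <- unlist(strsplit(toupper(seqs), "", fixed = TRUE))
  frac <- mean(chars %in% c("A", "C", "G", "T", "U", "N"))
  if (frac >= 0.85) "dna" else "protein"
}

#' @export
length.sequence_set <- function(x) length(x$ids)

#' @export
print.sequence_set <- function(x, ...) {
  cat("Sequence set: ", length(x), " ", x$alphabet, " sequences, lengths ",
      min(nchar(x$seq)), "-", max(nchar(x$seq)), "\n", sep = "")
  invisible(x)
}

#' @export
`[.sequence_set` <- function(x, i) {
  sequence_set(x$seq[i], ids = x$ids[i], descriptions = x$descriptions[i],
               alphabet = x$alphabet)
}

#' Create a multiple sequence alignment object
#'
#' All rows must share one length and at least one column; stripping the
#' gap character `-` from a row recovers the original sequence.
#'
#' @param seqs Character vector of equal-length gapped rows.
#' @param ids Row identifiers (unique, non-empty).
#' @param alphabet `"dna"` or `"protein"`.
#' @return An object of class `msa`.
#' @export
msa <- function(seqs, ids = names(seqs), alphabet) {
  force(ids)
  seqs <- toupper(as.character(seqs))
  if (is.null(ids)) stop("alignment rows must be named")
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate alignment row id")
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    stop("alignment rows must all have the same length")
  if (widths[1] == 0L) stop("alignment must have at least one column")
  structure(list(ids = ids, seq = seqs, alphabet = alphabet), class = "msa")
}

#' @export
length.msa <- function(x) length(x$ids)

#' Number of alignment columns
#' @param x An `msa`.
#' @return Integer column count.
#' @export
msa_ncol <- function(x) nchar(x$seq[1])

#' Remove gap characters from alignment rows
#' @param x An `msa` or character vector of gapped strings.
#' @return Character vector of ungapped sequences, named by row id.
#' @export
strip_gaps <- function(x) {
  s <- if (inherits(x, "msa")) stats::setNames(x$seq, x$ids) else x
  gsub("-", "", s, fixed = TRUE)
}

#' @export
print.msa <- function(x, ...) {
  cat("Multiple alignment: ", length(x), " rows x ", msa_ncol(x),
      " columns (", x$alphabet, ")\n", sep = "")
  w <- min(60L, msa_ncol(x))
  nm <- formatC(substr(x$ids, 1, 12), width = 14, flag = "-")
  for (i in seq_len(min(10L, length(x))))
    cat(nm[i], substr(x$seq[i], 1, w), "\n")
  if (length(x) > 10L) cat("...\n")
  invisible(x)
}
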