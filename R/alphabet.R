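# Residue alphabets, category coding and substitution matrices.
#
# Sequences are scored over a fixed category alphabet: 15 nucleotide
# categories (the four bases plus IUPAC ambiguity codes, with U mapped to
# the T category) or 23 amino-acid categories (the 20 standard residues
# plus B, Z, X).  Profiles pad the category space to 33 rows so that one
# profile shape serves both alphabets.

PROFILE_RESIDUE_ROWS <- 33L
PROFILE_ROWS <- 35L   # residue categories + gap-open row + gap-extend row
SCORE_SCALE <- 100L   # user-scale scores are stored as integers x 100

.dna_cats <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")
.dna_sets <- list(A = "A", C = "C", G = "G", T = "T",
                  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                  W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                  B = c("C", "G", "T"), D = c("A", "G", "T"),
                  H = c("A", "C", "T"), V = c("A", "C", "G"),
                  N = c("A", "C", "G", "T"))
.dna_letters <- c(.dna_cats, "U")

.protein_cats <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                   "K", "M", "F", "P", "S", "T", "W", "Y", "V", "B", "Z", "X")

#' Letters accepted for an alphabet
#' @param alphabet `"dna"` or `"protein"`.
#' @return Character vector of accepted (upper-case) residue letters.
#' @keywords internal
alphabet_letters <- function(alphabet) {
  switch(alphabet, dna = .dna_letters, protein = .protein_cats,
         stop("unknown alphabet '", alphabet, "'"))
}

#' Number of residue categories for an alphabet
#' @keywords internal
alphabet_ncat <- function(alphabet) {
  switch(alphabet, dna = length(.dna_cats), protein = length(.protein_cats))
}

#' Encode residues as 0-based category codes
#'
#' @param x A residue string (no gaps).
#' @param alphabet `"dna"` or `"protein"`.
#' @return Integer vector of 0-based category indices.
#' @keywords internal
alpha_encode <- function(x, alphabet) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  if (alphabet == "dna") chars[chars == "U"] <- "T"
  cats <- if (alphabet == "dna") .dna_cats else .protein_cats
  idx <- match(chars, cats)
  if (anyNA(idx)) {
    bad <- chars[which(is.na(idx))[1]]
    stop("residue '", bad, "' is not valid for the ", alphabet, " alphabet")
  }
  idx - 1L
}

# Nucleotide substitution matrix over the 15 categories: the score of two
# ambiguity codes is the mean match/mismatch score over their base sets.
.dna_submatrix <- function(match, mismatch) {
  n <- length(.dna_cats)
  m <- matrix(0, n, n, dimnames = list(.dna_cats, .dna_cats))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      si <- .dna_sets[[.dna_cats[i]]]
      sj <- .dna_sets[[.dna_cats[j]]]
      grid <- outer(si, sj, "==")
      m[i, j] <- mean(ifelse(grid, match, mismatch))
    }
  }
  m
}

.protein_submatrix <- function(name = "BLOSUM62") {
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  full <- env[[name]]
  full[.protein_cats, .protein_cats]
}

#' Scoring scheme for pairwise and profile alignment
#'
#' Bundles a symmetric substitution matrix over the residue categories of
#' one alphabet with affine gap penalties: a gap of length L costs
#' `gap_open + L * gap_extend`.
#'
#' Defaults follow the Clustal W tradition: nucleotide scoring is
#' match/mismatch (+1/0) with `gap_open = 15`, `gap_extend = 6.66`;
#' protein scoring is BLOSUM62 with `gap_open = 10`, `gap_extend = 0.1`.
#'
#' @param alphabet `"dna"` or `"protein"`.
#' @param match,mismatch Nucleotide match/mismatch scores (ignored for
#'   protein, and when `matrix` is supplied).
#' @param matrix Optional substitution matrix whose dimnames cover the
#'   alphabet's category letters (e.g. one read with
#'   [read_score_matrix()]).
#' @param gap_open,gap_extend Non-negative gap penalties with
#'   `gap_open >= gap_extend`.
#' @return An object of class `scoring_scheme`.
#' @examples
#' s <- scoring_scheme("dna", match = 1, mismatch = -1,
#'                     gap_open = 2, gap_extend = 0.5)
#' s$matrix["A", "A"]
#' @export
scoring_scheme <- function(alphabet = c("dna", "protein"),
                           match = 1, mismatch = 0,
                           matrix = NULL,
                           gap_open = NULL, gap_extend = NULL) {
  alphabet <- match.arg(alphabet)
  if (is.null(gap_open))
    gap_open <- if (alphabet == "dna") 15 else 10
  if (is.null(gap_extend))
    gap_extend <- if (alphabet == "dna") 6.66 else 0.1
  if (gap_open < 0 || gap_extend < 0 || gap_open < gap_extend)
    stop("gap penalties must satisfy gap_open >= gap_extend >= 0")
  cats <- if (alphabet == "dna") .dna_cats else .protein_cats
  if (is.null(matrix)) {
    matrix <- if (alphabet == "dna") .dna_submatrix(match, mismatch)
              else .protein_submatrix()
  } else {
    if (is.null(dimnames(matrix)) ||
        !all(cats %in% rownames(matrix)) || !all(cats %in% colnames(matrix)))
      stop("substitution matrix must have dimnames covering: ",
           paste(cats, collapse = ""))
    matrix <- matrix[cats, cats]
  }
  if (!isTRUE(all.equal(matrix, t(matrix))))
    stop("substitution matrix must be symmetric")
  structure(list(alphabet = alphabet,
                 matrix = matrix,
                 gap_open = gap_open,
                 gap_extend = gap_extend,
                 ncat = length(cats)),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("Scoring scheme (", x$alphabet, "): ", x$ncat, " residue categories, ",
      "gap open ", x$gap_open, ", gap extend ", x$gap_extend, "\n", sep = "")
  invisible(x)
}

#' Read a substitution matrix in NCBI/EMBOSS plain-text format
#'
#' Parses the whitespace-separated matrix format used by EMBOSS and the
#' NCBI toolkits: `#` comment lines, a header row of residue letters, then
#' one labelled score row per residue.
#'
#' @param path Path to the matrix file.
#' @return A symmetric numeric matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not a substitution matrix file: ", path)
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1]]
  rows <- lapply(lines[-1L], function(l) strsplit(trimws(l), "\\s+")[[1]])
  labels <- vapply(rows, `[`, "", 1L)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1L]),
                   numeric(length(header))))
  dimnames(vals) <- list(labels, header)
  vals
}
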