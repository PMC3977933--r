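# File formats: FASTA in/out, CLUSTAL out, Newick trees, PHYLIP distance
# matrices.  FASTA parsing is done line-by-line so that validation errors
# (gap characters, residues outside the alphabet) can report the offending
# line number.

#' Read unaligned sequences from a FASTA file
#'
#' @param path Path to a multi-record FASTA file.
#' @param alphabet `"auto"`, `"dna"` or `"protein"`; see [sequence_set()].
#' @return A [sequence_set()].
#' @details Record ids are the first whitespace-delimited token of each
#'   header; the remainder is kept as the description.  Residues are
#'   upper-cased.  Gap characters (`-` or `.`), duplicate ids and residues
#'   outside the (detected or forced) alphabet are rejected with the
#'   offending line number.
#' @export
read_fasta <- function(path, alphabet = c("auto", "dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(nzchar(trimws(lines))))
    stop("empty FASTA file: ", path)
  ids <- character(); descs <- character()
  parts <- list()        # per-record list of residue chunks
  part_lines <- list()   # line number of each chunk
  cur <- 0L
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line)) next
    if (startsWith(line, ">")) {
      header <- sub("^>", "", line)
      toks <- strsplit(header, "\\s+")[[1]]
      id <- if (length(toks)) toks[1] else ""
      if (!nzchar(id)) stop("empty sequence id at line ", ln)
      if (id %in% ids) stop("duplicate sequence id '", id, "' at line ", ln)
      cur <- cur + 1L
      ids[cur] <- id
      descs[cur] <- trimws(sub("^\\S+\\s*", "", header))
      parts[[cur]] <- character()
      part_lines[[cur]] <- integer()
    } else {
      if (cur == 0L) stop("sequence data before first header at line ", ln)
      chunk <- toupper(gsub("\\s", "", line))
      parts[[cur]] <- c(parts[[cur]], chunk)
      part_lines[[cur]] <- c(part_lines[[cur]], ln)
    }
  }
  if (cur == 0L) stop("no FASTA records in ", path)
  seqs <- vapply(parts, paste0, "", collapse = "")
  if (any(!nzchar(seqs))) {
    stop("record '", ids[which(!nzchar(seqs))[1]], "' has no residues")
  }
  resolved <- if (alphabet == "auto") detect_alphabet(seqs) else alphabet
  allowed <- alphabet_letters(resolved)
  for (r in seq_len(cur)) {
    for (ci in seq_along(parts[[r]])) {
      chars <- strsplit(parts[[r]][ci], "", fixed = TRUE)[[1]]
      if (any(chars %in% c("-", "."))) {
        stop("gap character in unaligned input at line ", part_lines[[r]][ci])
      }
      bad <- setdiff(unique(chars), allowed)
      if (length(bad)) {
        stop("invalid ", resolved, " residue '", bad[1], "' at line ",
             part_lines[[r]][ci])
      }
    }
  }
  sequence_set(seqs, ids = ids, descriptions = descs, alphabet = resolved)
}

#' Write sequences or an alignment to FASTA
#'
#' @param x A [sequence_set()] or [msa()].
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @export
write_fasta <- function(x, path, width = 60L) {
  ids <- x$ids
  seqs <- x$seq
  descs <- if (!is.null(x$descriptions)) x$descriptions
           else character(length(ids))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ids)) {
    header <- if (nzchar(descs[i])) paste(ids[i], descs[i]) else ids[i]
    writeLines(paste0(">", header), con)
    s <- seqs[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write a multiple alignment to FASTA or CLUSTAL format
#'
#' @param x An [msa()].
#' @param path Output path.
#' @param format `"fasta"` (wrapped at 60 columns) or `"clustal"`
#'   (interleaved 60-residue blocks; ids truncated to 30 characters).
#' @export
write_alignment <- function(x, path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!inherits(x, "msa")) stop("x must be an msa")
  if (msa_ncol(x) < 1L) stop("alignment has no columns")
  if (format == "fasta") return(write_fasta(x, path))
  ids <- substr(x$ids, 1, 30)
  namew <- max(nchar(ids)) + 4L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("CLUSTAL multiple sequence alignment (gridalign)", ""), con)
  ncol <- msa_ncol(x)
  for (start in seq(1L, ncol, by = 60L)) {
    end <- min(start + 59L, ncol)
    for (i in seq_along(ids)) {
      writeLines(paste0(formatC(ids[i], width = namew, flag = "-"),
                        substr(x$seq[i], start, end)), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read an alignment written by [write_alignment()]
#'
#' @param path Input path.
#' @param format `"auto"` (detected from the first line), `"fasta"` or
#'   `"clustal"`.
#' @param alphabet Alphabet passed to [msa()]; `"auto"` detects it.
#' @return An [msa()].
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal"),
                           alphabet = c("auto", "dna", "protein")) {
  format <- match.arg(format)
  alphabet <- match.arg(alphabet)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    first <- trimws(lines[nzchar(trimws(lines))][1])
    format <- if (startsWith(first, "CLUSTAL")) "clustal" else "fasta"
  }
  if (format == "fasta") {
    ids <- character(); seqs <- character(); cur <- 0L
    for (line in lines) {
      line <- trimws(line)
      if (!nzchar(line)) next
      if (startsWith(line, ">")) {
        cur <- cur + 1L
        ids[cur] <- strsplit(sub("^>", "", line), "\\s+")[[1]][1]
        seqs[cur] <- ""
      } else seqs[cur] <- paste0(seqs[cur], gsub("\\s", "", line))
    }
  } else {
    body <- lines[-1]
    rows <- list()
    order_ids <- character()
    for (line in body) {
      if (!nzchar(trimws(line)) || grepl("^\\s", line)) next
      toks <- strsplit(trimws(line), "\\s+")[[1]]
      if (length(toks) < 2L) next
      id <- toks[1]
      if (!(id %in% order_ids)) {
        order_ids <- c(order_ids, id)
        rows[[id]] <- ""
      }
      rows[[id]] <- paste0(rows[[id]], toks[2])
    }
    ids <- order_ids
    seqs <- unlist(rows[order_ids], use.names = FALSE)
  }
  resolved <- if (alphabet == "auto") detect_alphabet(gsub("-", "", seqs))
              else alphabet
  msa(stats::setNames(seqs, ids), alphabet = resolved)
}

#' Format a guide tree as a Newick string
#'
#' Branch lengths are printed with five decimal places; leaf labels are the
#' sequence ids.  Unrooted trees are written with a trifurcating root node,
#' following the neighbor-joining convention.
#'
#' @param tree A `phylo` tree (from [nj_build()] or [midpoint_root()]).
#' @param digits Decimal places for branch lengths.
#' @return A single Newick string.
#' @export
newick_string <- function(tree, digits = 5L) {
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object")
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stop("tree must have at least two leaves")
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt <- function(v) sprintf(paste0("%.", digits, "f"), v)
  rec <- function(node) {
    es <- kids[[as.character(node)]]
    parts <- vapply(es, function(e) {
      child <- tree$edge[e, 2]
      lab <- if (child <= ntip) tree$tip.label[child] else rec(child)
      paste0(lab, ":", fmt(tree$edge.length[e]))
    }, "")
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(rec(ntip + 1L), ";")
}

#' Write a guide tree in Newick format
#' @param tree A `phylo` tree.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  writeLines(newick_string(tree), path)
  invisible(path)
}

#' Write a distance matrix in PHYLIP square format
#'
#' First line is the sequence count; each following line is the id padded
#' to 10 characters and the row of distances with six decimal places.
#'
#' @param dm Symmetric numeric matrix with id dimnames.
#' @param path Output path.
#' @export
write_distance_matrix <- function(dm, path) {
  validate_distance_matrix(dm)
  n <- nrow(dm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", n), con)
  ids <- formatC(substr(rownames(dm), 1, 10), width = 10, flag = "-")
  for (i in seq_len(n)) {
    writeLines(paste0(ids[i], " ",
                      paste(sprintf("%.6f", dm[i, ]), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a PHYLIP square distance matrix
#' @param path Input path.
#' @return Symmetric numeric matrix with id dimnames.
#' @export
read_distance_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || n < 2L) stop("invalid PHYLIP matrix header")
  ids <- character(n)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    line <- lines[i + 1L]
    ids[i] <- trimws(substr(line, 1, 10))
    d[i, ] <- as.numeric(strsplit(trimws(substr(line, 11, nchar(line))),
                                  "\\s+")[[1]])
  }
  dimnames(d) <- list(ids, ids)
  d
}

validate_distance_matrix <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm))
    stop("distance matrix must be square")
  if (is.null(rownames(dm))) stop("distance matrix must have id dimnames")
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-9)))
    stop("distance matrix must be symmetric")
  if (any(diag(dm) != 0)) stop("distance matrix diagonal must be zero")
  if (any(dm < 0)) stop("distance matrix entries must be non-negative")
  invisible(dm)
}
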