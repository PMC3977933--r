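# Independent full-matrix affine-gap (Gotoh) oracle, written in plain R
# against the same scoring contract as the blocked engine: integer-scaled
# scores, gap of length L costs open + L * extend, tie-breaks diagonal >
# vertical (gap in b) > horizontal (gap in a), gap states close as early
# as possible, local maxima tie to the smallest (i, j).  It materializes
# the full three DP matrices and never touches the block/grid-cache code.

ORACLE_NEG <- -536870912  # same "minus infinity" sentinel scale as the engine

oracle_iround <- function(x) trunc(x + sign(x) * 0.5)  # round half away from zero

oracle_gotoh <- function(ca, cb, sub, go, ge, local = FALSE) {
  La <- length(ca); Lb <- length(cb)
  NEG <- ORACLE_NEG
  H <- matrix(0, La + 1, Lb + 1)
  E <- matrix(NEG, La + 1, Lb + 1)
  F <- matrix(NEG, La + 1, Lb + 1)
  if (!local) {
    for (j in seq_len(Lb) + 1L) {
      e <- max(H[1, j - 1] - go - ge, E[1, j - 1] - ge, NEG)
      H[1, j] <- e; E[1, j] <- e
    }
    for (i in seq_len(La) + 1L) {
      f <- max(H[i - 1, 1] - go - ge, F[i - 1, 1] - ge, NEG)
      H[i, 1] <- f; F[i, 1] <- f
    }
  }
  for (i in seq_len(La) + 1L) {
    for (j in seq_len(Lb) + 1L) {
      e <- max(H[i, j - 1] - go - ge, E[i, j - 1] - ge, NEG)
      f <- max(H[i - 1, j] - go - ge, F[i - 1, j] - ge, NEG)
      dg <- H[i - 1, j - 1]
      h <- max(if (dg <= NEG) NEG else dg + sub[ca[i - 1] + 1L, cb[j - 1] + 1L],
               e, f)
      if (local && h < 0) h <- 0
      H[i, j] <- h; E[i, j] <- e; F[i, j] <- f
    }
  }
  if (local) {
    best <- 0; bi <- 0L; bj <- 0L
    for (i in seq_len(La)) {
      for (j in seq_len(Lb)) {
        if (H[i + 1, j + 1] > best) { best <- H[i + 1, j + 1]; bi <- i; bj <- j }
      }
    }
  } else {
    best <- H[La + 1, Lb + 1]; bi <- La; bj <- Lb
  }
  if (local && best <= 0) {
    return(list(score = 0, pos_a = integer(), pos_b = integer(),
                origin_i = 0L, origin_j = 0L))
  }
  # traceback
  pa <- integer(); pb <- integer()
  i <- bi; j <- bj; state <- "H"
  repeat {
    if (state == "H") {
      if (local && H[i + 1, j + 1] == 0) break
      if (i == 0L && j == 0L) break
      if (i > 0L && j > 0L) {
        h <- H[i + 1, j + 1]
        dg <- H[i, j]
        if (dg > ORACLE_NEG && h == dg + sub[ca[i] + 1L, cb[j] + 1L]) {
          pa <- c(pa, i); pb <- c(pb, j); i <- i - 1L; j <- j - 1L
        } else if (h == F[i + 1, j + 1]) state <- "F"
        else if (h == E[i + 1, j + 1]) state <- "E"
        else stop("oracle traceback inconsistency")
      } else if (i > 0L) state <- "F"
      else state <- "E"
    } else if (state == "F") {
      f <- F[i + 1, j + 1]
      close <- H[i, j + 1] > ORACLE_NEG && f == H[i, j + 1] - go - ge
      pa <- c(pa, i); pb <- c(pb, 0L)
      i <- i - 1L
      if (close) state <- "H"
    } else {
      e <- E[i + 1, j + 1]
      close <- H[i + 1, j] > ORACLE_NEG && e == H[i + 1, j] - go - ge
      pa <- c(pa, 0L); pb <- c(pb, j)
      j <- j - 1L
      if (close) state <- "H"
    }
  }
  list(score = best, pos_a = rev(pa), pos_b = rev(pb),
       origin_i = i, origin_j = j)
}

# align two residue strings with the oracle under a scoring_scheme,
# returning user-scale score and gapped strings
oracle_align <- function(sa, sb, scheme, local = FALSE) {
  ca <- gridalign:::alpha_encode(sa, scheme$alphabet)
  cb <- gridalign:::alpha_encode(sb, scheme$alphabet)
  sub <- round(100 * scheme$matrix)
  go <- round(100 * scheme$gap_open); ge <- round(100 * scheme$gap_extend)
  res <- oracle_gotoh(ca, cb, sub, go, ge, local = local)
  st <- path_strings(sa, sb, res$pos_a, res$pos_b)
  list(score = res$score / 100, aligned_a = st[1], aligned_b = st[2],
       pos_a = res$pos_a, pos_b = res$pos_b,
       origin_i = res$origin_i, origin_j = res$origin_j)
}

path_strings <- function(sa, sb, pos_a, pos_b) {
  cha <- strsplit(sa, "", fixed = TRUE)[[1]]
  chb <- strsplit(sb, "", fixed = TRUE)[[1]]
  c(paste(ifelse(pos_a > 0, cha[pmax(pos_a, 1)], "-"), collapse = ""),
    paste(ifelse(pos_b > 0, chb[pmax(pos_b, 1)], "-"), collapse = ""))
}

random_dna <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = "")

random_protein <- function(len) paste(sample(gridalign:::.protein_cats[1:20],
                                             len, replace = TRUE),
                                      collapse = "")

# independent column-wise rescoring of an alignment path (integer scale,
# engine rounding), for sequences ...
rescore_pair_path <- function(pos_a, pos_b, ca, cb, sub, go, ge) {
  total <- 0
  state <- "H"  # a switch between gap-in-a and gap-in-b opens a new gap
  for (t in seq_along(pos_a)) {
    if (pos_a[t] > 0L && pos_b[t] > 0L) {
      total <- total + sub[ca[pos_a[t]] + 1L, cb[pos_b[t]] + 1L]
      state <- "H"
    } else if (pos_a[t] == 0L) {
      if (state != "E") total <- total - go
      total <- total - ge
      state <- "E"
    } else {
      if (state != "F") total <- total - go
      total <- total - ge
      state <- "F"
    }
  }
  total
}

# ... and for profile merges, using the package's prfscore as the
# column score and the profiles' own position-specific penalties
rescore_merge <- function(p1, p2, pos_a, pos_b) {
  go_a <- round(100 * p1$mat[34, ]); ge_a <- round(100 * p1$mat[35, ])
  go_b <- round(100 * p2$mat[34, ]); ge_b <- round(100 * p2$mat[35, ])
  total <- 0
  state <- "H"
  for (t in seq_along(pos_a)) {
    if (pos_a[t] > 0L && pos_b[t] > 0L) {
      total <- total + oracle_iround(100 * prfscore(p1, p2, pos_a[t], pos_b[t]))
      state <- "H"
    } else if (pos_a[t] == 0L) {  # gap in a, consume b
      j <- pos_b[t]
      if (state != "E") total <- total - go_b[j]
      total <- total - ge_b[j]
      state <- "E"
    } else {                      # gap in b, consume a
      i <- pos_a[t]
      if (state != "F") total <- total - go_a[i]
      total <- total - ge_a[i]
      state <- "F"
    }
  }
  total / 100
}
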