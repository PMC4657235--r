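#' Alignment profile
#'
#' A set of already-aligned rows treated as one alignable object, with
#' per-column merged gap penalties.
#'
#' @param ids Sequence ids.
#' @param rows Equal-length gapped rows.
#' @param penalties [gap_penalties()] with one entry per column.
#' @return An object of class `profile_aln`.
#' @export
new_profile <- function(ids, rows, penalties) {
  stopifnot(inherits(penalties, "gap_penalties"))
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("profile rows have unequal lengths")
  if (length(penalties$gpo) != w)
    stop("penalty length does not match profile column count")
  structure(list(ids = as.character(ids), rows = as.character(rows),
                 penalties = penalties),
            class = "profile_aln")
}

#' @export
print.profile_aln <- function(x, ...) {
  cat(sprintf("<profile_aln> %d sequence(s) x %d columns\n",
              length(x$ids), nchar(x$rows[1L])))
  invisible(x)
}

#' Single-sequence profile from an annotated sequence
#'
#' The profile inherits the sequence's own gap opening penalties; its
#' extension penalties are zero inside the predicted IndelFRs and equal
#' to the opening penalty elsewhere.
#'
#' @param aseq An [annotated_sequence()].
#' @return A [new_profile()] with one row.
#' @export
profile_from_annotated <- function(aseq) {
  stopifnot(inherits(aseq, "annotated_seq"))
  new_profile(aseq$seq$id, aseq$seq$residues,
              gap_penalties(aseq$gpo, extension_penalties(aseq$gpo, aseq$ifrs)))
}

# residue-frequency representation: F (alphabet x width, frequencies over
# non-gap entries) and occ (non-gap fraction per column)
profile_freqs <- function(p, alphabet) {
  mat <- do.call(rbind, strsplit(p$rows, ""))
  w <- ncol(mat)
  cnt <- matrix(0, length(alphabet), w, dimnames = list(alphabet, NULL))
  for (a in alphabet) cnt[a, ] <- colSums(mat == a)
  nong <- colSums(mat != "-")
  if (any(nong == 0L)) stop("profile contains an all-gap column")
  list(F = sweep(cnt, 2L, nong, "/"), occ = nong / nrow(mat))
}

#' Expected substitution score of two profile columns
#'
#' `occA * occB * sum_x sum_y fA(x) fB(y) S(x, y)` where `f` are residue
#' frequencies over the non-gap entries of each column and `occ` the
#' non-gap fractions; reduces to `S(a, b)` for two single-residue
#' columns.
#'
#' @param colA,colB Named counts (residue -> count; a `-` entry counts
#'   gaps) or plain character vectors of column symbols.
#' @param S Substitution matrix (see [load_gonnet250()]).
#' @return Expected score (numeric scalar).
#' @export
column_score <- function(colA, colB, S) {
  as_counts <- function(x) if (is.null(names(x))) table(x) else x
  score1 <- function(ca, cb) {
    ca <- ca[ca > 0]; cb <- cb[cb > 0]
    ra <- setdiff(names(ca), "-"); rb <- setdiff(names(cb), "-")
    if (length(ra) == 0L || length(cb) == 0L || length(rb) == 0L)
      stop("column_score on an all-gap column")
    fa <- ca[ra] / sum(ca[ra]); fb <- cb[rb] / sum(cb[rb])
    occa <- sum(ca[ra]) / sum(ca); occb <- sum(cb[rb]) / sum(cb)
    occa * occb * drop(t(fa) %*% S[ra, rb, drop = FALSE] %*% fb)
  }
  score1(as_counts(colA), as_counts(colB))
}

# full column-score grid between two profiles (rows of A x rows of B)
score_grid <- function(A, B, S) {
  alphabet <- rownames(S)
  fa <- profile_freqs(A, alphabet); fb <- profile_freqs(B, alphabet)
  g <- t(fa$F) %*% unclass(S) %*% fb$F
  sweep(sweep(g, 1L, fa$occ, "*"), 2L, fb$occ, "*")
}

# ---- three-state DP with variable gap penalties --------------------------
#
# Move codes in a trace: 1 = columns aligned, 2 = A column against a gap
# (gap in B), 3 = B column against a gap (gap in A).  A gap run over A
# columns i1..i2 costs gpoA[i1] + sum(gpeA[i1..i2]); runs over B columns
# symmetrically; openings are charged afresh when a run follows a run of
# the opposite kind.  `waive` drops the opening of a gap-in-B run that
# starts at the first A position (used by the divide-and-conquer halves);
# `force` constrains the final column to be gap-in-B.

vgp_dp_full <- function(sc, goA, geA, goB, geB, waive = FALSE, force = FALSE) {
  n <- nrow(sc); m <- ncol(sc)
  NEG <- -Inf
  M <- matrix(NEG, n + 1L, m + 1L); IA <- M; IB <- M
  pM <- matrix(1L, n + 1L, m + 1L); pA <- pM; pB <- pM
  M[1L, 1L] <- 0
  if (n > 0L) {
    M[-1L, 1L] <- -((if (waive) 0 else goA[1L]) + cumsum(geA))
    IA[-1L, 1L] <- M[-1L, 1L]
  }
  if (m > 0L) {
    M[1L, -1L] <- -(goB[1L] + cumsum(geB))
    IB[1L, -1L] <- M[1L, -1L]
  }
  for (i in seq_len(n)) {
    r <- i + 1L
    jj <- seq_len(m) + 1L
    # M and IA rows depend only on row r-1: vectorized
    c1 <- M[r - 1L, jj - 1L]; c2 <- IA[r - 1L, jj - 1L]; c3 <- IB[r - 1L, jj - 1L]
    best <- pmax(c1, c2, c3)
    M[r, jj] <- sc[i, ] + best
    pM[r, jj] <- ifelse(c1 >= best, 1L, ifelse(c2 >= best, 2L, 3L))
    a1 <- M[r - 1L, jj] - (goA[i] + geA[i])
    a2 <- IA[r - 1L, jj] - geA[i]
    a3 <- IB[r - 1L, jj] - (goA[i] + geA[i])
    besta <- pmax(a1, a2, a3)
    IA[r, jj] <- besta
    pA[r, jj] <- ifelse(a1 >= besta, 1L, ifelse(a2 >= besta, 2L, 3L))
    for (j in seq_len(m)) {  # IB depends on same-row j-1: sequential
      b1 <- M[r, j] - (goB[j] + geB[j])
      b2 <- IA[r, j] - (goB[j] + geB[j])
      b3 <- IB[r, j] - geB[j]
      if (b1 >= b2 && b1 >= b3) { IB[r, j + 1L] <- b1; pB[r, j + 1L] <- 1L }
      else if (b2 >= b3)        { IB[r, j + 1L] <- b2; pB[r, j + 1L] <- 2L }
      else                      { IB[r, j + 1L] <- b3; pB[r, j + 1L] <- 3L }
    }
  }
  end <- c(M[n + 1L, m + 1L], IA[n + 1L, m + 1L], IB[n + 1L, m + 1L])
  s <- if (force) 2L else which.max(end)  # which.max prefers M, then IA, then IB
  score <- end[s]
  codes <- integer(0)
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    if (i == 0L) { codes <- c(3L, codes); j <- j - 1L; next }
    if (j == 0L) { codes <- c(2L, codes); i <- i - 1L; next }
    if (s == 1L)      { codes <- c(1L, codes); s <- pM[i + 1L, j + 1L]; i <- i - 1L; j <- j - 1L }
    else if (s == 2L) { codes <- c(2L, codes); s <- pA[i + 1L, j + 1L]; i <- i - 1L }
    else              { codes <- c(3L, codes); s <- pB[i + 1L, j + 1L]; j <- j - 1L }
  }
  list(score = score, codes = codes)
}

# forward pass keeping only the last row; returns final-row state vectors
vgp_dp_lastrow <- function(sc, goA, geA, goB, geB, waive = FALSE) {
  n <- nrow(sc); m <- ncol(sc)
  Mp <- c(0, -(goB[1L] + cumsum(geB)))
  IAp <- rep(-Inf, m + 1L)
  IBp <- c(-Inf, Mp[-1L])
  colA0 <- -((if (waive) 0 else goA[1L]) + cumsum(geA))
  for (i in seq_len(n)) {
    jj <- seq_len(m) + 1L
    Mn <- c(colA0[i], sc[i, ] + pmax(Mp[jj - 1L], IAp[jj - 1L], IBp[jj - 1L]))
    IAn <- c(colA0[i], pmax(Mp[jj] - (goA[i] + geA[i]), IAp[jj] - geA[i],
                            IBp[jj] - (goA[i] + geA[i])))
    IBn <- rep(-Inf, m + 1L)
    for (j in seq_len(m)) {
      IBn[j + 1L] <- max(Mn[j] - (goB[j] + geB[j]), IAn[j] - (goB[j] + geB[j]),
                         IBn[j] - geB[j])
    }
    Mp <- Mn; IAp <- IAn; IBp <- IBn
  }
  list(M = Mp, IA = IAp, IB = IBp)
}

# backward pass from row `from` (1-based into sc rows) to the end; returns
# vectors over j = 0..m at row `from`:
#   u[j+1]: best score of aligning A[from..n] vs B[j+1..m], fresh openings
#   v[j+1]: same, but a leading gap-in-B run pays no opening (continuation)
# `force` constrains the final column of the suffix to be gap-in-B.
vgp_dp_backward <- function(sc, goA, geA, goB, geB, from, force = FALSE) {
  n <- nrow(sc); m <- ncol(sc)
  NEG <- -Inf
  tailB <- rev(cumsum(rev(geB)))          # sum geB[j+1..m] at index j+1
  if (force) {
    u <- rep(NEG, m + 1L); v <- u; w <- u
  } else {
    u <- c(-(goB[seq_len(m)] + tailB), 0)
    w <- c(-tailB, 0)
    v <- u
  }
  if (from > n) return(list(u = u, v = v))
  tailA <- rev(cumsum(rev(geA)))          # sum geA[i..n] at index i
  for (i in seq.int(n, from)) {
    un <- numeric(m + 1L); vn <- un; wn <- un
    un[m + 1L] <- -(goA[i] + tailA[i]); vn[m + 1L] <- -tailA[i]; wn[m + 1L] <- un[m + 1L]
    if (m > 0L) for (j in seq.int(m - 1L, 0L)) {
      diagv <- sc[i, j + 1L] + u[j + 2L]
      gapB_open <- -(goA[i] + geA[i]) + v[j + 1L]
      gapB_cont <- -geA[i] + v[j + 1L]
      gapA_open <- -(goB[j + 1L] + geB[j + 1L]) + wn[j + 2L]
      gapA_cont <- -geB[j + 1L] + wn[j + 2L]
      un[j + 1L] <- max(diagv, gapB_open, gapA_open)
      vn[j + 1L] <- max(diagv, gapB_cont, gapA_open)
      wn[j + 1L] <- max(diagv, gapB_open, gapA_cont)
    }
    u <- un; v <- vn; w <- wn
  }
  list(u = u, v = v)
}

# divide-and-conquer (Hirschberg / Myers-Miller style) trace in linear space
vgp_hirschberg <- function(sc, goA, geA, goB, geB, waive = FALSE, force = FALSE,
                           basecut = 24L) {
  n <- nrow(sc); m <- ncol(sc)
  if (n <= basecut || m <= 2L)
    return(vgp_dp_full(sc, goA, geA, goB, geB, waive, force)$codes)
  h <- n %/% 2L
  fw <- vgp_dp_lastrow(sc[seq_len(h), , drop = FALSE], goA[seq_len(h)],
                       geA[seq_len(h)], goB, geB, waive)
  bw <- vgp_dp_backward(sc, goA, geA, goB, geB, from = h + 1L, force = force)
  tot1 <- pmax(fw$M, fw$IA, fw$IB) + bw$u
  tot2 <- fw$IA + bw$v
  best1 <- max(tot1); best2 <- max(tot2)
  if (best1 >= best2) {
    js <- which.max(tot1) - 1L
    left <- vgp_hirschberg(sc[seq_len(h), seq_len(js), drop = FALSE],
                           goA[seq_len(h)], geA[seq_len(h)],
                           goB[seq_len(js)], geB[seq_len(js)],
                           waive = waive, force = FALSE, basecut = basecut)
    right <- vgp_hirschberg(sc[seq.int(h + 1L, n), seq.int(js + 1L, length.out = m - js), drop = FALSE],
                            goA[seq.int(h + 1L, n)], geA[seq.int(h + 1L, n)],
                            goB[seq.int(js + 1L, length.out = m - js)],
                            geB[seq.int(js + 1L, length.out = m - js)],
                            waive = FALSE, force = force, basecut = basecut)
  } else {
    js <- which.max(tot2) - 1L
    left <- vgp_hirschberg(sc[seq_len(h), seq_len(js), drop = FALSE],
                           goA[seq_len(h)], geA[seq_len(h)],
                           goB[seq_len(js)], geB[seq_len(js)],
                           waive = waive, force = TRUE, basecut = basecut)
    right <- vgp_hirschberg(sc[seq.int(h + 1L, n), seq.int(js + 1L, length.out = m - js), drop = FALSE],
                            goA[seq.int(h + 1L, n)], geA[seq.int(h + 1L, n)],
                            goB[seq.int(js + 1L, length.out = m - js)],
                            geB[seq.int(js + 1L, length.out = m - js)],
                            waive = TRUE, force = force, basecut = basecut)
  }
  c(left, right)
}

# score of a trace under the run-based gap cost (independent of the DP
# tables; used as the reported score of the linear-space path)
score_trace <- function(codes, sc, goA, geA, goB, geB) {
  i <- 0L; j <- 0L; prev <- 0L
  total <- 0
  for (cd in codes) {
    if (cd == 1L) {
      i <- i + 1L; j <- j + 1L
      total <- total + sc[i, j]
    } else if (cd == 2L) {
      i <- i + 1L
      total <- total - geA[i] - (if (prev == 2L) 0 else goA[i])
    } else {
      j <- j + 1L
      total <- total - geB[j] - (if (prev == 3L) 0 else goB[j])
    }
    prev <- cd
  }
  total
}

#' Align two profiles with variable gap penalties
#'
#' Global three-state dynamic programming in which a gap run over
#' positions `i1..i2` of one profile costs that profile's
#' `gpo[i1] + sum(gpe[i1..i2])`; column pairs score by
#' [column_score()].  With `linear_space = TRUE` the trace is found by
#' divide-and-conquer over the middle row with forward/backward state
#' vectors (linear memory, same score).
#'
#' @param A,B [new_profile()] objects with penalties attached.
#' @param S Substitution matrix (default [load_gonnet250()]).
#' @param linear_space Use the divide-and-conquer trace (default `FALSE`).
#' @return An object of class `alignment_result`: fields `profile` (the
#'   merged [new_profile()] with penalties combined by
#'   [merge_gap_penalties()]), `score`, and `trace` (two-column matrix of
#'   consumed column indices, `NA` at gaps).
#' @export
align_pair <- function(A, B, S = load_gonnet250(), linear_space = FALSE) {
  stopifnot(inherits(A, "profile_aln"), inherits(B, "profile_aln"))
  if (any(c("X") %in% unlist(strsplit(c(A$rows, B$rows), ""))))
    S <- expand_wildcard(S)
  sc <- score_grid(A, B, S)
  goA <- A$penalties$gpo; geA <- A$penalties$gpe
  goB <- B$penalties$gpo; geB <- B$penalties$gpe
  if (linear_space) {
    codes <- vgp_hirschberg(sc, goA, geA, goB, geB)
    score <- score_trace(codes, sc, goA, geA, goB, geB)
  } else {
    full <- vgp_dp_full(sc, goA, geA, goB, geB)
    codes <- full$codes
    score <- full$score
  }
  trace <- codes_to_trace(codes)
  merged_rows <- c(expand_rows(A$rows, codes, gap_code = 3L),
                   expand_rows(B$rows, codes, gap_code = 2L))
  pen <- merge_gap_penalties(A$penalties, B$penalties, trace)
  structure(list(profile = new_profile(c(A$ids, B$ids), merged_rows, pen),
                 score = score, trace = trace),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> %d sequences x %d columns, score %.4f\n",
              length(x$profile$ids), nchar(x$profile$rows[1L]), x$score))
  invisible(x)
}

codes_to_trace <- function(codes) {
  i <- 0L; j <- 0L
  tr <- matrix(NA_integer_, length(codes), 2L, dimnames = list(NULL, c("a", "b")))
  for (k in seq_along(codes)) {
    if (codes[k] != 3L) { i <- i + 1L; tr[k, 1L] <- i }
    if (codes[k] != 2L) { j <- j + 1L; tr[k, 2L] <- j }
  }
  tr
}

# insert '-' into each row wherever the trace skips this profile
expand_rows <- function(rows, codes, gap_code) {
  keep <- codes != gap_code
  vapply(rows, function(r) {
    out <- rep("-", length(codes))
    out[keep] <- strsplit(r, "")[[1L]]
    paste(out, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Recover the unaligned sequences from an alignment result
#'
#' Removes gaps from each merged row; by construction this reproduces the
#' member sequences of both inputs, in order (A's members then B's).
#'
#' @param r An [align_pair()] result.
#' @param strict Residue validation mode.
#' @return List of [protein_sequence()] objects.
#' @export
dealign <- function(r, strict = TRUE) {
  stopifnot(inherits(r, "alignment_result"))
  mapply(function(id, row) protein_sequence(id, gsub("-", "", row, fixed = TRUE),
                                            strict = strict),
         r$profile$ids, r$profile$rows, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Convert an alignment result or profile to a multiple alignment
#'
#' @param x An `alignment_result` or `profile_aln`.
#' @param strict Residue validation mode.
#' @return A [multiple_alignment()].
#' @export
as_multiple_alignment <- function(x, strict = TRUE) {
  if (inherits(x, "alignment_result")) x <- x$profile
  multiple_alignment(x$ids, x$rows, strict = strict)
}
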