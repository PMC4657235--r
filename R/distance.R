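#' Approximate-matching pairwise identity
#'
#' One-error pattern-matching identity in the style of the Muth-Manber
#' string matching algorithm: every length-`k` word of the shorter
#' sequence is compared against all words of the longer sequence; word
#' pairs differing in at most one position credit the matched fraction
#' `(k - mismatches)/k` and the identity is the mean of the best credit
#' per word.  For `ABCABCABC` vs `ABDABDABD` with `k = 3` every word
#' matches with exactly one mismatch, giving 2/3 (the two sequences are
#' 67% identical), where exact k-tuple matching reports 0.
#'
#' @param a,b [protein_sequence()] objects or character strings of length
#'   at least `k`.
#' @param k Word (pattern) length; 3 by default, the usual short-pattern
#'   length for protein searches.
#' @return Identity fraction in `[0, 1]`.
#' @export
mm_identity <- function(a, b, k = 3L) {
  wa <- words_of(a, k); wb <- words_of(b, k)
  if (ncol(wa) > ncol(wb)) { tmp <- wa; wa <- wb; wb <- tmp }  # wa: shorter
  credit <- numeric(ncol(wa))
  for (i in seq_len(ncol(wa))) {
    mism <- colSums(wb != wa[, i])
    ok <- mism <= 1L
    credit[i] <- if (any(ok)) max((k - mism[ok]) / k) else 0
  }
  mean(credit)
}

#' Exact k-tuple pairwise identity
#'
#' Fraction of the shorter sequence's length-`k` words with an exact
#' match anywhere in the longer sequence; the classical k-tuple distance
#' heuristic the approximate matcher improves on.
#'
#' @inheritParams mm_identity
#' @return Identity fraction in `[0, 1]`.
#' @export
ktuple_identity <- function(a, b, k = 3L) {
  wa <- words_of(a, k); wb <- words_of(b, k)
  if (ncol(wa) > ncol(wb)) { tmp <- wa; wa <- wb; wb <- tmp }
  sa <- apply(wa, 2L, paste, collapse = "")
  sb <- apply(wb, 2L, paste, collapse = "")
  mean(sa %in% sb)
}

# k x (n-k+1) character matrix of all length-k words
words_of <- function(x, k) {
  txt <- if (inherits(x, "protein_seq")) x$residues else as.character(x)
  n <- nchar(txt)
  if (n < k) stop(sprintf("sequence of length %d is shorter than the pattern length k=%d", n, k))
  ch <- strsplit(txt, "")[[1L]]
  vapply(seq_len(n - k + 1L), function(i) ch[i:(i + k - 1L)], character(k))
}

#' Pairwise distance matrix
#'
#' `d[i, j] = 1 - mm_identity(seqs[[i]], seqs[[j]], k)`: symmetric with a
#' zero diagonal and entries in `[0, 1]`.
#'
#' @param seqs List of at least two [protein_sequence()] objects, each of
#'   length at least `k`.
#' @param k Pattern length (default 3).
#' @return Symmetric numeric matrix with sequence ids as dimnames.
#' @export
distance_matrix <- function(seqs, k = 3L) {
  n <- length(seqs)
  if (n < 2L) stop("need at least two sequences")
  ids <- vapply(seqs, function(s) if (inherits(s, "protein_seq")) s$id else NA_character_, "")
  if (anyNA(ids)) ids <- paste0("s", seq_len(n) - 1L)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    d[i, j] <- d[j, i] <- 1 - mm_identity(seqs[[i]], seqs[[j]], k)
  }
  d
}

#' Write a distance matrix as TSV
#'
#' Square matrix with a header row of ids.
#'
#' @param d Matrix from [distance_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_distance_tsv <- function(d, path) {
  utils::write.table(format(d, digits = 6), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}
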