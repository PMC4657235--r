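#' Gap penalty pair
#'
#' Per-position (or per-column, for profiles) gap opening and extension
#' penalties, stored as non-negative magnitudes that the aligner
#' subtracts.
#'
#' @param gpo,gpe Equal-length non-negative numeric vectors.
#' @return An object of class `gap_penalties`.
#' @export
gap_penalties <- function(gpo, gpe) {
  gpo <- as.numeric(gpo); gpe <- as.numeric(gpe)
  if (length(gpo) != length(gpe))
    stop("gpo and gpe must have equal length")
  if (any(!is.finite(gpo)) || any(!is.finite(gpe)) || any(gpo < 0) || any(gpe < 0))
    stop("gap penalties must be finite and >= 0")
  structure(list(gpo = gpo, gpe = gpe), class = "gap_penalties")
}

#' @export
print.gap_penalties <- function(x, ...) {
  cat(sprintf("<gap_penalties> %d positions, gpo in [%.3g, %.3g]\n",
              length(x$gpo), min(x$gpo), max(x$gpo)))
  invisible(x)
}

#' Position-specific gap opening penalties from a scan
#'
#' For window starts `i = 1..n-L+1` the penalty is
#' `min(lppm[i], rppm[i])`; the last `L-1` positions, which have no
#' window of their own, repeat the value at `n-L+1`.
#'
#' @param scan A [scan_sequence()] result.
#' @param n Sequence length; must equal `length(scan$lppm) + L - 1`.
#' @return Numeric vector of length `n`.
#' @export
opening_penalties <- function(scan, n) {
  stopifnot(inherits(scan, "scan_result"))
  m <- length(scan$lppm)
  if (length(scan$rppm) != m)
    stop("lppm and rppm have different lengths")
  if (n != m + scan$L - 1L)
    stop(sprintf("inconsistent lengths: n=%d but scan covers %d window starts with L=%d",
                 n, m, scan$L))
  head_vals <- pmin(scan$lppm, scan$rppm)
  c(head_vals, rep(head_vals[m], n - m))
}

#' Region-specific gap extension penalties
#'
#' Zero inside any IndelFR interval, otherwise equal to the opening
#' penalty at the same position: extending a gap is free exactly where an
#' indel is predicted to be plausible.
#'
#' @param gpo Numeric vector of opening penalties.
#' @param ifrs Two-column 0-based half-open interval matrix (or `NULL`).
#' @return Numeric vector of the same length as `gpo`.
#' @export
extension_penalties <- function(gpo, ifrs = NULL) {
  n <- length(gpo)
  ifrs <- normalize_intervals(ifrs, n)
  gpe <- gpo
  if (nrow(ifrs) > 0L) for (k in seq_len(nrow(ifrs))) {
    gpe[seq.int(ifrs[k, 1L] + 1L, ifrs[k, 2L])] <- 0
  }
  gpe
}

#' Merge the gap penalties of two aligned profiles
#'
#' Column-wise rule for the profile produced by aligning profiles A and B:
#' where a column of A is aligned to a column of B the merged penalty is
#' the sum of the two; where B has a gap the merged penalty is A's value
#' alone, and symmetrically.  The extension penalty is merged by the
#' identical rule, so zero-extension (IndelFR) columns stay zero when
#' copied through a gap column.  Repeated merging therefore keeps each
#' column's opening penalty equal to the sum of the single-sequence
#' penalties of the residues present in it.
#'
#' @param pA,pB [gap_penalties()] of the two profiles.
#' @param trace Two-column integer matrix, one row per merged column:
#'   `(j, k)` for both-aligned, `(j, NA)` for gap-in-B, `(NA, k)` for
#'   gap-in-A; the `j`/`k` indices must consume `pA`/`pB` in order,
#'   exactly once each.
#' @return Merged [gap_penalties()] with one entry per trace row.
#' @export
merge_gap_penalties <- function(pA, pB, trace) {
  stopifnot(inherits(pA, "gap_penalties"), inherits(pB, "gap_penalties"))
  trace <- matrix(as.integer(as.matrix(trace)), ncol = 2L)
  ja <- trace[!is.na(trace[, 1L]), 1L]
  kb <- trace[!is.na(trace[, 2L]), 2L]
  if (!identical(ja, seq_along(pA$gpo)) || !identical(kb, seq_along(pB$gpo)))
    stop("trace must consume all positions of both inputs exactly once, in order")
  merge1 <- function(va, vb) {
    out <- numeric(nrow(trace))
    for (i in seq_len(nrow(trace))) {
      j <- trace[i, 1L]; k <- trace[i, 2L]
      out[i] <- if (!is.na(j) && !is.na(k)) va[j] + vb[k]
                else if (!is.na(j)) va[j] else vb[k]
    }
    out
  }
  gap_penalties(merge1(pA$gpo, pB$gpo), merge1(pA$gpe, pB$gpe))
}
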