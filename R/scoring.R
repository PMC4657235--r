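#' Reference alignment with core blocks
#'
#' Core blocks are the reference columns for which a reliable alignment
#' is known; only they are scored.  Without a mask every column is core.
#'
#' @param aln A [multiple_alignment()].
#' @param core_mask Logical vector, one entry per column (`TRUE` = core),
#'   or `NULL` for all-core.
#' @return An object of class `reference_alignment`.
#' @export
reference_alignment <- function(aln, core_mask = NULL) {
  stopifnot(inherits(aln, "multiple_alignment"))
  w <- alignment_width(aln)
  if (is.null(core_mask)) core_mask <- rep(TRUE, w)
  core_mask <- as.logical(core_mask)
  if (length(core_mask) != w)
    stop(sprintf("core mask has %d entries for %d columns", length(core_mask), w))
  if (!any(core_mask)) stop("reference has no core columns to score")
  structure(list(alignment = aln, core_mask = core_mask),
            class = "reference_alignment")
}

#' Read a core-block mask file
#'
#' Plain text of 1-based inclusive column ranges (`a-b`, whitespace or
#' newline separated; `#` comments ignored).
#'
#' @param path Mask file path.
#' @param width Number of reference columns.
#' @return Logical vector of length `width`.
#' @export
read_core_mask <- function(path, width) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  toks <- unlist(strsplit(trimws(lines), "\\s+"))
  toks <- toks[nzchar(toks)]
  mask <- rep(FALSE, width)
  for (tk in toks) {
    m <- regmatches(tk, regexec("^([0-9]+)-([0-9]+)$", tk))[[1L]]
    if (length(m) != 3L) stop(sprintf("malformed core-block range '%s'", tk))
    a <- as.integer(m[2L]); b <- as.integer(m[3L])
    if (a < 1L || b > width || a > b)
      stop(sprintf("core-block range '%s' outside [1, %d]", tk, width))
    mask[a:b] <- TRUE
  }
  mask
}

# residue-index bookkeeping shared by both metrics: for each sequence,
# the test column occupied by each residue, and the reference rows as
# residue-index-per-column matrices
scoring_state <- function(test, ref) {
  stopifnot(inherits(test, "multiple_alignment"),
            inherits(ref, "reference_alignment"))
  raln <- ref$alignment
  if (!setequal(test$ids, raln$ids))
    stop("test and reference alignments contain different sequence ids")
  ord <- match(raln$ids, test$ids)
  degap <- function(r) gsub("-", "", r, fixed = TRUE)
  if (!identical(degap(test$rows[ord]), degap(raln$rows)))
    stop("test and reference disagree on the unaligned residues of some sequence")
  n <- length(raln$ids)
  res_idx <- function(row) {           # per column: residue index or NA
    ch <- strsplit(row, "")[[1L]] != "-"
    idx <- cumsum(ch)
    idx[!ch] <- NA_integer_
    idx
  }
  test_col <- lapply(test$rows[ord], function(row) {  # per residue: column
    ch <- strsplit(row, "")[[1L]] != "-"
    which(ch)
  })
  ref_idx <- do.call(rbind, lapply(raln$rows, res_idx))  # n x width
  list(n = n, ref_idx = ref_idx, test_col = test_col,
       core = which(ref$core_mask))
}

#' Sum-of-pairs score of a test alignment
#'
#' The fraction of aligned residue pairs in the reference's core columns
#' that the test alignment recovers: a reference pair (two residues of
#' different sequences sharing a core column) is correct when the same
#' two residues share a column of the test alignment.
#'
#' @param test A [multiple_alignment()] of the same sequences.
#' @param ref A [reference_alignment()] (a bare `multiple_alignment` is
#'   promoted with an all-core mask).
#' @return SP in `[0, 1]`.
#' @export
sp_score <- function(test, ref) {
  if (inherits(ref, "multiple_alignment")) ref <- reference_alignment(ref)
  st <- scoring_state(test, ref)
  total <- 0L; correct <- 0L
  for (col in st$core) {
    present <- which(!is.na(st$ref_idx[, col]))
    if (length(present) < 2L) next
    cols <- vapply(present, function(s) st$test_col[[s]][st$ref_idx[s, col]], 0L)
    for (a in seq_len(length(present) - 1L)) {
      eqs <- cols[(a + 1L):length(present)] == cols[a]
      total <- total + length(eqs)
      correct <- correct + sum(eqs)
    }
  }
  if (total == 0L) stop("reference core blocks contain no aligned residue pairs")
  correct / total
}

#' Total-column score of a test alignment
#'
#' The fraction of aligned core columns of the reference (columns with at
#' least two residues) whose residues all share a single column of the
#' test alignment.  Equals [sp_score()] for pairwise alignments.
#'
#' @inheritParams sp_score
#' @return TC in `[0, 1]`.
#' @export
tc_score <- function(test, ref) {
  if (inherits(ref, "multiple_alignment")) ref <- reference_alignment(ref)
  st <- scoring_state(test, ref)
  total <- 0L; correct <- 0L
  for (col in st$core) {
    present <- which(!is.na(st$ref_idx[, col]))
    if (length(present) < 2L) next
    cols <- vapply(present, function(s) st$test_col[[s]][st$ref_idx[s, col]], 0L)
    total <- total + 1L
    if (all(cols == cols[1L])) correct <- correct + 1L
  }
  if (total == 0L) stop("reference core blocks contain no aligned columns")
  correct / total
}
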