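#' @keywords internal
"_PACKAGE"

AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Protein sequence
#'
#' A validated amino-acid sequence over the 20 standard residue letters.
#' In strict mode (the default) any non-standard letter (B, J, O, U, X, Z,
#' or anything else) is rejected; in permissive mode non-standard letters
#' are mapped to the wildcard `X`, which scores against every residue as
#' the row minimum of the substitution matrix.
#'
#' @param id Non-empty identifier without whitespace.
#' @param residues Character scalar of residues (uppercased on input).
#' @param description Optional free-text description.
#' @param strict Reject non-standard residue letters (default `TRUE`).
#' @return An object of class `protein_seq` with fields `id`,
#'   `description`, `residues`.
#' @export
protein_sequence <- function(id, residues, description = "", strict = TRUE) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id) || grepl("\\s", id))
    stop("sequence id must be a non-empty string without whitespace")
  residues <- toupper(as.character(residues))
  if (length(residues) != 1L || !nzchar(residues))
    stop(sprintf("record '%s': empty sequence", id))
  chars <- strsplit(residues, "")[[1]]
  bad <- !(chars %in% AA_ALPHABET20)
  if (any(bad)) {
    if (strict) {
      stop(sprintf("record '%s': illegal residue character(s) %s",
                   id, paste(unique(chars[bad]), collapse = ", ")))
    }
    chars[bad] <- "X"
    residues <- paste(chars, collapse = "")
  }
  structure(list(id = id, description = as.character(description),
                 residues = residues),
            class = "protein_seq")
}

#' @export
print.protein_seq <- function(x, ...) {
  cat(sprintf("<protein_seq> %s (%d aa)\n", x$id, nchar(x$residues)))
  invisible(x)
}

#' Length of a protein sequence
#' @param x A `protein_seq`.
#' @return Number of residues.
#' @export
seq_length <- function(x) nchar(x$residues)

as_residue_vector <- function(x) strsplit(x$residues, "")[[1]]

#' Annotated protein sequence
#'
#' A protein sequence carrying a position-specific gap opening penalty and
#' predicted indel flanking region (IndelFR) intervals, the payload of the
#' annotated FASTA dialect.  Intervals are stored 0-based half-open in
#' memory; the file format is 1-based inclusive.
#'
#' @param seq A [protein_sequence()].
#' @param gpo Numeric vector of non-negative gap opening penalties, one per
#'   residue.
#' @param ifrs Two-column matrix (`start`, `end`) of 0-based half-open
#'   intervals, sorted and pairwise disjoint, or `NULL` for none.
#' @return An object of class `annotated_seq`.
#' @export
annotated_sequence <- function(seq, gpo, ifrs = NULL) {
  stopifnot(inherits(seq, "protein_seq"))
  n <- seq_length(seq)
  gpo <- as.numeric(gpo)
  if (length(gpo) != n)
    stop(sprintf("record '%s': #GPO has %d values but sequence has %d residues",
                 seq$id, length(gpo), n))
  if (any(!is.finite(gpo)) || any(gpo < 0))
    stop(sprintf("record '%s': gap opening penalties must be finite and >= 0", seq$id))
  ifrs <- normalize_intervals(ifrs, n, seq$id)
  structure(list(seq = seq, gpo = gpo, ifrs = ifrs), class = "annotated_seq")
}

# validate / sort / check disjointness; intervals 0-based half-open in [0, n)
normalize_intervals <- function(ifrs, n, id = "?") {
  if (is.null(ifrs) || (is.matrix(ifrs) && nrow(ifrs) == 0L))
    return(matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  ifrs <- matrix(as.numeric(ifrs), ncol = 2L,
                 dimnames = list(NULL, c("start", "end")))
  if (any(ifrs[, 1L] < 0) || any(ifrs[, 2L] > n) || any(ifrs[, 1L] >= ifrs[, 2L]))
    stop(sprintf("record '%s': IndelFR interval outside [0, %d) or empty", id, n))
  ifrs <- ifrs[order(ifrs[, 1L]), , drop = FALSE]
  if (nrow(ifrs) > 1L && any(ifrs[-1L, 1L] < ifrs[-nrow(ifrs), 2L]))
    stop(sprintf("record '%s': IndelFR intervals overlap", id))
  ifrs
}

#' @export
print.annotated_seq <- function(x, ...) {
  cat(sprintf("<annotated_seq> %s (%d aa, %d IndelFR interval(s))\n",
              x$seq$id, seq_length(x$seq), nrow(x$ifrs)))
  invisible(x)
}

#' Multiple alignment container
#'
#' Equal-length gapped rows over sequence ids.  Construction enforces that
#' no column is all-gap and that every de-gapped row is a valid protein
#' sequence.  `'.'` gap characters are normalized to `'-'`.
#'
#' @param ids Character vector of sequence ids.
#' @param rows Character vector of gapped rows, same length as `ids`.
#' @param strict Residue validation mode, see [protein_sequence()].
#' @return An object of class `multiple_alignment` with fields `ids`, `rows`.
#' @export
multiple_alignment <- function(ids, rows, strict = TRUE) {
  ids <- as.character(ids); rows <- toupper(as.character(rows))
  if (length(ids) != length(rows) || length(ids) == 0L)
    stop("ids and rows must be non-empty and of equal length")
  if (anyDuplicated(ids)) stop("duplicate sequence ids in alignment")
  rows <- gsub(".", "-", rows, fixed = TRUE)
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("alignment rows have unequal lengths")
  mat <- do.call(rbind, strsplit(rows, ""))
  if (any(colSums(mat != "-") == 0L)) stop("alignment contains an all-gap column")
  for (i in seq_along(ids)) {  # validates residues
    protein_sequence(ids[i], gsub("-", "", rows[i], fixed = TRUE), strict = strict)
  }
  structure(list(ids = ids, rows = rows), class = "multiple_alignment")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat(sprintf("<multiple_alignment> %d sequences x %d columns\n",
              length(x$ids), nchar(x$rows[1L])))
  invisible(x)
}

#' Number of columns in a multiple alignment
#' @param x A `multiple_alignment`.
#' @return Integer column count.
#' @export
alignment_width <- function(x) nchar(x$rows[1L])
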