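#' Read protein sequences from FASTA
#'
#' Multi-line records are concatenated and descriptions (text after the
#' first whitespace in the header) preserved.  Lines beginning with `#`
#' are ignored, so annotated-FASTA files are readable as plain FASTA.
#'
#' @param path Path to a FASTA file.
#' @param strict Residue validation mode, see [protein_sequence()].
#' @return List of [protein_sequence()] objects in file order.
#' @export
read_fasta <- function(path, strict = TRUE) {
  recs <- fasta_records(path)
  lapply(recs, function(r)
    protein_sequence(r$id, r$residues, r$description, strict = strict))
}

# shared low-level FASTA splitter (Biostrings tolerates the '#' comment
# lines of the annotated dialect only via format="fasta" comment stripping,
# so records are pre-split here and residue text handed to the validators)
fasta_records <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(sprintf("empty FASTA file: %s", path))
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L || hdr[1L] != 1L)
    stop(sprintf("not FASTA-formatted (no leading '>'): %s", path))
  bounds <- c(hdr, length(lines) + 1L)
  lapply(seq_along(hdr), function(k) {
    h <- sub("^>", "", lines[hdr[k]])
    id <- sub("\\s.*$", "", h)
    desc <- if (grepl("\\s", h)) sub("^\\S+\\s+", "", h) else ""
    body <- lines[seq.int(hdr[k] + 1L, bounds[k + 1L] - 1L)]
    if (hdr[k] + 1L > bounds[k + 1L] - 1L) body <- character(0)
    meta <- grepl("^#", body)
    res <- gsub("\\s", "", paste(body[!meta], collapse = ""))
    if (!nzchar(res)) stop(sprintf("record '%s': empty sequence", id))
    list(id = id, description = desc, residues = res, meta = body[meta])
  })
}

#' Write protein sequences to FASTA
#'
#' @param seqs Non-empty list of [protein_sequence()] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  if (length(seqs) == 0L) stop("refusing to write an empty sequence list")
  set <- Biostrings::BStringSet(vapply(seqs, `[[`, "", "residues"))
  names(set) <- vapply(seqs, function(s)
    trimws(paste(s$id, s$description)), "")
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read an annotated-FASTA file
#'
#' The dialect appends two comment-style lines to each record, after its
#' sequence lines: `#GPO v1 v2 ... vn` (one non-negative real per residue)
#' and `#IFR a-b c-d ...` (1-based inclusive IndelFR intervals, possibly
#' empty).  Intervals are converted to the in-memory 0-based half-open
#' representation.
#'
#' @param path Path to an annotated-FASTA file.
#' @param strict If `TRUE` a record lacking its `#GPO` line is an error;
#'   also controls residue validation.
#' @return List of [annotated_sequence()] objects.
#' @export
read_annotated_fasta <- function(path, strict = TRUE) {
  recs <- fasta_records(path)
  lapply(recs, function(r) {
    ps <- protein_sequence(r$id, r$residues, r$description, strict = strict)
    n <- seq_length(ps)
    gline <- grep("^#GPO\\b", r$meta, value = TRUE)
    iline <- grep("^#IFR\\b", r$meta, value = TRUE)
    if (length(gline) == 0L) {
      if (strict) stop(sprintf("record '%s': missing #GPO block", r$id))
      gpo <- rep(0, n)
    } else {
      gpo <- suppressWarnings(as.numeric(strsplit(trimws(sub("^#GPO", "", gline[1L])), "\\s+")[[1L]]))
      if (anyNA(gpo)) stop(sprintf("record '%s': non-numeric #GPO value", r$id))
    }
    ifrs <- NULL
    if (length(iline) > 0L) {
      toks <- strsplit(trimws(sub("^#IFR", "", iline[1L])), "\\s+")[[1L]]
      toks <- toks[nzchar(toks)]
      if (length(toks) > 0L) {
        m <- regmatches(toks, regexec("^([0-9]+)-([0-9]+)$", toks))
        if (any(lengths(m) != 3L))
          stop(sprintf("record '%s': malformed #IFR interval", r$id))
        a <- as.integer(vapply(m, `[`, "", 2L))
        b <- as.integer(vapply(m, `[`, "", 3L))
        if (any(a < 1L) || any(b > n) || any(a > b))
          stop(sprintf("record '%s': #IFR interval outside [1, %d]", r$id, n))
        ifrs <- cbind(start = a - 1L, end = b)  # 1-based incl -> 0-based half-open
      }
    }
    annotated_sequence(ps, gpo, ifrs)
  })
}

#' Write annotated-FASTA
#'
#' Emits each record as a standard FASTA record (60 residues per line)
#' followed by its `#GPO` line (4 decimal places) and `#IFR` line (1-based
#' inclusive intervals; the tag alone when there are none).
#'
#' @param seqs List of [annotated_sequence()] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotated_fasta <- function(seqs, path) {
  if (length(seqs) == 0L) stop("refusing to write an empty sequence list")
  con <- file(path, "w")
  on.exit(close(con))
  for (a in seqs) {
    hdr <- trimws(paste(a$seq$id, a$seq$description))
    writeLines(paste0(">", hdr), con)
    res <- a$seq$residues
    starts <- seq.int(1L, nchar(res), by = 60L)
    writeLines(substring(res, starts, pmin(starts + 59L, nchar(res))), con)
    writeLines(paste("#GPO", paste(sprintf("%.4f", a$gpo), collapse = " ")), con)
    if (nrow(a$ifrs) == 0L) {
      writeLines("#IFR", con)
    } else {
      iv <- sprintf("%d-%d", as.integer(a$ifrs[, 1L]) + 1L, as.integer(a$ifrs[, 2L]))
      writeLines(paste("#IFR", paste(iv, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read an aligned FASTA file as a multiple alignment
#'
#' @param path Path to aligned FASTA (gap characters `-` or `.`).
#' @param strict Residue validation mode.
#' @return A [multiple_alignment()].
#' @export
read_alignment <- function(path, strict = TRUE) {
  recs <- fasta_records(path)
  multiple_alignment(vapply(recs, `[[`, "", "id"),
                     vapply(recs, `[[`, "", "residues"),
                     strict = strict)
}

#' Write a multiple alignment as aligned FASTA
#'
#' @param aln A [multiple_alignment()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(aln, path) {
  set <- Biostrings::BStringSet(aln$rows)
  names(set) <- aln$ids
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Load the GONNET250 substitution matrix
#'
#' The packaged 250-PAM Gonnet log-odds matrix over the 20 standard
#' residues.
#'
#' @return A symmetric 20x20 numeric matrix with residue-labelled
#'   dimnames, of class `c("substitution_matrix", "matrix", "array")`.
#' @export
load_gonnet250 <- function() {
  path <- system.file("extdata", "gonnet250.txt", package = "indelmsa",
                      mustWork = TRUE)
  read_substitution_matrix(path)
}

#' Read a substitution matrix from a text file
#'
#' Whitespace-delimited square matrix with a header row of residue labels
#' and a leading label on each row; `#` comment lines are skipped.
#'
#' @param path Path to the matrix file.
#' @return Symmetric labelled numeric matrix (see [load_gonnet250()]).
#' @export
read_substitution_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  labels <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  k <- length(labels)
  rows <- lapply(lines[-1L], function(l) strsplit(trimws(l), "\\s+")[[1L]])
  if (length(rows) != k || any(lengths(rows) != k + 1L))
    stop(sprintf("malformed substitution matrix file: %s", path))
  m <- t(vapply(rows, function(r) as.numeric(r[-1L]), numeric(k)))
  dimnames(m) <- list(vapply(rows, `[`, "", 1L), labels)
  if (!identical(rownames(m), colnames(m)) || max(abs(m - t(m))) > 1e-9)
    stop("substitution matrix is not symmetric")
  class(m) <- c("substitution_matrix", class(matrix()))
  m
}

# add a wildcard 'X' row/column scoring as the row minimum (permissive
# mode maps non-standard letters to X; conservative penalty by design)
expand_wildcard <- function(S) {
  if ("X" %in% rownames(S)) return(S)
  xm <- apply(S, 1L, min)
  S2 <- rbind(cbind(unclass(S), X = xm), X = c(xm, min(xm)))
  class(S2) <- class(S)
  S2
}
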