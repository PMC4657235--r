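#' Pipeline configuration
#'
#' Collects the pipeline's tunable constants: word length `k` for the
#' pairwise distances, scan window `L`, PPM order `D`, substitution
#' matrix, IndelFR extraction parameters, the linear-space flag, and the
#' alphabet mode.
#'
#' @param k Distance pattern length (default 3).
#' @param L Scan window length (default 10).
#' @param D PPM order (default 4); must satisfy `L >= D + 1`.
#' @param matrix Substitution matrix: the name `"GONNET250"` or a matrix
#'   from [read_substitution_matrix()].
#' @param extraction IndelFR extraction parameters (see
#'   [indel_predictor()]).
#' @param linear_space Use divide-and-conquer alignment (default `FALSE`).
#' @param strict Strict residue alphabet (default `TRUE`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(k = 3L, L = 10L, D = 4L, matrix = "GONNET250",
                            extraction = list(), linear_space = FALSE,
                            strict = TRUE) {
  k <- as.integer(k); L <- as.integer(L); D <- as.integer(D)
  if (k < 1L) stop("pattern length k must be >= 1")
  if (D < 0L) stop("model order D must be >= 0")
  if (L < D + 1L) stop("window length L must be at least D + 1")
  S <- if (is.character(matrix)) {
    if (toupper(matrix) != "GONNET250")
      stop(sprintf("unknown substitution matrix '%s'", matrix))
    load_gonnet250()
  } else matrix
  structure(list(k = k, L = L, D = D, S = S,
                 extraction = utils::modifyList(list(c = 1.0, W = 30L, smooth = FALSE),
                                                extraction),
                 linear_space = isTRUE(linear_space), strict = isTRUE(strict)),
            class = "pipeline_config")
}

#' Annotate input sequences with an IndelFR predictor
#'
#' Applies [annotate()] to each plain sequence; inputs that are already
#' [annotated_sequence()]s pass through unchanged.  In permissive mode a
#' sequence shorter than the scan window receives a constant opening
#' penalty equal to the mean penalty of the sequences that could be
#' scanned (or the uniform-model log-loss `log2(20)` if none could), and
#' no IndelFRs; in strict mode short sequences are an error.
#'
#' @param seqs List of [protein_sequence()] and/or [annotated_sequence()]
#'   objects.
#' @param pred An [indel_predictor()].
#' @param strict Reject sequences shorter than the window (default
#'   `TRUE`).
#' @return List of [annotated_sequence()] objects, in input order.
#' @export
annotate_inputs <- function(seqs, pred, strict = TRUE) {
  out <- vector("list", length(seqs))
  short <- integer(0)
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    if (inherits(s, "annotated_seq")) {
      out[[i]] <- s
    } else if (seq_length(s) >= pred$L) {
      out[[i]] <- annotate(pred, s)
    } else if (strict) {
      stop(sprintf("sequence '%s' has %d residues; sequences shorter than the scan window (L=%d) cannot be annotated",
                   s$id, seq_length(s), pred$L))
    } else {
      short <- c(short, i)
    }
  }
  if (length(short) > 0L) {
    pool <- unlist(lapply(out[-short], function(a) if (!is.null(a)) a$gpo))
    fallback <- if (length(pool) > 0L) mean(pool) else log2(20)
    for (i in short) {
      s <- seqs[[i]]
      out[[i]] <- annotated_sequence(s, rep(fallback, seq_length(s)))
    }
  }
  out
}

#' Progressive multiple sequence alignment with variable gap penalties
#'
#' Computes approximate-matching pairwise distances, builds a UPGMA guide
#' tree, and aligns sequences/profiles bottom-up along the tree with
#' [align_pair()], merging the per-column gap penalties at every internal
#' node.  The alignment at the root is returned, with rows in input
#' order.
#'
#' @param seqs List of at least one [annotated_sequence()] (unique ids).
#' @param cfg A [pipeline_config()].
#' @return A [multiple_alignment()].
#' @export
run_msa <- function(seqs, cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (length(seqs) == 0L) stop("no input sequences")
  if (!all(vapply(seqs, inherits, TRUE, "annotated_seq")))
    stop("run_msa expects annotated sequences; see annotate_inputs()")
  ids <- vapply(seqs, function(a) a$seq$id, "")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate sequence id '%s'", ids[duplicated(ids)][1L]))
  if (length(seqs) == 1L)
    return(multiple_alignment(ids, seqs[[1L]]$seq$residues, strict = cfg$strict))
  plain <- lapply(seqs, `[[`, "seq")
  d <- distance_matrix(plain, cfg$k)
  tree <- upgma(d)
  profs <- vector("list", nrow(tree$merge))
  get_node <- function(v) if (v < 0L) profile_from_annotated(seqs[[-v]]) else profs[[v]]
  for (nd in seq_len(nrow(tree$merge))) {
    res <- align_pair(get_node(tree$merge[nd, 1L]), get_node(tree$merge[nd, 2L]),
                      cfg$S, linear_space = cfg$linear_space)
    profs[[nd]] <- res$profile
  }
  root <- profs[[nrow(tree$merge)]]
  ord <- match(ids, root$ids)
  multiple_alignment(root$ids[ord], root$rows[ord], strict = cfg$strict)
}
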