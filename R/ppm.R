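#' Train a PPM (prediction by partial match) model
#'
#' Accumulates, for every context length 0..D, the (context, next symbol)
#' counts over all corpus sequences.  Probabilities are later blended with
#' the PPM-C escape scheme (escape count = number of distinct symbols seen
#' after the context, no exclusions), falling back through shorter
#' contexts down to a uniform order-(-1) distribution over the alphabet.
#'
#' @param corpus Non-empty list of [protein_sequence()] objects (or plain
#'   character strings).
#' @param D Maximum context length (memory), an integer >= 0; 4 by default,
#'   the value at which flank predictability saturates.
#' @param alphabet Residue alphabet; the 20 standard amino acids by default.
#' @return An object of class `ppm_model`.
#' @export
train_ppm <- function(corpus, D = 4L, alphabet = AA_ALPHABET20) {
  if (length(corpus) == 0L) stop("empty training corpus")
  D <- as.integer(D)
  if (D < 0L) stop("model order D must be >= 0")
  counts <- new.env(parent = emptyenv(), hash = TRUE)
  for (s in corpus) {
    txt <- if (inherits(s, "protein_seq")) s$residues else as.character(s)
    ch <- strsplit(txt, "")[[1L]]
    if (any(!ch %in% alphabet))
      stop("training sequence contains symbols outside the model alphabet")
    n <- length(ch)
    for (pos in seq_len(n)) {
      for (d in 0:min(D, pos - 1L)) {
        ctx <- if (d == 0L) "" else paste(ch[(pos - d):(pos - 1L)], collapse = "")
        key <- paste0(d, ":", ctx)
        tab <- if (is.null(counts[[key]])) integer(0) else counts[[key]]
        sym <- ch[pos]
        tab[sym] <- if (is.na(tab[sym])) 1L else tab[sym] + 1L
        counts[[key]] <- tab
      }
    }
  }
  structure(list(D = D, alphabet = alphabet, counts = counts,
                 escape = "PPM-C"),
            class = "ppm_model")
}

#' @export
print.ppm_model <- function(x, ...) {
  cat(sprintf("<ppm_model> order D=%d, %d stored contexts, escape %s\n",
              x$D, length(ls(x$counts)), x$escape))
  invisible(x)
}

#' Conditional symbol probability under a PPM model
#'
#' PPM-C blending: at each order `d` from `min(nchar(context), D)` down to
#' 0, a context seen `N` times with `q` distinct successors predicts a
#' seen symbol with weight `count/(N + q)` and escapes with probability
#' `q/(N + q)`; unseen contexts escape with probability 1.  The recursion
#' terminates in a uniform distribution over the alphabet, so the result
#' is always strictly positive and sums to 1 over the alphabet.
#'
#' @param model A `ppm_model`.
#' @param symbol Single residue character.
#' @param context Preceding symbols (any length; only the last
#'   `min(nchar(context), D)` are used).
#' @return Probability in (0, 1].
#' @export
symbol_prob <- function(model, symbol, context = "") UseMethod("symbol_prob")

#' @export
symbol_prob.ppm_model <- function(model, symbol, context = "") {
  if (!symbol %in% model$alphabet)
    stop(sprintf("symbol '%s' outside the model alphabet", symbol))
  ctx <- as.character(context)
  nc <- nchar(ctx)
  d0 <- min(nc, model$D)
  if (d0 > 0L) ctx <- substring(ctx, nc - d0 + 1L, nc)
  p <- 0
  w <- 1
  for (d in seq.int(d0, 0L)) {
    key <- paste0(d, ":", if (d == 0L) "" else substring(ctx, d0 - d + 1L, d0))
    tab <- model$counts[[key]]
    if (!is.null(tab)) {
      N <- sum(tab)
      q <- length(tab)
      cnt <- tab[symbol]
      if (!is.na(cnt)) p <- p + w * cnt / (N + q)
      w <- w * q / (N + q)
    }
  }
  unname(p + w / length(model$alphabet))
}

#' Average log-loss of a window under a PPM model
#'
#' Computes `-(1/L) * sum_k log2 P(window[k] | preceding min(k-1, D)
#' window symbols)`: the k-th term conditions on exactly the symbols of
#' the window before it, capped at the model order.  Low values mean the
#' window resembles the training corpus.
#'
#' @param model A model for which [symbol_prob()] is defined.
#' @param window Character scalar of length `L` (must satisfy
#'   `L >= D + 1` for a `ppm_model`).
#' @param L Expected window length (default: `nchar(window)`).
#' @return Non-negative average log-loss in bits.
#' @export
window_logloss <- function(model, window, L = nchar(window)) {
  if (nchar(window) != L) stop(sprintf("window has %d symbols, expected L=%d",
                                       nchar(window), L))
  if (inherits(model, "ppm_model") && L < model$D + 1L)
    stop("window length L must be at least D + 1")
  ch <- strsplit(window, "")[[1L]]
  D <- if (!is.null(model$D)) model$D else L
  total <- 0
  for (k in seq_len(L)) {
    d <- min(k - 1L, D)
    ctx <- if (d == 0L) "" else paste(ch[(k - d):(k - 1L)], collapse = "")
    total <- total + log2(symbol_prob(model, ch[k], ctx))
  }
  -total / L
}

#' IndelFR predictor: paired left/right PPM models
#'
#' Houses the two variable-order Markov models (one trained on left
#' flanking regions, one on right flanking regions), the scan window
#' length `L`, and the IndelFR extraction parameters.
#'
#' @param left,right `ppm_model`s of equal order, trained on left/right
#'   flank corpora.
#' @param L Scan window length (default 10, beyond which an indel's
#'   influence on its flanks is negligible); must satisfy `L >= D + 1`.
#' @param extraction List of extraction parameters: `c` (anchor depth in
#'   standard deviations below the mean log-loss, default 1.0), `W`
#'   (maximum left-to-right anchor pairing distance, default 30),
#'   `smooth` (apply a width-3 moving average to the log-loss profiles
#'   before anchor search, default `FALSE`).
#' @return An object of class `indel_predictor`.
#' @export
indel_predictor <- function(left, right, L = 10L,
                            extraction = list(c = 1.0, W = 30L, smooth = FALSE)) {
  stopifnot(inherits(left, "ppm_model"), inherits(right, "ppm_model"))
  if (left$D != right$D) stop("left and right models must have equal order D")
  L <- as.integer(L)
  if (L < left$D + 1L) stop("window length L must be at least D + 1")
  defaults <- list(c = 1.0, W = 30L, smooth = FALSE)
  extraction <- utils::modifyList(defaults, extraction)
  structure(list(left = left, right = right, L = L, extraction = extraction),
            class = "indel_predictor")
}

#' @export
print.indel_predictor <- function(x, ...) {
  cat(sprintf("<indel_predictor> D=%d, L=%d, extraction c=%.2f W=%d\n",
              x$left$D, x$L, x$extraction$c, x$extraction$W))
  invisible(x)
}

#' Train an IndelFR predictor from flank corpora
#'
#' @param left_corpus,right_corpus Lists of left/right flanking-region
#'   sequences (see [make_training_corpus()]).
#' @param D Model order (default 4).
#' @param L Scan window length (default 10).
#' @param extraction Extraction parameters, see [indel_predictor()].
#' @return An `indel_predictor`.
#' @export
train_predictor <- function(left_corpus, right_corpus, D = 4L, L = 10L,
                            extraction = list()) {
  indel_predictor(train_ppm(left_corpus, D), train_ppm(right_corpus, D),
                  L = L, extraction = extraction)
}

#' Scan a sequence with an IndelFR predictor
#'
#' Slides a window of length `L` one residue at a time and records the
#' left-model and right-model average log-loss at each window start:
#' `lppm[i]` and `rppm[i]` for `i = 1..n-L+1` (1-based window starts).
#' Windows never cross the sequence end, so the last `L-1` positions have
#' no window of their own (handled by tail padding in
#' [opening_penalties()]).
#'
#' @param pred An [indel_predictor()].
#' @param seq A [protein_sequence()] of length `n >= L`.
#' @return An object of class `scan_result` with numeric fields `lppm`,
#'   `rppm` (length `n - L + 1`) and `L`.
#' @export
scan_sequence <- function(pred, seq) {
  stopifnot(inherits(pred, "indel_predictor"), inherits(seq, "protein_seq"))
  n <- seq_length(seq)
  L <- pred$L
  if (n < L)
    stop(sprintf("sequence '%s' has %d residues; sequences shorter than the scan window (L=%d) cannot be annotated",
                 seq$id, n, L))
  m <- n - L + 1L
  lppm <- numeric(m); rppm <- numeric(m)
  for (i in seq_len(m)) {
    win <- substring(seq$residues, i, i + L - 1L)
    lppm[i] <- window_logloss(pred$left, win, L)
    rppm[i] <- window_logloss(pred$right, win, L)
  }
  structure(list(lppm = lppm, rppm = rppm, L = L), class = "scan_result")
}

#' Extract predicted IndelFR intervals from a scan
#'
#' Deterministic anchor-pairing rule: a position `p` is a left-flank
#' anchor if `lppm[p]` is a strict local minimum and lies below
#' `mean(lppm) - c * sd(lppm)`; right-flank anchors are found analogously
#' on `rppm`.  Each left anchor pairs with the nearest right anchor at
#' most `W` positions downstream, giving the interval
#' `[p, right_anchor + L)` (0-based half-open over sequence positions);
#' unpaired anchors of either kind yield an interval of length `L`.
#' Overlapping intervals are merged.
#'
#' @param scan A [scan_sequence()] result.
#' @param params Extraction parameters (`c`, `W`, `smooth`), as in
#'   [indel_predictor()].
#' @return Sorted, disjoint two-column interval matrix (0-based
#'   half-open); possibly with zero rows.
#' @export
extract_indelfrs <- function(scan, params = list(c = 1.0, W = 30L, smooth = FALSE)) {
  stopifnot(inherits(scan, "scan_result"))
  params <- utils::modifyList(list(c = 1.0, W = 30L, smooth = FALSE), params)
  L <- scan$L
  lp <- scan$lppm; rp <- scan$rppm
  if (isTRUE(params$smooth)) {
    lp <- moving_average3(lp); rp <- moving_average3(rp)
  }
  n <- length(lp) + L - 1L
  la <- find_anchors(lp, params$c)
  ra <- find_anchors(rp, params$c)
  iv <- NULL
  used_r <- logical(length(ra))
  for (p in la) {
    cand <- which(ra >= p & ra <= p + params$W)
    if (length(cand) > 0L) {
      j <- cand[which.min(ra[cand] - p)]
      used_r[j] <- TRUE
      iv <- rbind(iv, c(p - 1L, ra[j] - 1L + L))    # 0-based half-open
    } else {
      iv <- rbind(iv, c(p - 1L, p - 1L + L))
    }
  }
  for (j in which(!used_r)) {
    r <- ra[j]
    if (length(la) == 0L || all(!(la <= r & la >= r - params$W)))
      iv <- rbind(iv, c(r - 1L, r - 1L + L))
  }
  if (is.null(iv))
    return(matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  iv[, 2L] <- pmin(iv[, 2L], n)
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  merge_overlaps(iv)
}

# strict local minima below mean - c*sd (1-based indices into x)
find_anchors <- function(x, c) {
  m <- length(x)
  if (m < 3L) return(integer(0))
  sdx <- stats::sd(x)
  if (!is.finite(sdx) || sdx == 0) return(integer(0))
  thr <- mean(x) - c * sdx
  idx <- 2:(m - 1L)
  idx[x[idx] < x[idx - 1L] & x[idx] < x[idx + 1L] & x[idx] < thr]
}

moving_average3 <- function(x) {
  m <- length(x)
  if (m < 3L) return(x)
  out <- x
  out[2:(m - 1L)] <- (x[1:(m - 2L)] + x[2:(m - 1L)] + x[3:m]) / 3
  out
}

merge_overlaps <- function(iv) {
  out <- iv[1L, , drop = FALSE]
  if (nrow(iv) > 1L) for (k in 2:nrow(iv)) {
    if (iv[k, 1L] <= out[nrow(out), 2L]) {
      out[nrow(out), 2L] <- max(out[nrow(out), 2L], iv[k, 2L])
    } else out <- rbind(out, iv[k, , drop = FALSE])
  }
  colnames(out) <- c("start", "end")
  out
}

#' Annotate a sequence with gap penalties and predicted IndelFRs
#'
#' Scans the sequence, derives the position-specific gap opening penalty
#' profile (elementwise minimum of the left/right log-loss with constant
#' tail padding) and the predicted IndelFR intervals.
#'
#' @param pred An [indel_predictor()].
#' @param seq A [protein_sequence()] with `n >= L`.
#' @return An [annotated_sequence()].
#' @export
annotate <- function(pred, seq) {
  scan <- scan_sequence(pred, seq)
  gpo <- opening_penalties(scan, seq_length(seq))
  ifrs <- extract_indelfrs(scan, pred$extraction)
  annotated_sequence(seq, gpo, ifrs)
}

#' Save an IndelFR predictor to a JSON text file
#'
#' Persists order, window length, alphabet, escape scheme, both models'
#' context counts and the extraction parameters; [load_predictor()]
#' reconstructs [symbol_prob()] bit-exactly.
#'
#' @param pred An [indel_predictor()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_predictor <- function(pred, path) {
  dump_model <- function(m) {
    keys <- sort(ls(m$counts))
    list(D = m$D, alphabet = paste(m$alphabet, collapse = ""),
         escape = m$escape,
         counts = stats::setNames(lapply(keys, function(k) as.list(m$counts[[k]])), keys))
  }
  obj <- list(format = "indelmsa_predictor", version = 1L,
              L = pred$L, extraction = pred$extraction,
              left = dump_model(pred$left), right = dump_model(pred$right))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load an IndelFR predictor from a JSON text file
#'
#' @param path File written by [save_predictor()].
#' @return An [indel_predictor()].
#' @export
load_predictor <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$format, "indelmsa_predictor"))
    stop(sprintf("not a predictor file: %s", path))
  rebuild <- function(m) {
    counts <- new.env(parent = emptyenv(), hash = TRUE)
    for (k in names(m$counts)) {
      counts[[k]] <- vapply(m$counts[[k]], as.integer, 0L)
    }
    structure(list(D = as.integer(m$D),
                   alphabet = strsplit(m$alphabet, "")[[1L]],
                   counts = counts, escape = m$escape),
              class = "ppm_model")
  }
  ex <- obj$extraction
  indel_predictor(rebuild(obj$left), rebuild(obj$right), L = as.integer(obj$L),
                  extraction = list(c = as.numeric(ex$c), W = as.integer(ex$W),
                                    smooth = isTRUE(ex$smooth)))
}
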