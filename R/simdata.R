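# Residue background of indel-prone ("loop") segments: enriched in the
# small/polar/flexible residues that dominate real loop regions, so that
# indel flanks carry a composition signal a flank-trained model can learn.
LOOP_PROFILE <- c(G = 0.16, P = 0.13, S = 0.12, N = 0.10, D = 0.10, E = 0.08,
                  Q = 0.06, K = 0.06, T = 0.06, A = 0.05,
                  R = 0.01, H = 0.01, C = 0.01, F = 0.01, I = 0.01, L = 0.01,
                  M = 0.01, V = 0.01, W = 0.005, Y = 0.005)

#' Simulate a protein family with known alignment and indel sites
#'
#' Star-phylogeny evolution from a random ancestor.  The ancestor
#' alternates conserved "core" blocks (uniform residue background) with
#' indel-prone "loop" blocks drawn from a flexible-residue composition;
#' every descendant receives i.i.d. substitutions at each site and indel
#' events (insertions or deletions of geometric length) anchored inside
#' loop blocks.  The true alignment is built from the recorded edit
#' operations: each ancestor position is one column, and every insertion
#' gets its own private column block.  Events are kept at least two
#' ancestor positions apart so each deletion is exactly one gap run in
#' its own row and each insertion exactly one gap run in every other row.
#'
#' @param ancestor_length Ancestor length (>= 20).
#' @param n_seqs Number of descendants (>= 2).
#' @param sub_prob Per-site substitution probability in `[0, 1]`.
#' @param indel_prob Per-loop-site indel start probability in `[0, 1]`.
#' @param indel_len_mean Mean of the geometric indel length distribution.
#' @param flank Flank length `F` recorded around each indel (default 10).
#' @param seed Random seed; identical seeds give identical families.
#' @param core_len,loop_len Integer ranges (min, max) of core/loop block
#'   lengths.
#' @return An object of class `sim_family`: `true_alignment`
#'   (a [multiple_alignment()]), `sequences` (de-gapped
#'   [protein_sequence()]s), `true_indel_positions` (per-sequence 0-based
#'   half-open interval matrices covering each indel plus/minus the
#'   flank), `events` (per-indel bookkeeping incl. flank strings), and
#'   `params`.
#' @export
simulate_family <- function(ancestor_length = 80L, n_seqs = 5L,
                            sub_prob = 0.15, indel_prob = 0.06,
                            indel_len_mean = 3, flank = 10L, seed = 1L,
                            core_len = c(10L, 16L), loop_len = c(6L, 12L)) {
  if (ancestor_length < 20L) stop("ancestor_length must be at least 20")
  if (n_seqs < 2L) stop("need at least two descendants")
  if (sub_prob < 0 || sub_prob > 1 || indel_prob < 0 || indel_prob > 1)
    stop("probabilities must lie in [0, 1]")
  if (indel_len_mean < 1) stop("indel_len_mean must be >= 1")
  set.seed(as.integer(seed))
  n <- as.integer(ancestor_length)

  # ancestor: alternating core / loop blocks
  anc <- character(0); is_loop <- logical(0)
  loop_now <- FALSE
  while (length(anc) < n) {
    len <- if (loop_now) sample(loop_len[1L]:loop_len[2L], 1L)
           else sample(core_len[1L]:core_len[2L], 1L)
    block <- if (loop_now) sample(names(LOOP_PROFILE), len, TRUE, LOOP_PROFILE)
             else sample(AA_ALPHABET20, len, TRUE)
    anc <- c(anc, block); is_loop <- c(is_loop, rep(loop_now, len))
    loop_now <- !loop_now
  }
  anc <- anc[seq_len(n)]; is_loop <- is_loop[seq_len(n)]

  rgeom_len <- function() 1L + stats::rgeom(1L, 1 / indel_len_mean)

  # per-descendant substitutions and candidate indel events
  subs <- vector("list", n_seqs)
  cand <- NULL   # columns: seq, pos (anchor, 1-based ancestor), type, len
  for (d in seq_len(n_seqs)) {
    row <- anc
    hit <- stats::runif(n) < sub_prob
    if (any(hit)) {
      row[hit & !is_loop] <- sample(AA_ALPHABET20, sum(hit & !is_loop), TRUE)
      row[hit & is_loop] <- sample(names(LOOP_PROFILE), sum(hit & is_loop),
                                   TRUE, LOOP_PROFILE)
    }
    subs[[d]] <- row
    at <- which(is_loop & stats::runif(n) < indel_prob)
    for (p in at) {
      cand <- rbind(cand, data.frame(
        seq = d, pos = p,
        type = if (stats::runif(1L) < 0.5) "del" else "ins",
        len = min(rgeom_len(), 8L), stringsAsFactors = FALSE))
    }
  }
  # global separation >= 2 ancestor positions so gap runs never merge;
  # deletions additionally may not reach the last position
  events <- NULL
  if (!is.null(cand)) {
    cand <- cand[order(cand$pos, cand$seq), , drop = FALSE]
    last_end <- -2L
    for (r in seq_len(nrow(cand))) {
      ev <- cand[r, ]
      if (ev$type == "del") ev$len <- min(ev$len, n - ev$pos)  # keep last column
      if (ev$len < 1L || ev$pos <= last_end + 1L) next
      events <- rbind(events, ev)
      last_end <- ev$pos + (if (ev$type == "del") ev$len - 1L else 0L)
    }
  }
  n_ev <- if (is.null(events)) 0L else nrow(events)

  # deletion membership and insertion payloads
  deleted <- matrix(FALSE, n_seqs, n)
  ins_at <- vector("list", n + 1L)        # insertions anchored before pos p
  if (n_ev > 0L) for (r in seq_len(n_ev)) {
    ev <- events[r, ]
    if (ev$type == "del") {
      deleted[ev$seq, ev$pos:(ev$pos + ev$len - 1L)] <- TRUE
    } else {
      ins_at[[ev$pos]] <- c(ins_at[[ev$pos]], list(list(
        seq = ev$seq,
        res = sample(names(LOOP_PROFILE), ev$len, TRUE, LOOP_PROFILE))))
    }
  }

  # assemble aligned rows column block by column block
  rows <- vector("list", n_seqs)
  for (d in seq_len(n_seqs)) rows[[d]] <- character(0)
  for (p in seq_len(n)) {
    for (ins in ins_at[[p]]) {
      for (d in seq_len(n_seqs)) {
        rows[[d]] <- c(rows[[d]], if (d == ins$seq) ins$res
                                  else rep("-", length(ins$res)))
      }
    }
    for (d in seq_len(n_seqs)) {
      rows[[d]] <- c(rows[[d]], if (deleted[d, p]) "-" else subs[[d]][p])
    }
  }
  rows <- vapply(rows, paste, "", collapse = "")
  ids <- sprintf("seq%02d", seq_len(n_seqs))
  aln <- multiple_alignment(ids, rows)
  seqs <- lapply(seq_len(n_seqs), function(d)
    protein_sequence(ids[d], gsub("-", "", rows[d], fixed = TRUE)))

  # per-event sequence coordinates, flanks, IndelFR-style intervals
  F <- as.integer(flank)
  ev_out <- list(); intervals <- rep(list(NULL), n_seqs)
  if (n_ev > 0L) for (r in seq_len(n_ev)) {
    ev <- events[r, ]
    d <- ev$seq
    res_txt <- seqs[[d]]$residues
    nn <- nchar(res_txt)
    # residues of d preceding ancestor position ev$pos (incl. insertions
    # anchored strictly before it, and d's own insertion at it)
    q <- sum(!deleted[d, seq_len(ev$pos - 1L)])
    if (ev$pos > 1L) for (pp in seq_len(ev$pos - 1L)) {
      for (ins in ins_at[[pp]]) if (ins$seq == d) q <- q + length(ins$res)
    }
    if (ev$type == "ins") {
      start <- q; end <- q + ev$len          # inserted run, 0-based half-open
    } else {
      start <- q; end <- q                    # deletion breakpoint
    }
    lf <- substring(res_txt, max(1L, start - F + 1L), start)
    rf <- substring(res_txt, end + 1L, min(nn, end + F))
    iv <- c(max(0L, start - F), min(nn, end + F))
    intervals[[d]] <- rbind(intervals[[d]], iv)
    ev_out[[length(ev_out) + 1L]] <- list(
      seq = d, type = ev$type, anchor = ev$pos, len = ev$len,
      breakpoint = c(start, end), left_flank = lf, right_flank = rf)
  }
  intervals <- lapply(seq_len(n_seqs), function(d) {
    iv <- intervals[[d]]
    if (is.null(iv))
      return(matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
    iv <- iv[order(iv[, 1L]), , drop = FALSE]
    merge_overlaps(iv)
  })

  structure(list(true_alignment = aln, sequences = seqs,
                 true_indel_positions = intervals, events = ev_out,
                 params = list(ancestor_length = n, n_seqs = n_seqs,
                               sub_prob = sub_prob, indel_prob = indel_prob,
                               indel_len_mean = indel_len_mean, flank = F,
                               seed = as.integer(seed))),
            class = "sim_family")
}

#' @export
print.sim_family <- function(x, ...) {
  cat(sprintf("<sim_family> %d sequences, %d alignment columns, %d indel event(s), seed %d\n",
              length(x$sequences), alignment_width(x$true_alignment),
              length(x$events), x$params$seed))
  invisible(x)
}

#' Flank training corpora from a simulated family
#'
#' For every recorded indel, the up-to-`F` residues immediately left of
#' the indel go to the left corpus and the up-to-`F` residues immediately
#' right to the right corpus.  Only events with both flanks non-empty
#' contribute (so the two corpora always have equal size: the number of
#' indels not abutting a sequence end).
#'
#' @param fam A [simulate_family()] result with at least one indel.
#' @param F Maximum flank length (default: the family's `flank`
#'   parameter).
#' @return List with character vectors `left` and `right`.
#' @export
make_training_corpus <- function(fam, F = fam$params$flank) {
  stopifnot(inherits(fam, "sim_family"))
  if (length(fam$events) == 0L)
    stop("family contains no indel events; nothing to train on")
  left <- character(0); right <- character(0)
  for (ev in fam$events) {
    lf <- ev$left_flank; rf <- ev$right_flank
    if (nchar(lf) > F) lf <- substring(lf, nchar(lf) - F + 1L, nchar(lf))
    if (nchar(rf) > F) rf <- substring(rf, 1L, F)
    if (nzchar(lf) && nzchar(rf)) {
      left <- c(left, lf); right <- c(right, rf)
    }
  }
  list(left = left, right = right)
}
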