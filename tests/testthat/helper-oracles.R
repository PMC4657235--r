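# Exhaustive global-alignment oracle: enumerates every monotone path and
# scores it with the run-based gap cost (a gap run over positions i1..i2
# of one side costs gpo[i1] + sum(gpe[i1..i2]); openings are charged
# afresh after a run of the opposite kind).  Independent of the DP.
bf_align_score <- function(sc, goA, geA, goB, geB) {
  n <- nrow(sc); m <- ncol(sc); best <- -Inf
  rec <- function(i, j, prev, acc) {
    if (i == n && j == m) {
      if (acc > best) best <<- acc
      return(invisible())
    }
    if (i < n && j < m) rec(i + 1L, j + 1L, 1L, acc + sc[i + 1L, j + 1L])
    if (i < n) rec(i + 1L, j, 2L, acc - geA[i + 1L] - if (prev == 2L) 0 else goA[i + 1L])
    if (j < m) rec(i, j + 1L, 3L, acc - geB[j + 1L] - if (prev == 3L) 0 else goB[j + 1L])
  }
  rec(0L, 0L, 0L, 0)
  best
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_protein <- function(id, n) {
  protein_sequence(id, paste(sample(AA20, n, TRUE), collapse = ""))
}

# single-sequence profile with given constant or per-position penalties
make_profile <- function(id, residues, gpo, gpe = NULL, ifrs = NULL) {
  n <- nchar(residues)
  if (length(gpo) == 1L) gpo <- rep(gpo, n)
  a <- annotated_sequence(protein_sequence(id, residues), gpo, ifrs)
  p <- profile_from_annotated(a)
  if (!is.null(gpe)) {
    if (length(gpe) == 1L) gpe <- rep(gpe, n)
    p$penalties <- gap_penalties(gpo, gpe)
  }
  p
}

# random symmetric toy matrix over a small alphabet
rand_matrix <- function(ab, lo = -5, hi = 8) {
  k <- length(ab)
  S <- matrix(stats::runif(k * k, lo, hi), k, k, dimnames = list(ab, ab))
  (S + t(S)) / 2
}
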