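test_that("column scores reduce to matrix entries for single residues", {
  S <- load_gonnet250()
  expect_equal(column_score(c(A = 1), c(W = 1), S), S["A", "W"])
  expect_equal(column_score(c(A = 1), c(A = 1), S), S["A", "A"])
  toy <- matrix(c(4, 0, 0, 1), 2, 2, dimnames = list(c("A", "V"), c("A", "V")))
  expect_equal(column_score(c(A = 1, V = 1), c(A = 1), toy), 2)  # 1/2*4 + 1/2*0
  # gap entries scale by the non-gap fraction
  expect_equal(column_score(c(A = 1, `-` = 1), c(A = 1), toy), 2)
  expect_error(column_score(c(`-` = 2), c(A = 1), toy), "all-gap")
})

test_that("self-alignment with a dominant diagonal is gapless", {
  S <- load_gonnet250()
  set.seed(2)
  s <- rand_protein("s", 30)
  p <- make_profile("a", s$residues, gpo = 5)
  q <- make_profile("b", s$residues, gpo = 5)
  r <- align_pair(p, q, S)
  expect_equal(r$profile$rows[1], s$residues)
  expect_equal(r$profile$rows[2], s$residues)
  ch <- strsplit(s$residues, "")[[1]]
  expect_equal(r$score, sum(diag(S)[match(ch, rownames(S))]))
})

test_that("the DP equals exhaustive enumeration with arbitrary per-position penalties", {
  set.seed(6)
  ab <- c("A", "C", "D", "E")
  for (case in 1:80) {
    n <- sample(1:5, 1); m <- sample(1:5, 1)
    S <- rand_matrix(ab)
    a <- sample(ab, n, TRUE); b <- sample(ab, m, TRUE)
    sc <- S[a, b, drop = FALSE]
    goA <- runif(n, 0, 6); geA <- runif(n, 0, 3)
    goB <- runif(m, 0, 6); geB <- runif(m, 0, 3)
    expect_equal(indelmsa:::vgp_dp_full(sc, goA, geA, goB, geB)$score,
                 bf_align_score(sc, goA, geA, goB, geB), tolerance = 1e-9)
  }
})

test_that("constant penalties agree with an independent affine-gap aligner", {
  S <- load_gonnet250()
  set.seed(16)
  for (case in 1:25) {
    n <- sample(5:40, 1); m <- sample(5:40, 1)
    a <- paste(sample(AA20, n, TRUE), collapse = "")
    b <- paste(sample(AA20, m, TRUE), collapse = "")
    go <- runif(1, 3, 12); ge <- runif(1, 0.2, 2)
    r <- align_pair(make_profile("a", a, go, ge), make_profile("b", b, go, ge), S)
    oracle <- Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = unclass(S), gapOpening = go, gapExtension = ge,
      type = "global"))
    expect_equal(r$score, oracle, tolerance = 1e-4)
  }
})

test_that("divide-and-conquer alignment reproduces the full-matrix score and trace", {
  S <- load_gonnet250()
  set.seed(26)
  for (case in 1:20) {
    n <- sample(30:60, 1); m <- sample(30:60, 1)
    a <- paste(sample(AA20, n, TRUE), collapse = "")
    b <- paste(sample(AA20, m, TRUE), collapse = "")
    p <- make_profile("a", a, runif(n, 0, 8), runif(n, 0, 8))
    q <- make_profile("b", b, runif(m, 0, 8), runif(m, 0, 8))
    rf <- align_pair(p, q, S)
    rl <- align_pair(p, q, S, linear_space = TRUE)
    expect_equal(rl$score, rf$score, tolerance = 1e-6)
    da <- dealign(rl)
    expect_equal(da[[1]]$residues, a)
    expect_equal(da[[2]]$residues, b)
  }
  # deep recursion (tiny base case) still matches the full matrix
  for (case in 1:20) {
    n <- sample(6:15, 1); m <- sample(6:15, 1)
    ab <- c("A", "C", "D", "E")
    S2 <- rand_matrix(ab)
    sc <- S2[sample(ab, n, TRUE), sample(ab, m, TRUE), drop = FALSE]
    goA <- runif(n, 0, 6); geA <- runif(n, 0, 3)
    goB <- runif(m, 0, 6); geB <- runif(m, 0, 3)
    full <- indelmsa:::vgp_dp_full(sc, goA, geA, goB, geB)$score
    codes <- indelmsa:::vgp_hirschberg(sc, goA, geA, goB, geB, basecut = 3L)
    expect_equal(indelmsa:::score_trace(codes, sc, goA, geA, goB, geB),
                 full, tolerance = 1e-9)
  }
})

test_that("alignment score is symmetric in its arguments", {
  S <- load_gonnet250()
  set.seed(36)
  for (case in 1:10) {
    p <- make_profile("a", rand_protein("a", sample(10:25, 1))$residues,
                      runif(1, 1, 6))
    q <- make_profile("b", rand_protein("b", sample(10:25, 1))$residues,
                      runif(1, 1, 6))
    expect_equal(align_pair(p, q, S)$score, align_pair(q, p, S)$score,
                 tolerance = 1e-9)
  }
})

test_that("raising any single opening penalty never raises the optimal score", {
  S <- load_gonnet250()
  set.seed(46)
  for (case in 1:10) {
    n <- sample(8:16, 1); m <- sample(8:16, 1)
    a <- rand_protein("a", n)$residues; b <- rand_protein("b", m)$residues
    gpo <- runif(n, 0, 4)
    p <- make_profile("a", a, gpo, pmin(gpo, runif(n, 0, 4)))
    q <- make_profile("b", b, runif(m, 0, 4))
    base <- align_pair(p, q, S)$score
    i <- sample(n, 1)
    p2 <- p
    p2$penalties$gpo[i] <- p2$penalties$gpo[i] + runif(1, 0.5, 3)
    expect_lte(align_pair(p2, q, S)$score, base + 1e-9)
  }
})

test_that("de-gapping a result restores both inputs and all columns hold residues", {
  S <- load_gonnet250()
  set.seed(56)
  p <- make_profile("a", rand_protein("a", 22)$residues, 3)
  q <- make_profile("b", rand_protein("b", 18)$residues, 3)
  r <- align_pair(p, q, S)
  aln <- as_multiple_alignment(r)    # construction checks no all-gap column
  expect_equal(length(aln$ids), 2L)
  # profile-profile alignment: member counts add up and rows de-gap correctly
  r3 <- align_pair(r$profile, make_profile("c", rand_protein("c", 20)$residues, 3), S)
  expect_length(r3$profile$ids, 3L)
  da <- dealign(r3)
  expect_equal(vapply(da, `[[`, "", "id"), c("a", "b", "c"))
})

test_that("merged profile penalties follow the column merging rule", {
  S <- load_gonnet250()
  a <- make_profile("a", "MKVLW", c(1, 2, 3, 4, 5))
  b <- make_profile("b", "MKW", c(10, 20, 30))
  r <- align_pair(a, b, S)
  w <- nchar(r$profile$rows[1])
  expect_length(r$profile$penalties$gpo, w)
  # every aligned column's gpo is the sum of the constituent positions
  tr <- r$trace
  for (k in seq_len(nrow(tr))) {
    expected <- sum(c(a$penalties$gpo[tr[k, 1]], b$penalties$gpo[tr[k, 2]]), na.rm = TRUE)
    expect_equal(r$profile$penalties$gpo[k], expected)
  }
})
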