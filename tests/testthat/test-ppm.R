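test_that("training counts every context/successor occurrence up to order D", {
  m <- train_ppm(list("AAAA"), D = 1, alphabet = c("A", "B"))
  expect_equal(m$counts[["0:"]], c(A = 4L))
  expect_equal(m$counts[["1:A"]], c(A = 3L))
  m2 <- train_ppm(list(protein_sequence("x", "MKVM"), protein_sequence("y", "KV")), D = 2)
  expect_equal(m2$counts[["0:"]], c(M = 2L, K = 2L, V = 2L))
  expect_equal(m2$counts[["2:KV"]], c(M = 1L))
  expect_error(train_ppm(list(), 2), "empty")
})

test_that("symbol probabilities are positive and normalize over the alphabet", {
  set.seed(11)
  ab <- AA20
  corpus <- replicate(5, paste(sample(ab, 40, TRUE), collapse = ""))
  m <- train_ppm(as.list(corpus), D = 4)
  for (ctx in c("", "A", "MK", "WYVQ", "ZZZZ" = "GGGG", substr(corpus[1], 3, 6))) {
    p <- vapply(ab, function(s) symbol_prob(m, s, ctx), 0)
    expect_true(all(p > 0))
    expect_equal(sum(p), 1, tolerance = 1e-9)
  }
  expect_error(symbol_prob(m, "Z", "A"), "alphabet")
})

test_that("PPM-C escape blending matches hand-expanded arithmetic", {
  # corpus ABAB, D=2, alphabet {A,B}; a one-symbol context uses order 1:
  # context A holds {B:2} (N=2, q=1 -> 2/3, escape 1/3); order 0 holds
  # {A:2, B:2} (N=4, q=2 -> B at 2/6, escape 2/6); uniform 1/2 closes:
  # 2/3 + (1/3)[2/6 + (2/6)(1/2)] = 5/6
  m <- train_ppm(list("ABAB"), D = 2, alphabet = c("A", "B"))
  p_b_after_a <- symbol_prob(m, "B", "A")
  expect_equal(p_b_after_a, 2/3 + (1/3) * (2/6 + (2/6) * (1/2)), tolerance = 1e-12)
  # familiarity: model trained on ABABABAB strongly prefers B after A
  m2 <- train_ppm(list("ABABABAB"), D = 2, alphabet = c("A", "B"))
  expect_gt(symbol_prob(m2, "B", "A") / symbol_prob(m2, "A", "A"), 5)
})

test_that("unseen model falls back to the uniform distribution", {
  empty <- structure(list(D = 4L, alphabet = AA20,
                          counts = new.env(parent = emptyenv()),
                          escape = "PPM-C"),
                     class = "ppm_model")
  expect_equal(symbol_prob(empty, "W", "MKVL"), 1 / 20)
})

test_that("window log-loss matches the analytic extremes and the hand-expanded sum", {
  uni <- structure(list(), class = "uniform20")
  registerS3method("symbol_prob", "uniform20", function(model, symbol, context = "") 1 / 20,
                   envir = asNamespace("indelmsa"))
  expect_equal(window_logloss(uni, strrep("A", 10)), log2(20), tolerance = 1e-12)

  certain <- structure(list(), class = "allcertain")
  registerS3method("symbol_prob", "allcertain", function(model, symbol, context = "") 1,
                   envir = asNamespace("indelmsa"))
  expect_equal(window_logloss(certain, strrep("A", 10)), 0)

  # hand expansion for the AAAA-trained order-1 model on an all-A window:
  # term 1 uses order 0 (P = 4/5 + (1/5)(1/20)); terms 2..10 use context
  # "A" (P = 3/4 + (1/4) * P0)
  m <- train_ppm(list("AAAA"), D = 1)
  p0 <- 4/5 + (1/5) * (1/20)
  p1 <- 3/4 + (1/4) * p0
  expect_equal(window_logloss(m, strrep("A", 10)),
               -(log2(p0) + 9 * log2(p1)) / 10, tolerance = 1e-12)
  expect_error(window_logloss(m, "AAA", L = 10), "expected L")
})

test_that("log-loss is lower on familiar text than on random text", {
  set.seed(21)
  motif <- "GGPPSSNNDD"
  corpus <- as.list(replicate(30, {
    ch <- strsplit(motif, "")[[1]]
    flip <- runif(10) < 0.1
    ch[flip] <- sample(AA20, sum(flip), TRUE)
    paste(ch, collapse = "")
  }))
  m <- train_ppm(corpus, D = 4)
  fam <- mean(vapply(corpus, function(w) window_logloss(m, w), 0))
  rnd <- mean(replicate(50, window_logloss(m, paste(sample(AA20, 10, TRUE), collapse = ""))))
  expect_lt(fam, rnd)
})

test_that("scanning produces one window per start and rejects short sequences", {
  set.seed(5)
  corpus <- as.list(replicate(10, paste(sample(AA20, 25, TRUE), collapse = "")))
  pred <- train_predictor(corpus, corpus, D = 2, L = 10)
  s10 <- rand_protein("w", 10L)
  sc <- scan_sequence(pred, s10)
  expect_length(sc$lppm, 1L)
  expect_length(sc$rppm, 1L)
  expect_true(all(c(sc$lppm, sc$rppm) >= 0))
  expect_error(scan_sequence(pred, rand_protein("v", 9L)), "shorter than the scan window")
})

test_that("scan log-loss dips at planted left-flank motifs", {
  motif <- "GGPPSSNNDD"
  set.seed(31)
  left_model <- train_ppm(as.list(replicate(40, {
    ch <- strsplit(motif, "")[[1]]
    flip <- runif(10) < 0.1
    ch[flip] <- sample(AA20, sum(flip), TRUE)
    paste(ch, collapse = "")
  })), D = 4)
  pred <- indel_predictor(left_model, left_model, L = 10)
  at_motif <- numeric(0); elsewhere <- numeric(0)
  for (rep in 1:50) {
    p <- sample(10:30, 1)
    seqch <- sample(AA20, 50, TRUE)
    seqch[p:(p + 9)] <- strsplit(motif, "")[[1]]
    sc <- scan_sequence(pred, protein_sequence("s", paste(seqch, collapse = "")))
    at_motif <- c(at_motif, sc$lppm[p])
    elsewhere <- c(elsewhere, mean(sc$lppm[-p]))
  }
  expect_lt(mean(at_motif), mean(elsewhere))
})

test_that("IndelFR extraction pairs anchors and returns sorted disjoint intervals", {
  flat <- structure(list(lppm = rep(3, 30), rppm = rep(3, 30), L = 10),
                    class = "scan_result")
  expect_equal(nrow(extract_indelfrs(flat)), 0L)

  lp <- rep(4, 30); rp <- rep(4, 30)
  lp[11] <- 1; rp[16] <- 1              # left anchor at 11, right at 16 (1-based)
  dip <- structure(list(lppm = lp, rppm = rp, L = 10), class = "scan_result")
  iv <- extract_indelfrs(dip)
  expect_equal(nrow(iv), 1L)
  expect_equal(unname(iv[1, ]), c(10, 25))   # [p, right + L) 0-based half-open

  # unpaired anchors give length-L intervals
  lp2 <- rep(4, 40); lp2[11] <- 1
  solo <- structure(list(lppm = lp2, rppm = rep(4, 40), L = 10), class = "scan_result")
  iv2 <- extract_indelfrs(solo)
  expect_equal(unname(iv2[1, ]), c(10, 20))

  set.seed(9)
  for (rep in 1:20) {
    x <- structure(list(lppm = runif(40, 1, 5), rppm = runif(40, 1, 5), L = 10),
                   class = "scan_result")
    iv <- extract_indelfrs(x)
    if (nrow(iv) > 1) {
      expect_true(all(diff(iv[, 1]) > 0))
      expect_true(all(iv[-1, 1] >= iv[-nrow(iv), 2]))
    }
    expect_true(all(iv >= 0) && all(iv[, 2] <= 49))
  }
})

test_that("annotation is deterministic and covers the full sequence", {
  fam <- simulate_family(seed = 101)
  corp <- make_training_corpus(fam)
  pred <- train_predictor(corp$left, corp$right)
  s <- fam$sequences[[1]]
  a1 <- annotate(pred, s); a2 <- annotate(pred, s)
  expect_length(a1$gpo, seq_length(s))
  expect_identical(a1$gpo, a2$gpo)
  expect_identical(a1$ifrs, a2$ifrs)
})

test_that("predicted IndelFRs cover true indel sites better than random intervals", {
  # predictor trained on 20 families; coverage evaluated on 30 held-out
  # families against a permutation baseline with the same interval count
  # and lengths
  train_fams <- lapply(1:20, function(s) simulate_family(seed = 1000 + s))
  corp <- do.call(Map, c(c, lapply(train_fams, make_training_corpus)))
  pred <- train_predictor(as.list(corp$left), as.list(corp$right))
  cover <- function(iv, truth, n) {
    inside <- rep(FALSE, n); hit <- rep(FALSE, n)
    if (nrow(truth)) for (k in seq_len(nrow(truth)))
      inside[(truth[k, 1] + 1):truth[k, 2]] <- TRUE
    if (nrow(iv)) for (k in seq_len(nrow(iv)))
      hit[(iv[k, 1] + 1):iv[k, 2]] <- TRUE
    if (!any(inside)) return(NA_real_)
    mean(hit[inside])
  }
  pred_cov <- numeric(0); rand_cov <- numeric(0)
  set.seed(77)
  for (s in 1:30) {
    fam <- simulate_family(seed = 2000 + s)
    for (d in seq_along(fam$sequences)) {
      sq <- fam$sequences[[d]]
      n <- seq_length(sq)
      iv <- annotate(pred, sq)$ifrs
      truth <- fam$true_indel_positions[[d]]
      pc <- cover(iv, truth, n)
      if (is.na(pc) || nrow(iv) == 0) next
      lens <- iv[, 2] - iv[, 1]
      starts <- vapply(lens, function(l) sample.int(n - l + 1, 1) - 1, 0)
      riv <- cbind(starts, starts + lens)
      pred_cov <- c(pred_cov, pc)
      rand_cov <- c(rand_cov, cover(riv, truth, n))
    }
  }
  expect_gt(length(pred_cov), 50)
  expect_gt(mean(pred_cov), mean(rand_cov))
})

test_that("predictor persistence reconstructs probabilities bit-exactly", {
  fam <- simulate_family(seed = 55)
  corp <- make_training_corpus(fam)
  pred <- train_predictor(corp$left, corp$right, extraction = list(c = 1.5, W = 20))
  f <- withr::local_tempfile(fileext = ".json")
  save_predictor(pred, f)
  back <- load_predictor(f)
  expect_identical(back$L, pred$L)
  expect_equal(back$extraction, pred$extraction)
  set.seed(3)
  for (rep in 1:25) {
    sym <- sample(AA20, 1); ctx <- paste(sample(AA20, sample(0:6, 1), TRUE), collapse = "")
    expect_identical(symbol_prob(back$left, sym, ctx), symbol_prob(pred$left, sym, ctx))
    expect_identical(symbol_prob(back$right, sym, ctx), symbol_prob(pred$right, sym, ctx))
  }
})
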