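test_that("find_longest_orf handles canonical, absent and trailing ORFs", {
  orf <- find_longest_orf("ATGAAATAG")
  expect_equal(orf$start, 0L)
  expect_equal(orf$length, 9L)

  expect_equal(nrow(find_longest_orf("CCCCCC")), 0L)
  expect_error(find_longest_orf(""), "empty")

  # trailing ORF without a stop counts, truncated to complete codons
  orf <- find_longest_orf("ATGAAAAAAA") # ATG + 7 nt
  expect_equal(orf$length, 9L)

  # tie broken by smaller start: two 6-nt ORFs in different frames
  orf <- find_longest_orf("ATGTAACATGTGAC")
  expect_equal(orf$start, 0L)
})

test_that("find_longest_orf agrees with the exhaustive scan oracle", {
  set.seed(17)
  for (i in 1:100) {
    s <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
    got <- find_longest_orf(s)
    want <- oracle_orf(s)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$start, want$start)
      expect_equal(got$length, want$length)
    }
  }
})

test_that("fickett_testcode matches the straight-line lookup oracle", {
  set.seed(23)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    expect_equal(fickett_testcode(s), oracle_fickett(s), tolerance = 1e-12)
  }
  # pure-A sequence drives the A position ratio into the top bin
  s <- strrep("A", 99)
  expect_equal(suppressWarnings(fickett_testcode(s)), oracle_fickett(s),
    tolerance = 1e-12
  )
})

test_that("fickett_testcode excludes N and is bounded", {
  set.seed(3)
  s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  expect_equal(fickett_testcode(s), fickett_testcode(paste0(s, "NNN")))
  upper <- sum(c(0.22, 0.23, 0.24, 0.18) * c(0.58, 0.60, 0.74, 0.69)) +
    sum(c(0.11, 0.12, 0.15, 0.14) * c(0.58, 0.63, 0.59, 0.56))
  expect_lt(fickett_testcode(s), upper + 1e-9)
  expect_error(suppressWarnings(fickett_testcode("ACGTXX")), "outside")
  expect_error(suppressWarnings(fickett_testcode("ACG")), "shorter")
})

test_that("hexamer model is symmetric, signed, and separates synthetic classes", {
  seqs <- c("ATGGCCAAATTTGGG", "ATGCCCTTTAAAGGG")
  m <- train_hexamer_model(seqs, seqs)
  expect_true(all(unclass(m) == 0))
  expect_equal(hexamer_score(seqs[1], m), 0)

  m2 <- train_hexamer_model("AAAAAAAAAAAA", "CCCCCCCCCCCC")
  expect_gt(unclass(m2)[["AAAAAA"]], 0)
  expect_lt(unclass(m2)[["CCCCCC"]], 0)

  tr <- simulate_codpot_training(60, seed = 41)
  te <- simulate_codpot_training(40, seed = 42)
  m3 <- train_hexamer_model(
    vapply(tr$sequence[tr$label == "coding"], lincnet:::orf_subsequence, character(1)),
    tr$sequence[tr$label == "noncoding"]
  )
  sc <- vapply(te$sequence, function(s) {
    o <- lincnet:::orf_subsequence(s)
    if (nchar(o) >= 6) hexamer_score(o, m3) else 0
  }, numeric(1))
  lab <- te$label == "coding"
  expect_gt(mean(sc[lab]), mean(sc[!lab]))
  # rank-based AUC
  auc <- (mean(rank(sc)[lab]) - (sum(lab) + 1) / 2) / sum(!lab)
  expect_gte(auc, 0.9)
})

test_that("logistic fit degenerates to the class prior and orders separable data", {
  X <- matrix(0, 40, 2)
  y <- rep(c(1, 0), c(10, 30))
  coef <- suppressWarnings(fit_logistic(X, y))
  expect_equal(unname(logistic_coding_score(X, coef)[1]), 0.25, tolerance = 1e-6)

  x1 <- matrix(c(rnorm(30, 0), rnorm(30, 0.8)), ncol = 1)
  y1 <- rep(c(0, 1), each = 30)
  coef1 <- suppressWarnings(fit_logistic(x1, y1))
  p <- logistic_coding_score(matrix(c(-2, 0, 2), ncol = 1), coef1)
  expect_true(all(diff(p) > 0))
})

test_that("logistic IRLS matches glm on non-separable data", {
  set.seed(77)
  X <- matrix(rnorm(200), 100, 2)
  y <- rbinom(100, 1, plogis(0.5 * X[, 1] - 0.3 * X[, 2]))
  ours <- fit_logistic(X, y)
  ref <- coef(glm(y ~ X, family = binomial))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-6)
})

test_that("k-mer features and classifier behave as specified", {
  # 1-mer block of a balanced sequence: frequencies 0.25 scaled by 1/4
  f <- kmer_features(strrep("ACGT", 10))
  expect_equal(unname(f[1, 1:4]), rep(0.25 / 4, 4))
  expect_equal(ncol(f), 1364L)
  expect_error(kmer_features("ACG"), "shorter")

  zero <- structure(
    list(weights = rep(0, 1364), bias = -1),
    class = "kmer_classifier"
  )
  expect_equal(kmer_predict(c("ACGTACGT", "GGGGGGGG"), zero),
    c("noncoding", "noncoding"))
})

test_that("trained classifiers reach held-out accuracy on synthetic transcripts", {
  tr <- simulate_codpot_training(100, seed = 4)
  te <- simulate_codpot_training(80, seed = 104)
  model <- suppressWarnings(train_codpot_model(tr))
  res <- codpot_classify(te, model)
  expect_gte(mean((res$cpat_label == "coding") == (te$label == "coding")), 0.9)
  expect_gte(mean((res$kmer_label == "coding") == (te$label == "coding")), 0.85)
  expect_true(all(res$orf_coverage >= 0 & res$orf_coverage <= 1))
  expect_equal(res$orf_coverage, res$orf_size / res$length)
})

test_that("the consensus gate requires both noncoding calls and is monotone", {
  expect_true(consensus_noncoding("noncoding", "noncoding"))
  expect_false(consensus_noncoding("coding", "noncoding"))
  expect_false(consensus_noncoding("noncoding", "coding"))
  expect_false(consensus_noncoding("coding", "coding"))
  # flipping any label from noncoding to coding can only shrink the set
  labs <- expand.grid(
    cpat = c("coding", "noncoding"), kmer = c("coding", "noncoding"),
    stringsAsFactors = FALSE
  )
  base <- consensus_noncoding(labs$cpat, labs$kmer)
  flipped <- consensus_noncoding(rep("coding", 4), labs$kmer)
  expect_true(all(flipped <= base))
})
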