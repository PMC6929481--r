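test_that("confusion counts classify each pair correctly", {
  expect_equal(confusionCounts(c(1, 1, 0, 0), c(1, 1, 0, 0)),
               c(TP = 2L, FP = 0L, TN = 2L, FN = 0L))
  expect_equal(confusionCounts(c(1, 0), c(0, 1)),
               c(TP = 0L, FP = 1L, TN = 0L, FN = 1L))
  expect_equal(confusionCounts(c(1, 1, 1, 0, 0), c(1, 0, 1, 1, 0)),
               c(TP = 2L, FP = 1L, TN = 1L, FN = 1L))
  expect_error(confusionCounts(c(1, 0), c(1)), "length")
  expect_error(confusionCounts(integer(), integer()), "empty")
})

test_that("ACC, SN and SP follow their defining ratios", {
  expect_equal(basicMetrics(c(TP = 50, FP = 0, TN = 50, FN = 0)),
               c(ACC = 1, SN = 1, SP = 1))
  expect_equal(basicMetrics(c(TP = 0, FP = 10, TN = 0, FN = 10)),
               c(ACC = 0, SN = 0, SP = 0))
  expect_equal(basicMetrics(c(TP = 35, FP = 20, TN = 30, FN = 15)),
               c(ACC = 0.65, SN = 0.70, SP = 0.60))
  # missing class flags the ratio as undefined
  expect_true(is.na(basicMetrics(c(TP = 0, FP = 5, TN = 5, FN = 0))[["SN"]]))
})

test_that("MCC matches its closed form and flags undefined cases", {
  expect_equal(mccScore(c(TP = 50, FP = 0, TN = 50, FN = 0)), 1.0)
  expect_equal(mccScore(c(TP = 25, FP = 25, TN = 25, FN = 25)), 0.0)
  expect_equal(mccScore(c(TP = 35, FP = 20, TN = 30, FN = 15)),
               (35 * 30 - 20 * 15) / sqrt(55 * 50 * 50 * 45))
  expect_true(is.na(mccScore(c(TP = 0, FP = 0, TN = 5, FN = 5))))
})

test_that("MCC equals the Pearson correlation of label and prediction vectors", {
  withr::with_seed(17, {
    for (rep in 1:50) {
      n <- sample(10:60, 1)
      labels <- rbinom(n, 1, 0.5)
      preds <- rbinom(n, 1, 0.5)
      cc <- confusionCounts(labels, preds)
      m <- mccScore(cc)
      if (sd(labels) == 0 || sd(preds) == 0) {
        expect_true(is.na(m))
      } else {
        expect_equal(m, cor(labels, preds), tolerance = 1e-12)
      }
    }
  })
})

test_that("AUC equals the probability a positive outscores a negative", {
  expect_equal(aucScore(c(1, 1, 0, 0), c(0.9, 0.9, 0.1, 0.1)), 1.0)
  expect_equal(aucScore(c(1, 1, 0, 0), rep(0.4, 4)), 0.5)  # ties at 1/2
  expect_equal(aucScore(c(1, 1, 0, 0), c(0.8, 0.4, 0.6, 0.2)), 0.75)
  expect_error(aucScore(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("rank AUC matches brute-force pair counting and monotone invariance", {
  bruteAUC <- function(labels, scores) {
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    tot <- 0
    for (p in pos) for (q in neg)
      tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
    tot / (length(pos) * length(neg))
  }
  withr::with_seed(23, {
    for (rep in 1:30) {
      n <- sample(8:40, 1)
      labels <- c(1, 0, rbinom(n, 1, 0.5))
      scores <- round(runif(n + 2), 2)  # rounding forces some ties
      expect_equal(aucScore(labels, scores), bruteAUC(labels, scores))
      expect_equal(aucScore(labels, plogis(5 * scores - 2)),
                   aucScore(labels, scores))
    }
  })
})

test_that("swapping the class labeling maps SN<->SP, AUC->1-AUC, |MCC| fixed", {
  withr::with_seed(29, {
    labels <- rbinom(40, 1, 0.5)
    labels[1:2] <- c(0, 1)
    scores <- runif(40)
  })
  preds <- as.integer(scores >= 0.5)
  a <- basicMetrics(confusionCounts(labels, preds))
  b <- basicMetrics(confusionCounts(1 - labels, 1 - preds))
  expect_equal(a[["SN"]], b[["SP"]])
  expect_equal(a[["SP"]], b[["SN"]])
  expect_equal(a[["ACC"]], b[["ACC"]])
  expect_equal(aucScore(1 - labels, scores), 1 - aucScore(labels, scores))
  expect_equal(abs(mccScore(confusionCounts(labels, preds))),
               abs(mccScore(confusionCounts(1 - labels, preds))))
})

test_that("accuracy decomposes as the class-size-weighted mean of SN and SP", {
  withr::with_seed(37, {
    for (rep in 1:20) {
      labels <- c(1, 0, rbinom(30, 1, 0.4))
      preds <- rbinom(32, 1, 0.5)
      m <- basicMetrics(confusionCounts(labels, preds))
      P <- sum(labels == 1); N <- sum(labels == 0)
      expect_equal(m[["ACC"]], (m[["SN"]] * P + m[["SP"]] * N) / (P + N))
    }
  })
})

test_that("trial summaries report mean and sample SD per metric", {
  reps <- data.frame(ACC = c(0.7, 0.8, 0.9), MCC = c(0.4, 0.4, 0.4))
  s <- summarizeTrials(reps, digits = NULL)
  expect_equal(s["mean", "ACC"], 0.8)
  expect_equal(s["sd", "ACC"], sd(c(0.7, 0.8, 0.9)))
  expect_equal(s["sd", "MCC"], 0)
  identical3 <- reps[c(1, 1, 1), ]
  expect_true(all(summarizeTrials(identical3)["sd", ] == 0))
  expect_error(summarizeTrials(reps[0, ]), "no reports")
})
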