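test_that("flattened dimension matches the architecture arithmetic", {
  expect_equal(flattenedDim(cnnConfig()), 768L)
  expect_equal(flattenedDim(cnnConfig(poolSize = 2L)), 3200L)   # 50 * 64
  expect_equal(flattenedDim(cnnConfig(inputLength = 100L)), 384L)  # 6 * 64
  # pooling a short input to zero length is refused
  expect_error(cnnConfig(inputLength = 8L, poolAfter = c(1L, 2L, 3L)),
               "zero")
})

test_that("config validity ties fcSizes to the convolutional stack", {
  expect_error(cnnConfig(fcSizes = c(100L, 256L)), "does not match")
  cfg <- cnnConfig()
  expect_equal(cfg@fcSizes, c(768L, 256L))
  expect_equal(cfg@epochs, 20L)
  expect_equal(cfg@learningRate, 1e-4)
})

test_that("model builds are seeded and deterministic", {
  a <- buildModel(tinyConfig(seed = 5L))
  b <- buildModel(tinyConfig(seed = 5L))
  d <- buildModel(tinyConfig(seed = 6L))
  expect_identical(a@theta, b@theta)
  expect_false(identical(a@theta, d@theta))
  expect_true(is.na(a@chosenEpoch))
})

test_that("probabilities are valid, order-preserving and reproducible", {
  model <- buildModel(tinyConfig(seed = 2L))
  ds <- tinyDataset(6, seed = 3)
  enc <- encodeDataset(ds)
  p <- predictProba(model, enc)
  expect_length(p, 12)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(names(p), names(ds))
  expect_identical(p, predictProba(model, enc))
  # single matrix input and empty input
  expect_length(predictProba(model, enc[1, , ]), 1)
  expect_length(predictProba(model, enc[integer(0), , , drop = FALSE]), 0)
  # shape mismatch
  expect_error(predictProba(model, array(0, c(2, 16, 8))), "shape")
})

test_that("analytic gradients match finite differences", {
  cfg <- cnnConfig(inputLength = 16L, filters = 4L, poolSize = 2L,
                   fcSizes = c(16L, 6L), seed = 5L)
  init <- withSeed(5L, enhancerCNN:::.initParams(cfg))
  theta <- init$theta
  withr::with_seed(9, {
    x <- array(runif(5 * 16 * 8), c(5, 16, 8))
    y <- c(1, 0, 1, 1, 0)
  })
  fb <- enhancerCNN:::.flattenBatch(x)
  st <- enhancerCNN:::.trainStep(theta, init$bnStats, cfg, fb$X, y, 5L)
  lossAt <- function(th)
    enhancerCNN:::.trainStep(th, init$bnStats, cfg, fb$X, y, 5L)$loss
  eps <- 1e-6
  # conv biases are excluded: batch norm subtracts the batch mean right
  # after the convolution, so their true gradient is identically zero
  withr::with_seed(1, {
    for (nm in setdiff(names(theta), sprintf("c%d.b", 1:6))) {
      for (j in sample(length(theta[[nm]]), min(4, length(theta[[nm]])))) {
        tp <- theta; tp[[nm]][j] <- tp[[nm]][j] + eps
        tm <- theta; tm[[nm]][j] <- tm[[nm]][j] - eps
        num <- (lossAt(tp) - lossAt(tm)) / (2 * eps)
        ana <- st$grads[[nm]][j]
        expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4)
      }
    }
  })
})

test_that("training keeps the first epoch minimizing validation loss", {
  ds <- tinyDataset(20, seed = 4)
  enc <- encodeDataset(ds)
  y <- classLabels(ds)
  tr <- c(1:15, 21:35)
  va <- c(16:20, 36:40)
  m1 <- trainModel(enc[tr, , ], y[tr], enc[va, , ], y[va],
                   tinyConfig(epochs = 1L, seed = 7L))
  expect_equal(m1@chosenEpoch, 1L)
  m4 <- trainModel(enc[tr, , ], y[tr], enc[va, , ], y[va],
                   tinyConfig(epochs = 4L, seed = 7L))
  expect_length(m4@valLoss, 4)
  expect_equal(m4@chosenEpoch, which.min(m4@valLoss))
})

test_that("degenerate training inputs are refused", {
  ds <- tinyDataset(6, seed = 8)
  enc <- encodeDataset(ds)
  y <- classLabels(ds)
  cfg <- tinyConfig(epochs = 1L)
  expect_error(trainModel(enc[1:6, , ], y[1:6], enc[7:12, , ], y[7:12], cfg),
               "both classes")
  expect_error(trainModel(enc, y, enc[integer(0), , , drop = FALSE],
                          integer(0), cfg), "empty")
  expect_error(trainModel(enc[1:8, , ], y[1:8], enc[5:12, , ], y[5:12], cfg),
               "share record ids")
})

test_that("a separable GC contrast is learned to high validation accuracy", {
  ds <- simulateDataset(200, length = 200, gcPositive = 0.8,
                        gcNegative = 0.2, seed = 13)
  enc <- encodeDataset(ds)
  y <- classLabels(ds)
  va <- c(161:200, 361:400)
  tr <- setdiff(seq_len(400), va)
  cfg <- cnnConfig(epochs = 3L, seed = 21L)
  m <- trainModel(enc[tr, , ], y[tr], enc[va, , ], y[va], cfg)
  p <- predictProba(m, enc[va, , ])
  expect_gte(mean((p >= 0.5) == (y[va] == 1)), 0.9)
  # training loss trends down on separable data
  expect_lt(m@trainLoss[length(m@trainLoss)], m@trainLoss[1])
  # reruns reproduce the trained model exactly
  m2 <- trainModel(enc[tr, , ], y[tr], enc[va, , ], y[va], cfg)
  expect_identical(m@theta, m2@theta)
  expect_identical(m@valLoss, m2@valLoss)
})
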