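test_that("configuration defaults match the DNA-scale architecture", {
  cfg <- kdeepConfig(16, strandType = "DNA")
  expect_equal(cfg@nFilters, 320L)
  expect_equal(cfg@lstmUnits, 320L)
  expect_equal(kdeepConfig(16, strandType = "RNA")@lstmUnits, 32L)
  expect_error(kdeepConfig(16, dropoutCnn = 1), "dropout")
  expect_error(kdeepConfig(16, nFilters = 0), ">= 1")
  expect_error(kdeepConfig(16, inputRows = 10, filterWidth = 16), "inputRows")
})

test_that("builds are deterministic in the seed and predictions lie in (0,1)", {
  cfg <- tinyConfig(seed = 3L)
  m1 <- buildModel(cfg)
  m2 <- buildModel(cfg)
  expect_identical(m1@params, m2@params)
  m3 <- buildModel(tinyConfig(seed = 4L))
  expect_false(identical(m1@params, m3@params))

  withr::local_seed(1)
  s <- randomStrand(61)
  sc <- predictScores(m1, stats::setNames(s, "q"))
  expect_equal(dim(sc), c(1L, 1L))
  expect_true(all(sc > 0 & sc < 1))
})

test_that("parameter counts follow the closed-form layer arithmetic", {
  cfg <- tinyConfig(nFilters = 4, filterWidth = 3)
  m <- buildModel(cfg)
  by <- countTrainableParameters(m, byLayer = TRUE)
  # conv: nFilters * (F * inputCols) + nFilters biases
  expect_equal(unname(by["convW"] + by["convB"]), 4 * (3 * 16) + 4)  # 196
  expect_equal(sum(by), countTrainableParameters(m))
  # same architecture, different seed: identical count
  expect_equal(countTrainableParameters(buildModel(tinyConfig(
    nFilters = 4, filterWidth = 3, seed = 99L))),
    countTrainableParameters(m))
  # widening the input columns grows conv (and only layers fed by it)
  cfg64 <- kdeepConfig(inputCols = 64, inputRows = 59, nFilters = 4,
                       filterWidth = 3, lstmUnits = 8, denseUnits = 16, k2 = 3)
  by64 <- countTrainableParameters(buildModel(cfg64), byLayer = TRUE)
  expect_equal(unname(by64["convW"]), 4 * 3 * 64)
  expect_equal(unname(by64["dense1W"]), unname(by["dense1W"]))
})

test_that("analytic gradients agree with finite differences", {
  for (useAtt in c(FALSE, TRUE)) {
    cfg <- kdeepConfig(inputCols = 4, inputRows = 9, nOutputs = 2,
                       nFilters = 3, filterWidth = 3, poolSize = 2,
                       dropoutCnn = 0, dropoutLstm = 0, lstmUnits = 3,
                       attnUnits = 3, denseUnits = 8, useAttention = useAtt,
                       k1 = 3, k2 = 1, seed = 11L)
    p <- buildModel(cfg)@params
    withr::local_seed(7)
    n <- 4; S <- 9; C <- 4
    X <- array(stats::runif(n * S * C), c(n, S, C))
    mask <- matrix(TRUE, n, S)
    mask[2, 8:9] <- FALSE; X[2, 8:9, ] <- 0   # one padded strand
    Y <- matrix(stats::rbinom(n * 2, 1, 0.5), n, 2)
    fw <- kdeep:::.nnForward(p, cfg, X, mask)
    gr <- kdeep:::.nnBackward(p, cfg, fw, Y)
    lossAt <- function(pp)
      kdeep:::.bceLoss(kdeep:::.nnForward(pp, cfg, X, mask)$logits, Y)
    eps <- 1e-6; nChecked <- 0
    for (nm in names(p)) {
      for (i in seq_len(min(6, length(p[[nm]])))) {
        p1 <- p; p1[[nm]][i] <- p1[[nm]][i] + eps
        p2 <- p; p2[[nm]][i] <- p2[[nm]][i] - eps
        num <- (lossAt(p1) - lossAt(p2)) / (2 * eps)
        if (abs(num) < 1e-9) next   # dead unit (ReLU/pool selection)
        nChecked <- nChecked + 1
        expect_lt(abs(num - gr[[nm]][i]) / (abs(num) + abs(gr[[nm]][i])),
                  1e-3)
      }
    }
    expect_gt(nChecked, 20)
  }
})

test_that("the attention block softmax-normalizes per-position scores", {
  # uniform features give uniform scores for any scorer
  u <- matrix(0.3, 5, 4)
  expect_equal(attentionBlock(u)$scores, rep(0.2, 5))
  expect_equal(attentionBlock(matrix(1, 1, 4))$scores, 1)
  withr::local_seed(13)
  f <- matrix(stats::rnorm(24), 6, 4)
  ab <- attentionBlock(f)
  expect_equal(sum(ab$scores), 1, tolerance = 1e-6)
  expect_true(all(ab$scores >= 0))
  expect_equal(ab$features, f * ab$scores)
})

test_that("training lowers the loss on a learnable synthetic problem", {
  ds <- tinyDataset(150, seed = 5)
  batch <- encodeBatch(ds, "2lk", 3, 2)
  mod <- trainModel(buildModel(tinyConfig(seed = 2L)), batch,
                    epochs = 4, batchSize = 32, validationFraction = 0)
  log <- trainingLog(mod)
  expect_equal(nrow(log), 4L)
  expect_lt(log$trainLoss[4], log$trainLoss[1])
  expect_true(mod@trained)
})

test_that("an all-negative dataset drives predictions toward zero", {
  withr::local_seed(17)
  seqs <- vapply(1:60, function(i) randomStrand(61), character(1))
  names(seqs) <- paste0("n", 1:60)
  batch <- encodeBatch(seqs, "2lk", 3, 2)
  mod <- trainModel(buildModel(tinyConfig(seed = 6L)), batch,
                    labels = matrix(0, 60, 1), epochs = 40, batchSize = 16,
                    learningRate = 0.03, validationFraction = 0)
  log <- trainingLog(mod)
  expect_lt(log$trainLoss[nrow(log)], 0.1)
  expect_true(all(predictScores(mod, batch) < 0.2))
})

test_that("training is reproducible and inference deterministic", {
  ds <- tinyDataset(100, seed = 8)
  batch <- encodeBatch(ds, "2lk", 3, 2)
  m1 <- trainModel(buildModel(tinyConfig(seed = 9L)), batch, epochs = 2)
  m2 <- trainModel(buildModel(tinyConfig(seed = 9L)), batch, epochs = 2)
  expect_identical(trainingLog(m1), trainingLog(m2))
  expect_identical(m1@params, m2@params)
  s1 <- predictScores(m1, batch)
  expect_identical(s1, predictScores(m1, batch))
})

test_that("a batch of one predicts identically to its row in a larger batch", {
  withr::local_seed(19)
  # variable lengths: padding must not leak into real positions
  seqs <- c(a = randomStrand(61), b = randomStrand(45), c = randomStrand(52))
  for (useAtt in c(FALSE, TRUE)) {
    mod <- buildModel(tinyConfig(seed = 23L, useAttention = useAtt))
    all3 <- predictScores(mod, seqs)
    for (i in 1:3)
      expect_equal(unname(predictScores(mod, seqs[i])[1, ]),
                   unname(all3[i, ]), tolerance = 1e-12)
  }
})

test_that("multi-target models emit one sigmoid score per target", {
  cfg <- tinyConfig(nOutputs = 5)
  mod <- buildModel(cfg)
  withr::local_seed(29)
  sc <- predictScores(mod, stats::setNames(
    vapply(1:4, function(i) randomStrand(61), character(1)), paste0("s", 1:4)))
  expect_equal(dim(sc), c(4L, 5L))
  expect_true(all(sc > 0 & sc < 1))
  expect_false(any(abs(rowSums(sc) - 1) < 1e-6))  # not a simplex
})

test_that("models round-trip through save/load bitwise", {
  ds <- tinyDataset(80, seed = 31)
  batch <- encodeBatch(ds, "2lk", 3, 2)
  mod <- trainModel(buildModel(tinyConfig(seed = 37L, useAttention = TRUE)),
                    batch, epochs = 1)
  f <- withr::local_tempfile(fileext = ".rds")
  saveModel(mod, f)
  back <- loadModel(f)
  expect_identical(predictScores(back, batch), predictScores(mod, batch))
  expect_identical(back@config@seed, mod@config@seed)
  expect_true(back@config@useAttention)
  expect_error(loadModel(tempfile()), "no such model")
  g <- withr::local_tempfile(fileext = ".rds")
  writeLines("not a model", g)
  expect_error(loadModel(g), "model")
})

test_that("shape mismatches are caught before any computation", {
  mod <- buildModel(tinyConfig())
  batch <- encodeBatch(c(s = randomStrand(61)), "2lk", 3, 3)
  expect_error(predictScores(mod, batch), "does not match")
  long <- encodeBatch(c(s = randomStrand(200)), "2lk", 3, 2)
  expect_error(predictScores(mod, long), "built for")
  ds <- tinyDataset(40, seed = 41)
  b <- encodeBatch(ds, "2lk", 3, 2)
  expect_error(trainModel(buildModel(tinyConfig(nOutputs = 2)), b),
               "target")
})
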