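# Hybrid loss, training loop behavior, fine-tuning protocol.

test_that("hybridLoss combines MSE and entropy as printed", {
  # direct arithmetic: (0.1 - (-0.1))^2 = 0.04 plus -log(0.5) = ln 2
  expect_equal(hybridLoss(-0.1, 0.1, 0.5), 0.04 + log(2))
  expect_equal(hybridLoss(-0.1, 0.1, 0.5), 0.73315, tolerance = 1e-5)
  # the printed default weight is 1
  expect_equal(formals(hybridLoss)$alpha, 1)
  # alpha = 0 reduces to the pure MSE term
  set.seed(4)
  yh <- rnorm(10); yt <- rnorm(10); ph <- runif(10)
  expect_equal(hybridLoss(yh, yt, ph, alpha = 0), mean((yh - yt)^2))
  # perfect predictions with confident correct classes drive the loss to 0
  expect_lt(hybridLoss(c(1, -1), c(1, -1), c(1 - 1e-12, 1e-12)), 1e-10)
  # ties are excluded from the entropy term
  expect_equal(hybridLoss(c(0, 1), c(0, 1), c(0.5, 0.99)),
               mean(c(0, 0)) + -log(0.99))
})

test_that("training is deterministic given the seed", {
  model <- initPairNet(pairNetConfig(m = 4L, L = 1L, precodeDepth = 1L,
                                     readoutSteps = 1L, dropout = 0,
                                     seed = 2L), deskPotential())
  tensors <- deskTrainTensors()
  pairs <- enumeratePairs(deskTrainSeries()[[1]])[1:10, ]
  cfg <- trainConfig(batchSize = 5L, lr = 1e-3, epochs = 2, seed = 9L)
  m1 <- trainPairNet(model, pairs, tensors, cfg)
  m2 <- trainPairNet(model, pairs, tensors, cfg)
  expect_identical(m1@state$history$loss, m2@state$history$loss)
  expect_identical(m1@params, m2@params)
})

test_that("full-batch loss decreases monotonically over the first evaluations", {
  model <- initPairNet(pairNetConfig(m = 4L, L = 1L, precodeDepth = 1L,
                                     readoutSteps = 1L, dropout = 0,
                                     seed = 2L), deskPotential())
  tensors <- deskTrainTensors()
  pairs <- enumeratePairs(deskTrainSeries()[[1]])[1:10, ]
  cfg <- trainConfig(batchSize = 10L, lr = 5e-3, epochs = 6, seed = 1L)
  m <- trainPairNet(model, pairs, tensors, cfg)
  losses <- m@state$history$loss
  expect_gte(length(losses), 5L)
  expect_true(all(diff(losses[1:5]) < 0))
})

test_that("series are never split across cross-validation folds", {
  ids <- rep(paste0("S", 1:10), times = sample(3:6, 10, replace = TRUE))
  fold <- seriesFolds(ids, k = 5L, seed = 2L)
  for (s in unique(ids)) {
    expect_length(unique(fold[names(fold) == s]), 1L)
  }
  expect_equal(sort(unique(fold)), 1:5)
})

test_that("checkpoints round-trip and reproduce the validation loss", {
  model <- deskModel()
  tensors <- deskTrainTensors()
  valPairs <- enumeratePairs(deskTrainSeries()[[2]])[1:8, ]
  valPairs <- pairKeys(valPairs)
  before <- validationRmsePw(model@params, model@config, valPairs, tensors)
  f <- tempfile(fileext = ".rds")
  saveCheckpoint(model, f)
  back <- loadCheckpoint(f)
  after <- validationRmsePw(back@params, back@config, valPairs, tensors)
  expect_equal(after, before, tolerance = 1e-6)
  expect_identical(back@params, model@params)
})

test_that("fine-tuning uses reference pairs only and freezes the ranking head", {
  model <- deskModel()
  tt <- deskTestTensors(); labels <- deskTestLabels()
  refs <- names(tt)[1:4]
  ft <- fineTunePairNet(model, tt[refs], labels[refs],
                        fineTuneConfig(lr = 1e-3, epochs = 2, seed = 1L))
  clsNames <- grep("^cls_", names(model@params), value = TRUE)
  expect_identical(ft@params[clsNames], model@params[clsNames])  # bitwise
  regNames <- grep("^reg_|^l1\\.", names(model@params), value = TRUE)
  expect_false(identical(ft@params[regNames], model@params[regNames]))
  expect_setequal(ft@state$referenceIds, refs)
  expect_error(fineTunePairNet(model, tt[1], labels[1]), "at least two")
})

test_that("four references induce C(4,2) = 6 unordered / 12 directed fine-tune pairs", {
  # combinatorics of the fine-tune pair set
  expect_equal(choose(4, 2), 6)
  ids <- paste0("L", 1:4)
  idx <- utils::combn(4, 2)
  directed <- rbind(data.frame(i = ids[idx[1, ]], j = ids[idx[2, ]]),
                    data.frame(i = ids[idx[2, ]], j = ids[idx[1, ]]))
  expect_equal(nrow(directed), 12L)
  expect_equal(anyDuplicated(paste(directed$i, directed$j)), 0L)
})

test_that("a diverging run aborts with a diagnostic", {
  model <- initPairNet(pairNetConfig(m = 4L, L = 1L, precodeDepth = 1L,
                                     readoutSteps = 1L, dropout = 0,
                                     seed = 2L), deskPotential())
  bad <- model
  bad@params$reg_W3[] <- NaN
  tensors <- deskTrainTensors()
  pairs <- enumeratePairs(deskTrainSeries()[[1]])[1:2, ]
  expect_error(
    trainPairNet(bad, pairs, tensors,
                 trainConfig(batchSize = 2L, lr = 1e-3, epochs = 1, seed = 1L)),
    "diverged")
})
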