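# Network blocks against the straight-line equation oracle, plus the
# structural invariants of the Siamese architecture.

perturbedOracleModel <- function(seed = 42L) {
  model <- oracleModel()
  set.seed(seed)
  model@params <- lapply(model@params, function(w) {
    w + matrix(rnorm(length(w), 0, 0.1), nrow(w))
  })
  model
}

secondToyGraph <- function() {
  pocket <- molStructure(
    data.frame(element = "C", x = 0, y = 0, z = 3,
               resno = 1L, resid = "GLY", chain = "A"),
    NULL, role = "protein")
  ligand <- molStructure(
    data.frame(element = c("C", "O"), x = c(0, 1.4), y = 0, z = 0),
    data.frame(i = 1L, j = 2L, order = 1), role = "ligand")
  buildComplexGraph(pocket, ligand)
}

test_that("the full forward pass reproduces the manual equation oracle", {
  model <- perturbedOracleModel()
  gI <- oracleComplex(); gJ <- secondToyGraph()
  got <- forwardPair(model, gI, gJ, record = TRUE)
  ref <- manualPairForward(model, gI, gJ)
  expect_equal(got$yhat, ref$yhat, tolerance = 1e-10)
  expect_equal(got$phat, ref$phat, tolerance = 1e-10)
  expect_equal(got$xi, as.numeric(ref$xi), tolerance = 1e-10)
  expect_equal(got$xj, as.numeric(ref$xj), tolerance = 1e-10)
  expect_equal(got$attnI$alpha, ref$attnI, tolerance = 1e-10)
})

test_that("deeper configurations also match the oracle", {
  model <- initPairNet(pairNetConfig(m = 4L, L = 2L, precodeDepth = 2L,
                                     readoutSteps = 2L, dropout = 0,
                                     seed = 11L), uncoveredPotential())
  set.seed(12)
  model@params <- lapply(model@params, function(w) {
    w + matrix(rnorm(length(w), 0, 0.08), nrow(w))
  })
  gI <- oracleComplex(); gJ <- secondToyGraph()
  got <- forwardPair(model, gI, gJ)
  ref <- manualPairForward(model, gI, gJ)
  expect_equal(got$yhat, ref$yhat, tolerance = 1e-10)
  expect_equal(got$phat, ref$phat, tolerance = 1e-10)
})

test_that("initial encodings: zero features with zero biases give zero states", {
  model <- oracleModel()
  p <- model@params
  cfg <- model@config
  # h_v^0 = ReLU(W x_v + b): zero features and zero bias give the zero state
  h0 <- pmax(matrix(0, 1, cfg$lNode) %*% p$Winode + 0 * p$binode, 0)
  expect_equal(as.numeric(h0), rep(0, cfg$m))
  # and the edge encoder seeded with zeros stays zero
  xp <- pmax(matrix(0, 1, cfg$lEdge) %*% p$Wiedge + 0 * p$biedge, 0)
  he0 <- pmax(cbind(h0, xp) %*% p$Wi + 0 * p$bi, 0)
  expect_equal(as.numeric(he0), rep(0, cfg$m))
  # 2-dim hand example of the ReLU recipe with identity-like weights
  expect_equal(pmax(c(-1, 2), 0), c(0, 2))
})

test_that("the m/2 intermediate edge dimension is respected", {
  cfg <- pairNetConfig(m = 4L, L = 1L, dropout = 0)
  model <- initPairNet(cfg, uncoveredPotential())
  expect_equal(ncol(model@params$Wiedge), 2L)           # x'_uv in R^{m/2}
  expect_equal(nrow(model@params$Wi), 4L + 2L)          # cat(h, x') -> 6
  expect_equal(ncol(model@params$Wi), 4L)               # projected to m
  expect_error(pairNetConfig(m = 5L))                   # odd m rejected
})

test_that("pocket pre-encoding is a symmetric-normalized GCN", {
  # 3-node path graph, 1-dim hand weights: values must match the manual
  # normalized-adjacency multiplication
  A <- matrix(c(1, 1, 0, 1, 1, 1, 0, 1, 1), 3, 3)
  dinv <- 1 / sqrt(rowSums(A))
  Ahat <- A * outer(dinv, dinv)
  X <- matrix(c(1, -2, 3), 3, 1)
  W <- matrix(0.5, 1, 1)
  manual <- pmax(Ahat %*% X %*% W, 0)
  # isolated node (self-loop only) keeps its own transformed feature
  expect_equal(manual[1], pmax((X[1] / sqrt(2) + X[2] / sqrt(6)) * 0.5, 0))
  # permutation equivariance of the same layer
  perm <- c(3, 1, 2)
  P <- diag(3)[perm, ]
  manual2 <- pmax((P %*% Ahat %*% t(P)) %*% (P %*% X) %*% W, 0)
  expect_equal(as.numeric(manual2), as.numeric(manual)[perm])
})

test_that("attention softmax groups sum to one everywhere", {
  model <- deskModel()
  s <- deskTestSeries()
  g <- buildComplexGraph(s@pocket, s@poses[[1]])
  out <- forwardPair(model, g, buildComplexGraph(s@pocket, s@poses[[2]]),
                     record = TRUE)
  for (a in list(out$attnI, out$attnJ)) {
    sums <- tapply(a$alpha, a$dst, sum)
    expect_equal(unname(as.numeric(sums)), rep(1, length(sums)),
                 tolerance = 1e-9)
  }
})

test_that("singleton neighborhoods receive attention one", {
  # ligand with a single atom: each virtual edge to the pocket atom is the
  # sole incoming edge of its target
  pocket <- toyPocketAtom(3.0)
  lig <- molStructure(data.frame(element = "C", x = 0.75, y = 0, z = 0))
  g <- buildComplexGraph(pocket, lig)
  model <- perturbedOracleModel()
  out <- forwardPair(model, g, g, record = TRUE)
  expect_equal(out$attnI$alpha, rep(1, nrow(out$attnI)))
  expect_true(is.finite(out$yhat))
})

test_that("the pair representation concatenates xi, xj and their difference", {
  expect_equal(pairRepresentation(c(1, 2), c(0, 1)), c(1, 2, 0, 1, 1, 1))
  expect_error(pairRepresentation(c(1, 2), c(1, 2, 3)), "mismatch")
  m <- deskModel()@config$m
  out <- forwardPair(deskModel(), deskTestTensors()[[1]], deskTestTensors()[[2]])
  expect_length(pairRepresentation(out$xi, out$xj), 3L * m)
})

test_that("an identical pair gives identical branch outputs and zero difference block", {
  model <- deskModel()
  gt <- deskTestTensors()[[1]]
  out <- forwardPair(model, gt, gt)
  expect_equal(out$xi, out$xj, tolerance = 1e-12)
  expect_equal(pairRepresentation(out$xi, out$xj)[(2 * model@config$m + 1):
                                                    (3 * model@config$m)],
               rep(0, model@config$m))
})

test_that("each prediction head has exactly three affine layers and shares nothing", {
  p <- names(deskModel()@params)
  expect_equal(sum(grepl("^reg_W", p)), 3L)
  expect_equal(sum(grepl("^cls_W", p)), 3L)
  expect_length(intersect(grep("^reg_", p, value = TRUE),
                          grep("^cls_", p, value = TRUE)), 0L)
})

test_that("the classification output lies strictly inside (0, 1)", {
  out <- forwardPair(deskModel(), deskTestTensors()[[3]], deskTestTensors()[[4]])
  expect_gt(out$phat, 0)
  expect_lt(out$phat, 1)
})

test_that("the forward pass is deterministic and permutation invariant", {
  model <- deskModel()
  s <- deskTestSeries()
  g1 <- buildComplexGraph(s@pocket, s@poses[[5]])
  g2 <- buildComplexGraph(s@pocket, s@poses[[6]])
  a <- forwardPair(model, g1, g2)
  b <- forwardPair(model, g1, g2)
  expect_identical(a$yhat, b$yhat)
  expect_identical(a$phat, b$phat)
  # relabel the atoms of ligand i
  lig <- s@poses[[5]]
  set.seed(2)
  perm <- sample(nAtoms(lig)); inv <- order(perm)
  a2 <- lig@atoms[perm, , drop = FALSE]; rownames(a2) <- NULL
  b2 <- lig@bonds; b2$i <- inv[b2$i]; b2$j <- inv[b2$j]
  gP <- buildComplexGraph(s@pocket, molStructure(a2, b2, role = "ligand"))
  cc <- forwardPair(model, gP, g2)
  expect_equal(cc$yhat, a$yhat, tolerance = 1e-6)
  expect_equal(cc$phat, a$phat, tolerance = 1e-6)
})

test_that("mismatched pockets trigger the shared-pocket warning", {
  s1 <- makeSeries(syntheticSpec(seed = 11, nLigands = 2))
  s2 <- makeSeries(syntheticSpec(seed = 12, nLigands = 2))
  model <- deskModel()
  g1 <- buildComplexGraph(s1@pocket, s1@poses[[1]])
  g2 <- buildComplexGraph(s2@pocket, s2@poses[[1]])
  expect_warning(forwardPair(model, g1, g2), "identical pocket")
})

test_that("one optimizer step reduces the loss on a single pair", {
  model <- initPairNet(pairNetConfig(m = 8L, L = 1L, precodeDepth = 1L,
                                     readoutSteps = 1L, dropout = 0,
                                     seed = 7L), deskPotential())
  tensors <- deskTrainTensors()
  pairs <- data.frame(series_id = "S11", i = "L01", j = "L02",
                      label = 1.2, stringsAsFactors = FALSE)
  m1 <- trainPairNet(model, pairs, tensors,
                     trainConfig(batchSize = 1L, lr = 1e-2, epochs = 1,
                                 alpha = 1, seed = 1L))
  h <- m1@state$history
  lossBefore <- h$loss[1]
  m2 <- trainPairNet(m1, pairs, tensors,
                     trainConfig(batchSize = 1L, lr = 1e-2, epochs = 1,
                                 alpha = 1, seed = 1L))
  expect_lt(m2@state$history$loss[1], lossBefore)
})
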