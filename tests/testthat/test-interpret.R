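# Attention extraction and substructure-mask attribution.

test_that("extracted attention matches the oracle and perturbs nothing", {
  model <- oracleModel()
  set.seed(42)
  model@params <- lapply(model@params, function(w) {
    w + matrix(rnorm(length(w), 0, 0.1), nrow(w))
  })
  gI <- oracleComplex()
  gJ <- buildComplexGraph(
    molStructure(data.frame(element = "C", x = 0, y = 0, z = 3,
                            resno = 1L, resid = "GLY", chain = "A"),
                 NULL, role = "protein"),
    toyEthane())
  att <- extractAttention(model, gI, gJ)
  ref <- manualPairForward(model, gI, gJ)
  expect_equal(att$attnI$alpha, ref$attnI, tolerance = 1e-10)
  # recording does not change the prediction
  plain <- forwardPair(model, gI, gJ, record = FALSE)
  expect_identical(att$yhat, plain$yhat)
  # per-node incoming attention sums to one; edges are kind-tagged
  sums <- tapply(att$attnI$alpha, att$attnI$dst, sum)
  expect_equal(unname(as.numeric(sums)), rep(1, length(sums)))
  expect_true(all(att$attnI$kind %in%
                    c("covalent", "virtual_distance", "virtual_aromatic")))
})

test_that("fragmentLigand cuts at ring attachments and partitions the atoms", {
  s <- deskTestSeries()
  # a di-substituted ligand: ring + two substituents -> 3 substructures
  lg <- ligandTable(s)
  di <- lg$ligand_id[vapply(s@poses[lg$ligand_id], nAtoms, 1L) == 8L][1]
  frags <- fragmentLigand(s@poses[[di]])
  expect_equal(length(frags), 3L)
  expect_setequal(unlist(frags), seq_len(8))
  sizes <- sort(vapply(frags, length, 1L))
  expect_equal(sizes, c(1L, 1L, 6L))
  # no cuttable bond: the whole ligand is one substructure
  expect_equal(fragmentLigand(toyBenzene()), list(1:6))
})

test_that("amide C-N bonds are cut", {
  # CH3-C(=O)-N-CH3 backbone
  amide <- molStructure(
    data.frame(element = c("C", "C", "O", "N", "C"),
               x = c(0, 1.5, 2.1, 2.2, 3.6), y = c(0, 0, 1.1, -1.1, -1.2),
               z = 0),
    data.frame(i = c(1, 2, 2, 4), j = c(2, 3, 4, 5),
               order = c(1, 2, 1, 1)))
  frags <- fragmentLigand(amide)
  expect_equal(length(frags), 2L)  # acyl half and amine half
})

test_that("SME attribution equals the masked-readout differences of the oracle", {
  model <- oracleModel()
  set.seed(43)
  model@params <- lapply(model@params, function(w) {
    w + matrix(rnorm(length(w), 0, 0.1), nrow(w))
  })
  pocket <- molStructure(data.frame(element = "C", x = 0, y = 0, z = 3,
                                    resno = 1L, resid = "GLY", chain = "A"),
                         NULL, role = "protein")
  compound <- toyEthane()
  reference <- molStructure(
    data.frame(element = c("C", "O"), x = c(0, 1.4), y = 0, z = 0),
    data.frame(i = 1L, j = 2L, order = 1), role = "ligand")
  res <- smeAttribution(model, compound, reference, pocket,
                        fragments = list(1L, 2L))
  gI <- buildComplexGraph(pocket, compound)
  gJ <- buildComplexGraph(pocket, reference)
  base <- manualPairForward(model, gI, gJ)$yhat
  m1 <- manualPairForward(model, gI, gJ, maskI = c(0, 1))$yhat
  m2 <- manualPairForward(model, gI, gJ, maskI = c(1, 0))$yhat
  expect_equal(res$yhat, base, tolerance = 1e-10)
  expect_equal(res$attribution, c(base - m1, base - m2), tolerance = 1e-10)
  # masking nothing changes nothing (zero attribution)
  resNone <- smeAttribution(model, compound, reference, pocket,
                            fragments = list(integer(0), 1:2))
  expect_equal(resNone$attribution[1], 0, tolerance = 1e-12)
})

test_that("normalized attributions sum to one and merging groups works", {
  model <- deskModel()
  s <- deskTestSeries()
  lg <- ligandTable(s)
  di <- lg$ligand_id[vapply(s@poses[lg$ligand_id], nAtoms, 1L) == 8L][1:2]
  res <- smeAttribution(model, s@poses[[di[1]]], s@poses[[di[2]]], s@pocket)
  expect_equal(sum(res$attributionN), 1, tolerance = 1e-9)
  if (all(res$attribution >= 0)) {
    expect_true(all(res$attributionN >= 0 & res$attributionN <= 1))
  }
  merged <- smeAttribution(model, s@poses[[di[1]]], s@poses[[di[2]]],
                           s@pocket, mergeGroups = list(c(1L, 2L)))
  expect_equal(length(merged$substructures),
               length(res$substructures) - 1L)
  # fragments must partition the ligand
  expect_error(smeAttribution(model, s@poses[[di[1]]], s@poses[[di[2]]],
                              s@pocket, fragments = list(1:3)),
               "partition")
})
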