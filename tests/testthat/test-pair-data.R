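# Activity cleaning, pIC50 conversion, pair enumeration, similarity
# filtering and label balancing.

test_that("logConvert implements pIC50 = -log10(IC50 [M])", {
  expect_equal(logConvert(1, "uM"), 6.0)
  expect_equal(logConvert(10, "nM"), 8.0)
  expect_equal(logConvert(50, "nM"), 7.30103, tolerance = 1e-5)
  expect_equal(logConvert(1e-6), 6.0)
  expect_error(logConvert(0), "positive")
  expect_error(logConvert(-2, "nM"), "positive")
})

test_that("cleanActivities drops qualified rows and unpairable series", {
  raw <- data.frame(
    ligand_id = c("a", "b", "c", "d", "e", "f"),
    series_id = c("s1", "s1", "s1", "s1", "s2", "s2"),
    ic50_nM = c("10", "> 10000", "100", "50", "25", "< 1"),
    stringsAsFactors = FALSE)
  out <- cleanActivities(raw)
  expect_named(out, "s1")  # s2 reduced to one ligand -> dropped whole
  lg <- ligandTable(out$s1)
  expect_setequal(lg$ligand_id, c("a", "c", "d"))  # 'b' qualified -> dropped
  expect_equal(lg$pic50[lg$ligand_id == "a"], 8.0)
  # a clean series passes through unchanged
  raw2 <- data.frame(ligand_id = c("x", "y", "z"), series_id = "s",
                     pic50 = c(6.2, 5.0, 7.1))
  lg2 <- ligandTable(cleanActivities(raw2)$s)
  expect_equal(lg2$pic50, c(6.2, 5.0, 7.1))
  expect_error(cleanActivities(data.frame(ligand_id = "q", series_id = "s",
                                          pic50 = NA_real_)),
               "no parseable")
})

test_that("enumeratePairs yields C(N,2) pairs with difference labels", {
  lg <- data.frame(ligand_id = paste0("L", 1:5),
                   pic50 = c(6.2, 5.0, 7.4, 6.8, 5.5))
  s <- new("CongenericSeries", seriesId = "s", ligands = lg, poses = list())
  p <- enumeratePairs(s)
  expect_equal(nrow(p), choose(5, 2))
  expect_equal(p$label[p$i == "L1" & p$j == "L2"], 1.2)
  # bidirectional expansion: antisymmetric labels for every pair
  pb <- enumeratePairs(s, bidirectional = TRUE)
  expect_equal(nrow(pb), 2 * choose(5, 2))
  for (r in seq_len(nrow(pb))) {
    mirror <- pb$label[pb$i == pb$j[r] & pb$j == pb$i[r]]
    expect_equal(pb$label[r], -mirror)
  }
  # labels reconstruct exactly from per-ligand activities
  y <- stats::setNames(lg$pic50, lg$ligand_id)
  expect_equal(pb$label, unname(y[pb$i] - y[pb$j]))
})

test_that("similarityFilter keeps pairs strictly above the threshold", {
  s <- deskTestSeries()
  lg <- ligandTable(s)
  smiles <- stats::setNames(lg$smiles, lg$ligand_id)
  pairs <- enumeratePairs(s)
  kept <- similarityFilter(pairs, smiles, threshold = 0.6)
  # brute-force oracle: recompute every similarity pair by pair
  fp <- ligandFingerprints(smiles)
  for (r in seq_len(nrow(pairs))) {
    sim <- tanimoto(fp, pairs$i[r], pairs$j[r])
    inKept <- any(kept$i == pairs$i[r] & kept$j == pairs$j[r])
    expect_equal(inKept, sim > 0.6)
    if (inKept) {
      expect_equal(kept$similarity[kept$i == pairs$i[r] &
                                     kept$j == pairs$j[r]], sim)
    }
  }
  # identical molecules have similarity 1 and are retained
  two <- pairs[1:2, ]
  two$i <- c("A1", "A1"); two$j <- c("A2", "A3")
  sm <- c(A1 = "c1ccccc1O", A2 = "c1ccccc1O", A3 = "c1ccccc1O")
  keptTwo <- similarityFilter(two, sm, threshold = 0.6)
  expect_equal(nrow(keptTwo), 2L)
  expect_equal(keptTwo$similarity, c(1, 1))
})

test_that("label balancing narrows the bin-count spread without touching labels", {
  set.seed(0)
  pairs <- data.frame(series_id = "s", i = "a", j = "b",
                      label = stats::rnorm(400, 0, 0.8))
  out <- balanceLabels(pairs, binWidth = 0.5, capRatio = 4, seed = 3)
  binOf <- function(x) floor(x / 0.5)
  sdBefore <- stats::sd(table(binOf(pairs$label)))
  sdAfter <- stats::sd(table(factor(binOf(out$label),
                                    levels = names(table(binOf(pairs$label))))))
  expect_lt(sdAfter, sdBefore)
  # occupied-bin ratio bounded by the cap
  counts <- table(binOf(out$label))
  expect_lte(max(counts) / min(counts), 4 + 1e-9)
  # only multiplicities change: every label existed before
  expect_true(all(out$label %in% pairs$label))
  # seeded: identical resample on identical seed
  out2 <- balanceLabels(pairs, binWidth = 0.5, capRatio = 4, seed = 3)
  expect_identical(out, out2)
})

test_that("a uniform label histogram passes through balancing unchanged in size", {
  pairs <- data.frame(series_id = "s", i = "a", j = "b",
                      label = rep(seq(-1.75, 1.75, by = 0.5), each = 20))
  out <- balanceLabels(pairs, binWidth = 0.5, capRatio = 4, seed = 1)
  expect_equal(nrow(out), nrow(pairs))
  expect_equal(sort(out$label), sort(pairs$label))
})

test_that("a single occupied bin is returned unchanged with a warning", {
  pairs <- data.frame(series_id = "s", i = "a", j = "b",
                      label = rep(0.1, 5))
  expect_warning(out <- balanceLabels(pairs), "single occupied")
  expect_identical(out, pairs)
})
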