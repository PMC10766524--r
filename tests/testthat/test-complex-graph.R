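# Pocket extraction, complex-graph construction, angle domains, pose
# selection.

test_that("extractPocket keeps whole residues within the cutoff, boundary inclusive", {
  # three one-atom 'residues' at 7.9, exactly 8.0, and 8.1 A from the ligand
  protein <- molStructure(
    data.frame(element = "C", x = c(7.9, 8.0, 8.1), y = 0, z = 0,
               resno = 1:3, resid = "GLY", chain = "A"),
    NULL, role = "protein")
  ligand <- molStructure(data.frame(element = "C", x = 0, y = 0, z = 0))
  pocket <- extractPocket(protein, ligand, cutoff = 8.0)
  expect_setequal(atoms(pocket)$resno, c(1L, 2L))  # 8.0 A retained
})

test_that("a mis-posed ligand (translated far away) raises the empty-pocket error", {
  protein <- makePocket(syntheticSpec(seed = 7))
  ligand <- toyEthane()
  far <- ligand
  far@atoms$x <- far@atoms$x + 50
  expect_error(extractPocket(protein, far), "no pocket within cutoff")
})

test_that("pocket extraction matches an all-pairs brute-force distance scan", {
  spec <- syntheticSpec(seed = 7)
  series <- makeSeries(spec)
  protein <- series@pocket
  ligand <- series@poses[[1]]
  pocket <- extractPocket(protein, ligand, cutoff = 8.0)
  # brute force: loop every protein atom x ligand atom pair
  pa <- atoms(protein); la <- atoms(ligand)
  keep <- character()
  for (r in unique(pa$resno)) {
    sub <- pa[pa$resno == r, ]
    dmin <- Inf
    for (i in seq_len(nrow(sub))) {
      for (j in seq_len(nrow(la))) {
        d <- sqrt((sub$x[i] - la$x[j])^2 + (sub$y[i] - la$y[j])^2 +
                    (sub$z[i] - la$z[j])^2)
        dmin <- min(dmin, d)
      }
    }
    if (dmin <= 8.0) keep <- c(keep, r)
  }
  expect_setequal(unique(atoms(pocket)$resno), as.numeric(keep))
})

test_that("ethane plus one pocket atom gives 2 covalent and 4 virtual distance directed edges", {
  g <- buildComplexGraph(toyPocketAtom(4.0), toyEthane())
  tab <- table(graphEdges(g)$kind)
  expect_equal(unname(tab[["covalent"]]), 2L)
  expect_equal(unname(tab[["virtual_distance"]]), 4L)
  expect_false("virtual_aromatic" %in% names(tab))
})

test_that("benzene contributes one centroid node and 12 directed virtual aromatic edges", {
  g <- buildComplexGraph(toyPocketAtom(4.0), toyBenzene())
  nd <- graphNodes(g)
  expect_equal(sum(nd$virtual), 1L)
  cen <- nd[nd$virtual, ]
  ringXY <- atoms(toyBenzene())[, c("x", "y")]
  expect_equal(c(cen$x, cen$y, cen$z),
               c(mean(ringXY$x), mean(ringXY$y), 0), tolerance = 1e-12)
  expect_equal(sum(graphEdges(g)$kind == "virtual_aromatic"), 12L)
})

test_that("per-kind edge counts match a brute-force re-enumeration from raw coordinates", {
  series <- makeSeries(syntheticSpec(seed = 7))
  pocket <- series@pocket; ligand <- series@poses[[2]]
  g <- buildComplexGraph(pocket, ligand)
  tab <- table(graphEdges(g)$kind)
  # brute force from the raw structures
  nCov <- 2L * (nrow(bonds(pocket)) + nrow(bonds(ligand)))
  pXYZ <- as.matrix(atoms(pocket)[, c("x", "y", "z")])
  lXYZ <- as.matrix(atoms(ligand)[, c("x", "y", "z")])
  nVd <- 0L
  for (i in seq_len(nrow(lXYZ))) {
    for (j in seq_len(nrow(pXYZ))) {
      if (sqrt(sum((lXYZ[i, ] - pXYZ[j, ])^2)) <= 5.0) nVd <- nVd + 2L
    }
  }
  nVa <- 2L * 6L  # one aromatic benzene ring in the ligand, none in pocket
  expect_equal(unname(tab[["covalent"]]), nCov)
  expect_equal(unname(tab[["virtual_distance"]]), nVd)
  expect_equal(unname(tab[["virtual_aromatic"]]), nVa)
})

test_that("every directed edge has a reverse counterpart of identical kind and length", {
  g <- buildComplexGraph(deskTestSeries()@pocket, deskTestSeries()@poses[[1]])
  e <- graphEdges(g)
  key <- paste(e$src, e$dst, e$kind, signif(e$dist, 12))
  rev <- paste(e$dst, e$src, e$kind, signif(e$dist, 12))
  expect_true(all(rev %in% key))
  vd <- e[e$kind == "virtual_distance", ]
  expect_true(all(vd$dist > 0 & vd$dist <= 5.0 + 1e-9))
})

test_that("graph construction is invariant to ligand atom order up to relabeling", {
  series <- makeSeries(syntheticSpec(seed = 7))
  lig <- series@poses[[3]]
  set.seed(4)
  perm <- sample(nAtoms(lig))
  inv <- order(perm)
  a2 <- lig@atoms[perm, , drop = FALSE]; rownames(a2) <- NULL
  b2 <- lig@bonds
  b2$i <- inv[b2$i]; b2$j <- inv[b2$j]
  lig2 <- molStructure(a2, b2, role = "ligand")
  g1 <- buildComplexGraph(series@pocket, lig)
  g2 <- buildComplexGraph(series@pocket, lig2)
  canon <- function(g) {
    e <- graphEdges(g); nd <- graphNodes(g)
    lab <- paste(round(nd$x, 6), round(nd$y, 6), round(nd$z, 6))
    sort(paste(lab[e$src], lab[e$dst], e$kind, round(e$dist, 6)))
  }
  expect_identical(canon(g1), canon(g2))
})

test_that("angleDivider maps angles into six half-open domains", {
  expect_equal(angleDivider(0)[1, ], c(1, 0, 0, 0, 0, 0))
  expect_equal(ncol(angleDivider(runif(5, 0, pi))), 6L)
  # floor(1.60 / (pi/6)) = 3 -> fourth domain
  expect_equal(which(angleDivider(1.60)[1, ] == 1), 4L)
  # boundary pi clamps into the last domain
  expect_equal(which(angleDivider(pi)[1, ] == 1), 6L)
  expect_error(angleDivider(-0.1), "outside")
  expect_error(angleDivider(pi + 0.1), "outside")
})

test_that("angleDivider partitions [0, pi]: one bin fires, frequencies near 1/6", {
  set.seed(8)
  theta <- runif(1e4, 0, pi)
  M <- angleDivider(theta)
  expect_true(all(rowSums(M) == 1))
  freq <- colSums(M) / nrow(M)
  sigma <- sqrt((1 / 6) * (5 / 6) / nrow(M))
  expect_true(all(abs(freq - 1 / 6) < 3 * sigma + 1e-12))
})

test_that("selectPose applies the MCS-RMSD acceptability rule and score ordering", {
  ref <- toyEthane()
  shift <- function(mol, dx) {
    mol@atoms$x <- mol@atoms$x + dx
    mol
  }
  # single candidate at RMSD 1.5 -> accepted
  got <- selectPose(list(shift(ref, 1.5)), scores = -7, reference = ref)
  expect_equal(got$index, 1L)
  expect_equal(got$rmsd, 1.5, tolerance = 1e-9)
  # all candidates beyond 2.0 -> NULL (ligand discarded)
  expect_null(selectPose(list(shift(ref, 2.5), shift(ref, 3)),
                         scores = c(-9, -9), reference = ref))
  # two acceptable candidates: lower (better) score wins
  got <- selectPose(list(shift(ref, 0.5), shift(ref, 1.0)),
                    scores = c(-7.2, -8.1), reference = ref)
  expect_equal(got$index, 2L)
  expect_equal(got$score, -8.1)
  # empty MCS -> error
  other <- molStructure(data.frame(element = "S", x = 0, y = 0, z = 0))
  expect_error(selectPose(list(other), scores = 0, reference = ref),
               "not congeneric")
})
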