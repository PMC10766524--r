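# Shared fixtures, built in code.  Expensive objects (series, graphs, the
# trained desk-scale model) are cached for the duration of the test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

# --- tiny hand-made structures -------------------------------------------

# ethane-like two-carbon ligand in the z = 0 plane
toyEthane <- function() {
  molStructure(
    data.frame(element = c("C", "C"), x = c(0, 1.5), y = 0, z = 0),
    data.frame(i = 1L, j = 2L, order = 1), role = "ligand", name = "ethane")
}

# single-carbon pseudo-pocket at distance d above the ethane midpoint:
# at d = 4.0 both carbons sit within sqrt(0.75^2 + 16) < 5 A
toyPocketAtom <- function(z = 4.0) {
  molStructure(
    data.frame(element = "C", x = 0.75, y = 0, z = z,
               resno = 1L, resid = "GLY", chain = "A"),
    NULL, role = "protein", name = "onepocket")
}

# flat benzene with aromatic flags set
toyBenzene <- function() {
  ang <- (0:5) * pi / 3
  molStructure(
    data.frame(element = "C", x = 1.39 * cos(ang), y = 1.39 * sin(ang),
               z = 0, aromatic = TRUE),
    data.frame(i = 1:6, j = c(2:6, 1L), order = 4, aromatic = TRUE),
    role = "ligand", name = "benzene")
}

# the tiny complex used by the manual equation oracle: one pocket carbon,
# a two-carbon ligand, both ligand atoms within the 5 A cutoff
oracleComplex <- function() {
  pocket <- molStructure(
    data.frame(element = "C", x = 0, y = 0, z = 3,
               resno = 1L, resid = "GLY", chain = "A"),
    NULL, role = "protein", name = "p1")
  ligand <- toyEthane()
  buildComplexGraph(pocket, ligand)
}

# potential table whose alphabet covers no real element: every virtual
# edge falls through to the fallback bias, which the oracle hard-codes
uncoveredPotential <- function() {
  potentialTable("Xx", seq(0, 5, by = 0.25), array(1, c(1, 1, 20)))
}

oracleModel <- function(seed = 5L) {
  initPairNet(pairNetConfig(m = 2L, L = 1L, precodeDepth = 1L,
                            readoutSteps = 1L, dropout = 0, seed = seed),
              uncoveredPotential())
}

# --- synthetic series and the trained desk-scale model -------------------

deskTrainSeries <- function() {
  cached("trainSeries", lapply(c(11, 12, 13, 14), function(sd) {
    makeSeries(syntheticSpec(seed = sd, nLigands = 8L))
  }))
}

deskTestSeries <- function() {
  cached("testSeries", makeSeries(syntheticSpec(seed = 99L, nLigands = 16L)))
}

deskPotential <- function() {
  cached("potential", {
    graphs <- unlist(lapply(deskTrainSeries(), function(s) {
      lapply(s@poses, function(p) buildComplexGraph(s@pocket, p))
    }), recursive = FALSE)
    fitReferencePotential(graphs)
  })
}

deskModel <- function(seed = 3L) {
  cached(paste0("model", seed), {
    model <- initPairNet(pairNetConfig(m = 8L, L = 1L, precodeDepth = 1L,
                                       readoutSteps = 1L, dropout = 0,
                                       seed = seed), deskPotential())
    tensors <- deskTrainTensors()
    pairs <- do.call(rbind, lapply(deskTrainSeries(), enumeratePairs,
                                   bidirectional = TRUE))
    trainPairNet(model, pairs, tensors,
                 trainConfig(batchSize = 24L, lr = 3e-3, epochs = 8,
                             seed = seed))
  })
}

deskTrainTensors <- function() {
  cached("trainTensors", {
    model <- initPairNet(pairNetConfig(m = 8L, L = 1L, precodeDepth = 1L,
                                       readoutSteps = 1L, dropout = 0,
                                       seed = 3L), deskPotential())
    prepareSeriesTensors(model, deskTrainSeries())
  })
}

deskTestTensors <- function() {
  cached("testTensors", {
    tt <- prepareSeriesTensors(deskModel(), list(deskTestSeries()))
    names(tt) <- sub("^[^:]*::", "", names(tt))
    tt
  })
}

deskTestLabels <- function() {
  s <- deskTestSeries()
  stats::setNames(s@ligands$pic50, s@ligands$ligand_id)
}

# out-of-domain target for the few-shot experiment: same substituent
# alphabet, different planted structure-activity pattern, so zero-shot
# transfer is poor and reference information genuinely matters
shiftedTestSeries <- function() {
  cached("shiftedSeries", {
    shifted <- SUBSTITUENTS
    shifts <- c(H = 0, F = 0.9, CH3 = 0.1, Cl = 0.8, NH2 = 0.25, OH = 0.45)
    for (nm in names(shifted)) {
      shifted[[nm]]$contribution <- unname(shifts[nm])
    }
    makeSeries(syntheticSpec(seed = 55L, nLigands = 16L,
                             substituents = shifted))
  })
}
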