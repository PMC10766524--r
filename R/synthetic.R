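# Synthetic congeneric-series generator: desk-scale docked-like fixtures
# with planted additive activities, so every stage of the pipeline can be
# exercised with no external data.
#
# A pseudo-pocket of glycine-like residues is arranged on a jittered
# sphere enclosing a cavity; ligands are para-substituted benzenes (a
# shared aromatic core with two substituent sites) posed in the cavity
# with a small seeded rigid jitter, emulating docking poses of a
# congeneric series.  Ground-truth pIC50 is base + the sum of substituent
# contributions + Gaussian noise; synthesis order is generation order.

SUBSTITUENTS <- list(
  H   = list(element = NA,   smiles = "",  contribution = 0.0),
  F   = list(element = "F",  smiles = "F", contribution = 0.2),
  CH3 = list(element = "C",  smiles = "C", contribution = 0.35),
  Cl  = list(element = "Cl", smiles = "Cl", contribution = 0.55),
  NH2 = list(element = "N",  smiles = "N", contribution = 0.75),
  OH  = list(element = "O",  smiles = "O", contribution = 1.0))

#' Synthetic series specification
#'
#' @param seed RNG seed (drives pocket geometry, ligand sampling, noise
#'   and pose jitter)
#' @param nResidues pseudo-residues in the pocket (12)
#' @param nLigands ligands in the series (10, at most 21 distinct
#'   para-substitution patterns)
#' @param basePic50 core scaffold activity (6.0)
#' @param noiseSd activity noise SD in pIC50 units (0.1)
#' @param jitterSd pose jitter SD in Angstrom (0.3)
#' @param pocketRadius sphere radius of the residue shell in Angstrom (6)
#' @param substituents substituent alphabet with additive contributions
#' @return named list
#' @export
syntheticSpec <- function(seed = 7L, nResidues = 12L, nLigands = 10L,
                          basePic50 = 6.0, noiseSd = 0.1, jitterSd = 0.3,
                          pocketRadius = 6.0, substituents = SUBSTITUENTS) {
  stopifnot(nResidues >= 1L, nLigands >= 1L,
            all(is.finite(vapply(substituents, `[[`, 1.0, "contribution"))))
  list(seed = as.integer(seed), nResidues = as.integer(nResidues),
       nLigands = as.integer(nLigands), basePic50 = basePic50,
       noiseSd = noiseSd, jitterSd = jitterSd, pocketRadius = pocketRadius,
       substituents = substituents)
}

# glycine-like backbone template (N, CA, C, O), centered
resTemplate <- function() {
  xyz <- rbind(N = c(0.00, 0.0, 0.0), CA = c(1.45, 0.0, 0.0),
               C = c(2.20, 1.2, 0.0), O = c(3.40, 1.2, 0.0))
  sweep(xyz, 2L, colMeans(xyz))
}

# roughly even directions on the unit sphere (Fibonacci lattice)
sphereDirections <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Generate the pseudo-protein pocket
#'
#' @param spec from \code{\link{syntheticSpec}}
#' @return a protein \linkS4class{MolStructure} with residue metadata;
#'   deterministic for a given spec
#' @export
makePocket <- function(spec = syntheticSpec()) {
  set.seed(spec$seed)
  dirs <- sphereDirections(spec$nResidues)
  tmpl <- resTemplate()
  rows <- list()
  for (r in seq_len(spec$nResidues)) {
    center <- dirs[r, ] * spec$pocketRadius + stats::rnorm(3, 0, 0.3)
    for (a in seq_len(nrow(tmpl))) {
      el <- c("N", "C", "C", "O")[a]
      rows[[length(rows) + 1L]] <- data.frame(
        element = el, x = center[1] + tmpl[a, 1],
        y = center[2] + tmpl[a, 2], z = center[3] + tmpl[a, 3],
        charge = 0, aromatic = FALSE, nH = 0L,
        resno = r, resid = "GLY", chain = "A",
        atomName = rownames(tmpl)[a], stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, rows)
  mol <- molStructure(atoms, NULL, role = "protein",
                      name = sprintf("pocket_seed%d", spec$seed))
  initialize(mol, bonds = inferBonds(mol))
}

# benzene core with substituent sites at ring positions 3 and 6 (para)
ligandFromPattern <- function(s1, s2, subs) {
  ringR <- 1.39
  ang <- (0:5) * pi / 3
  atoms <- data.frame(element = rep("C", 6),
                      x = ringR * cos(ang), y = ringR * sin(ang), z = 0,
                      charge = 0, aromatic = TRUE, nH = 0L,
                      stringsAsFactors = FALSE)
  bonds <- data.frame(i = 1:6, j = c(2:6, 1L), order = 4, aromatic = TRUE)
  for (site in c(1L, 2L)) {
    nm <- if (site == 1L) s1 else s2
    sub <- subs[[nm]]
    if (is.na(sub$element)) next
    pos <- if (site == 1L) 3L else 6L
    dir <- c(cos(ang[pos]), sin(ang[pos]))
    atoms <- rbind(atoms, data.frame(
      element = sub$element, x = 2.79 * dir[1], y = 2.79 * dir[2], z = 0,
      charge = 0, aromatic = FALSE, nH = 0L, stringsAsFactors = FALSE))
    bonds <- rbind(bonds, data.frame(i = pos, j = nrow(atoms), order = 1,
                                     aromatic = FALSE))
  }
  list(atoms = atoms, bonds = bonds,
       smiles = paste0("c1cc",
                       if (nzchar(subs[[s1]]$smiles))
                         paste0("(", subs[[s1]]$smiles, ")") else "",
                       "ccc1", subs[[s2]]$smiles))
}

rotZ <- function(a) {
  rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
}

#' Generate a synthetic congeneric series with 3-D poses
#'
#' Samples distinct para-substitution patterns of the benzene core,
#' plants additive ground-truth activities, and poses each ligand in the
#' pocket cavity with a small seeded rigid jitter.
#'
#' @param spec from \code{\link{syntheticSpec}}
#' @return a \linkS4class{CongenericSeries} with pocket, poses, SMILES,
#'   activities, synthesis order and generator truth attached
#' @export
makeSeries <- function(spec = syntheticSpec()) {
  pocket <- makePocket(spec)  # consumes the seed stream first
  subs <- spec$substituents
  nm <- names(subs)
  combos <- expand.grid(s1 = nm, s2 = nm, stringsAsFactors = FALSE)
  combos <- combos[match(combos$s1, nm) <= match(combos$s2, nm), ]
  n <- min(spec$nLigands, nrow(combos))
  if (n < spec$nLigands) warning("substituent alphabet supports only ",
                                 nrow(combos), " distinct ligands")
  pick <- combos[sample(nrow(combos), n), , drop = FALSE]
  poses <- list(); rows <- list(); truthPer <- list()
  for (k in seq_len(n)) {
    lig <- ligandFromPattern(pick$s1[k], pick$s2[k], subs)
    contrib <- subs[[pick$s1[k]]]$contribution +
      subs[[pick$s2[k]]]$contribution
    pic50 <- spec$basePic50 + contrib + stats::rnorm(1, 0, spec$noiseSd)
    xyz <- as.matrix(lig$atoms[, c("x", "y", "z")])
    xyz <- xyz %*% t(rotZ(stats::rnorm(1, 0, 0.1)))
    xyz <- sweep(xyz, 2L, stats::rnorm(3, 0, spec$jitterSd), "+")
    lig$atoms$x <- xyz[, 1]; lig$atoms$y <- xyz[, 2]; lig$atoms$z <- xyz[, 3]
    id <- sprintf("L%02d", k)
    poses[[id]] <- molStructure(lig$atoms, lig$bonds, role = "ligand",
                                name = id)
    rows[[k]] <- data.frame(ligand_id = id, smiles = lig$smiles,
                            pic50 = pic50, synth_order = k,
                            stringsAsFactors = FALSE)
    truthPer[[id]] <- list(s1 = pick$s1[k], s2 = pick$s2[k],
                           additive = spec$basePic50 + contrib)
  }
  new("CongenericSeries",
      seriesId = sprintf("S%d", spec$seed),
      ligands = do.call(rbind, rows), poses = poses, pocket = pocket,
      truth = list(basePic50 = spec$basePic50, noiseSd = spec$noiseSd,
                   contributions = lapply(subs, `[[`, "contribution"),
                   perLigand = truthPer))
}

#' Write a fixture directory (PDB pocket, SDF poses, CSV activities,
#' JSON truth)
#' @param series from \code{\link{makeSeries}}
#' @param dir output directory (created)
#' @return invisibly, the directory
#' @export
writeFixtures <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writePocketPDB(series@pocket, file.path(dir, "pocket.pdb"))
  writeLigandSDF(series@poses, file.path(dir, "poses.sdf"),
                 data = lapply(seq_len(nrow(series@ligands)), function(k) {
                   c(pic50 = sprintf("%.6f", series@ligands$pic50[k]))
                 }))
  lg <- series@ligands
  lg$series_id <- series@seriesId
  utils::write.csv(lg, file.path(dir, "activities.csv"), row.names = FALSE)
  jsonlite::write_json(series@truth, file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Load a fixture directory written by \code{\link{writeFixtures}}
#' @param dir fixture directory
#' @return a \linkS4class{CongenericSeries}
#' @export
loadFixtures <- function(dir) {
  lg <- utils::read.csv(file.path(dir, "activities.csv"),
                        stringsAsFactors = FALSE)
  poses <- readLigandSDF(file.path(dir, "poses.sdf"))
  pocket <- readPocketPDB(file.path(dir, "pocket.pdb"))
  truth <- if (file.exists(file.path(dir, "truth.json"))) {
    jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  } else list()
  new("CongenericSeries", seriesId = as.character(lg$series_id[1]),
      ligands = lg[, setdiff(names(lg), "series_id")],
      poses = poses[lg$ligand_id], pocket = pocket, truth = as.list(truth))
}
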