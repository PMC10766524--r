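# Pocket extraction and construction of the directed pocket-ligand
# complex graph with covalent, virtual distance and virtual aromatic edges.

#' Extract the binding pocket around a ligand
#'
#' Keeps whole protein residues whose minimum heavy-atom distance to any
#' ligand heavy atom is less than or equal to \code{cutoff}.
#'
#' @param protein protein MolStructure
#' @param ligand ligand MolStructure (pose in the same frame)
#' @param cutoff distance cutoff in Angstrom (default 8.0)
#' @return pocket MolStructure (whole residues, bonds restricted)
#' @export
extractPocket <- function(protein, ligand, cutoff = 8.0) {
  protein <- stripHydrogens(protein)
  ligand <- stripHydrogens(ligand)
  stopifnot(nAtoms(protein) >= 1L, nAtoms(ligand) >= 1L)
  pa <- protein@atoms
  if (is.null(pa$resno)) pa$resno <- seq_len(nrow(pa))
  if (is.null(pa$chain)) pa$chain <- "A"
  resKey <- paste(pa$chain, pa$resno)
  pXYZ <- coordMatrix(protein)
  lXYZ <- coordMatrix(ligand)
  # min distance from each protein atom to the ligand
  dmin <- apply(pXYZ, 1L, function(p) {
    sqrt(min(colSums((t(lXYZ) - p)^2)))
  })
  keepRes <- unique(resKey[dmin <= cutoff + 1e-9])
  if (!length(keepRes)) {
    stop("no pocket within cutoff: ligand appears mis-posed")
  }
  keep <- which(resKey %in% keepRes)
  remap <- integer(nrow(pa)); remap[keep] <- seq_along(keep)
  b <- protein@bonds
  bk <- b[b$i %in% keep & b$j %in% keep, , drop = FALSE]
  bk$i <- remap[bk$i]; bk$j <- remap[bk$j]
  a2 <- pa[keep, , drop = FALSE]; rownames(a2) <- NULL; rownames(bk) <- NULL
  initialize(protein, atoms = a2, bonds = bk)
}

#' Divide an angle into one of six domains over [0, pi]
#'
#' One-hot over the half-open intervals \code{[k*pi/6, (k+1)*pi/6)};
#' \code{theta == pi} is clamped into the last domain.
#'
#' @param theta angle(s) in radians, within [0, pi] (numerical slack 1e-9)
#' @return one-hot matrix with 6 columns (one row per angle)
#' @export
angleDivider <- function(theta) {
  if (any(theta < -1e-9 | theta > pi + 1e-9)) {
    stop("angle outside [0, pi]")
  }
  theta <- pmin(pmax(theta, 0), pi)
  k <- pmin(floor(theta / (pi / 6)), 5)
  m <- matrix(0, length(theta), 6L)
  m[cbind(seq_along(theta), k + 1L)] <- 1
  m
}

centroid <- function(xyz) colMeans(xyz)

#' Build the directed pocket-ligand complex graph
#'
#' Covalent bonds become two directed edges each; ligand/pocket heavy-atom
#' pairs within \code{distanceCutoff} become two directed virtual distance
#' edges; each aromatic ring (in ligand or pocket) contributes one virtual
#' node at its centroid plus two directed virtual aromatic edges per ring
#' member.  Virtual nodes and virtual edges carry all-zero features.
#'
#' @param pocket pocket MolStructure (from \code{\link{extractPocket}})
#' @param ligand ligand MolStructure (pose)
#' @param distanceCutoff virtual-distance-edge cutoff in Angstrom (5.0)
#' @return a \linkS4class{ComplexGraph}; node order is pocket atoms,
#'   ligand atoms, then virtual nodes
#' @export
buildComplexGraph <- function(pocket, ligand, distanceCutoff = 5.0) {
  pocket <- perceiveAromaticity(stripHydrogens(pocket))
  ligand <- perceiveAromaticity(stripHydrogens(ligand))
  if (nAtoms(ligand) < 1L) stop("ligand has no heavy atoms")
  if (nAtoms(pocket) < 1L) stop("pocket is empty")
  nP <- nAtoms(pocket); nL <- nAtoms(ligand)
  pXYZ <- coordMatrix(pocket); lXYZ <- coordMatrix(ligand)

  nodes <- data.frame(
    origin = c(rep("pocket", nP), rep("ligand", nL)),
    virtual = FALSE,
    element = c(pocket@atoms$element, ligand@atoms$element),
    x = c(pXYZ[, 1], lXYZ[, 1]), y = c(pXYZ[, 2], lXYZ[, 2]),
    z = c(pXYZ[, 3], lXYZ[, 3]),
    atomIdx = c(seq_len(nP), seq_len(nL)),
    stringsAsFactors = FALSE)

  src <- integer(); dst <- integer(); kind <- character()

  addBoth <- function(u, v, k) {
    src <<- c(src, u, v); dst <<- c(dst, v, u); kind <<- c(kind, k, k)
  }

  covFeatRows <- integer()  # index into the per-molecule bond feature rows
  pb <- pocket@bonds; lb <- ligand@bonds
  for (r in seq_len(nrow(pb))) {
    addBoth(pb$i[r], pb$j[r], "covalent")
    covFeatRows <- c(covFeatRows, r, r)
  }
  for (r in seq_len(nrow(lb))) {
    addBoth(nP + lb$i[r], nP + lb$j[r], "covalent")
    covFeatRows <- c(covFeatRows, nrow(pb) + r, nrow(pb) + r)
  }

  # virtual distance edges: ligand <-> pocket real atoms within cutoff
  if (nP > 0 && nL > 0) {
    d2 <- outer(rowSums(lXYZ^2), rowSums(pXYZ^2), "+") -
      2 * lXYZ %*% t(pXYZ)
    d <- sqrt(pmax(d2, 0))
    hit <- which(d <= distanceCutoff + 1e-9 & d > 1e-9, arr.ind = TRUE)
    for (r in seq_len(nrow(hit))) {
      addBoth(nP + hit[r, 1L], hit[r, 2L], "virtual_distance")
    }
  }

  # virtual aromatic nodes: one centroid per aromatic ring (both molecules)
  vNodes <- list()
  addRingNodes <- function(mol, offset, origin) {
    for (ring in aromaticRings(mol)) {
      cen <- centroid(coordMatrix(mol)[ring, , drop = FALSE])
      vNodes[[length(vNodes) + 1L]] <<- data.frame(
        origin = origin, virtual = TRUE, element = "*",
        x = cen[1], y = cen[2], z = cen[3], atomIdx = NA_integer_,
        stringsAsFactors = FALSE)
      vid <- nP + nL + length(vNodes)
      for (m in ring) addBoth(offset + m, vid, "virtual_aromatic")
    }
  }
  addRingNodes(pocket, 0L, "pocket")
  addRingNodes(ligand, nP, "ligand")
  if (length(vNodes)) nodes <- rbind(nodes, do.call(rbind, vNodes))
  rownames(nodes) <- NULL

  xyzAll <- as.matrix(nodes[, c("x", "y", "z")])
  dist <- sqrt(rowSums((xyzAll[src, , drop = FALSE] -
                        xyzAll[dst, , drop = FALSE])^2))
  edges <- data.frame(src = src, dst = dst, kind = kind, dist = dist,
                      stringsAsFactors = FALSE)

  # features
  sch <- atomFeatureSchema(); bsch <- bondFeatureSchema()
  nodeFeat <- matrix(0, nrow(nodes), attr(sch, "width"))
  if (nP) nodeFeat[seq_len(nP), ] <- featurizeAtoms(pocket)
  if (nL) nodeFeat[nP + seq_len(nL), ] <- featurizeAtoms(ligand)
  edgeFeat <- matrix(0, nrow(edges), attr(bsch, "width"))
  isCov <- edges$kind == "covalent"
  if (any(isCov)) {
    bondFeat <- rbind(
      if (nrow(pb)) featurizeBonds(pocket) else NULL,
      if (nrow(lb)) featurizeBonds(ligand) else NULL)
    edgeFeat[isCov, ] <- bondFeat[covFeatRows, , drop = FALSE]
  }

  meta <- list(nPocket = nP, nLigand = nL,
               pocketIdx = seq_len(nP),
               ligandIdx = nP + seq_len(nL),
               distanceCutoff = distanceCutoff,
               ligandName = ligand@name)
  new("ComplexGraph", nodes = nodes, edges = edges,
      nodeFeatures = nodeFeat, edgeFeatures = edgeFeat, meta = meta)
}

#' Select a docking pose consistent with a co-crystallized reference
#'
#' Computes the maximum common substructure between the candidate ligand
#' and the reference ligand once, then the RMSD over MCS atoms for each
#' candidate pose against the reference pose.  Among poses with RMSD
#' within \code{rmsdCutoff} the one with the most favorable docking score
#' is returned; \code{NULL} when no pose is acceptable (the caller should
#' discard the ligand).
#'
#' @param candidates list of MolStructure poses of one ligand
#' @param scores numeric docking scores, one per candidate
#' @param reference co-crystallized reference MolStructure
#' @param rmsdCutoff acceptability threshold in Angstrom (2.0)
#' @param lowerIsBetter docking-score sense (default TRUE: more negative
#'   is more favorable, the usual convention)
#' @return list(pose, index, rmsd, score) or NULL
#' @export
selectPose <- function(candidates, scores, reference, rmsdCutoff = 2.0,
                       lowerIsBetter = TRUE) {
  stopifnot(length(candidates) == length(scores), length(candidates) >= 1L)
  map <- mcsMap(stripHydrogens(candidates[[1L]]), stripHydrogens(reference))
  rmsds <- vapply(candidates, function(p) {
    mappedRmsd(stripHydrogens(p), stripHydrogens(reference), map)
  }, 1.0)
  ok <- which(rmsds <= rmsdCutoff + 1e-9)
  if (!length(ok)) return(NULL)
  best <- ok[if (lowerIsBetter) which.min(scores[ok]) else which.max(scores[ok])]
  list(pose = candidates[[best]], index = best, rmsd = rmsds[best],
       score = scores[best])
}
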