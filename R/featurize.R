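# Initial featurization of atoms and bonds.
#
# 15 atomic feature categories: atomic mass, explicit valence, implicit
# valence and van der Waals radius as scalars; element, heavy degree,
# formal charge, hybridization, aromaticity, in-ring flag, ring size,
# hydrogen-bond donor/acceptor flags, chirality tag and attached-hydrogen
# count as one-hots.  5 bond categories: bond order, conjugation, in-ring
# flag, stereo tag, edge-kind tag.  Virtual nodes and virtual edges carry
# all-zero feature vectors.

FEAT_ELEMENTS <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "other")
FEAT_HYBRID <- c("sp", "sp2", "sp3", "sp3d", "sp3d2", "other")
FEAT_CHIRAL <- c("none", "CW", "CCW")

oneHot <- function(value, levels) {
  m <- matrix(0, length(value), length(levels))
  idx <- match(value, levels)
  idx[is.na(idx)] <- length(levels)  # fall through to the final/other slot
  m[cbind(seq_along(value), idx)] <- 1
  m
}

#' Atomic feature schema
#'
#' @return list with one entry per feature category giving its name and
#'   width; the number of categories (15) and total width are attributes
#' @export
atomFeatureSchema <- function() {
  sch <- list(
    atomic_mass = 1L, explicit_valence = 1L, implicit_valence = 1L,
    vdw_radius = 1L,
    element = length(FEAT_ELEMENTS), degree = 6L, formal_charge = 5L,
    hybridization = length(FEAT_HYBRID), aromatic = 1L, in_ring = 1L,
    ring_size = 6L, hbond_donor = 1L, hbond_acceptor = 1L,
    chirality = length(FEAT_CHIRAL), num_hydrogens = 5L)
  structure(sch, nCategories = length(sch),
            width = sum(unlist(sch)))
}

#' Bond feature schema
#' @return list as in \code{\link{atomFeatureSchema}} (5 categories)
#' @export
bondFeatureSchema <- function() {
  sch <- list(order = 4L, conjugated = 1L, in_ring = 1L, stereo = 3L,
              edge_kind = 3L)
  structure(sch, nCategories = length(sch), width = sum(unlist(sch)))
}

#' Featurize the atoms of a molecule
#'
#' @param mol MolStructure (heavy atoms; aromaticity perceived)
#' @return numeric matrix, one row per atom, of width
#'   \code{attr(atomFeatureSchema(), "width")}; elements outside the
#'   supported alphabet map to the "other" slot
#' @export
featurizeAtoms <- function(mol) {
  a <- mol@atoms
  rings <- perceiveRings(mol)
  rm <- ringMembership(mol, rings)
  nH <- pmin(totalNumH(mol), 4L)
  deg <- pmin(heavyDegree(mol), 5L)
  chg <- pmin(pmax(round(a$charge), -2L), 2L)
  out <- cbind(
    elementInfo(a$element, "mass"),
    explicitValence(mol),
    implicitValence(mol),
    elementInfo(a$element, "vdw"),
    oneHot(a$element, FEAT_ELEMENTS),
    oneHot(deg, 0:5),
    oneHot(chg, -2:2),
    oneHot(hybridization(mol), FEAT_HYBRID),
    as.numeric(a$aromatic),
    as.numeric(rm$inRing),
    rm$sizes + 0,
    as.numeric(hbondDonor(mol)),
    as.numeric(hbondAcceptor(mol)),
    oneHot(rep("none", nrow(a)), FEAT_CHIRAL),
    oneHot(nH, 0:4))
  dimnames(out) <- NULL
  out
}

#' Featurize the covalent bonds of a molecule
#'
#' @param mol MolStructure
#' @return numeric matrix, one row per bond row in \code{bonds(mol)}
#' @export
featurizeBonds <- function(mol) {
  b <- mol@bonds
  rings <- perceiveRings(mol)
  ordClass <- ifelse(b$aromatic, "aromatic",
                     c("single", "double", "triple")[pmin(b$order, 3)])
  out <- cbind(
    oneHot(ordClass, c("single", "double", "triple", "aromatic")),
    as.numeric(conjugatedBond(mol)),
    as.numeric(inRingBond(mol, rings)),
    oneHot(rep("none", nrow(b)), c("none", "Z", "E")),
    oneHot(rep("covalent", nrow(b)),
           c("covalent", "virtual_distance", "virtual_aromatic")))
  dimnames(out) <- NULL
  out
}
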