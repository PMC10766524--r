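# Chemical perception on the package's light-weight molecule model.
# Standard file formats go through ChemmineR / ChemmineOB / bio3d; what lives
# here is the perception the graph builder needs: rings, aromaticity,
# valence-derived features, maximum common substructure, fragmentation.

ELEMENT_DATA <- data.frame(
  element = c("H", "C", "N", "O", "S", "P", "F", "Cl", "Br", "I"),
  mass    = c(1.008, 12.011, 14.007, 15.999, 32.06, 30.974, 18.998,
              35.45, 79.904, 126.904),
  vdw     = c(1.20, 1.70, 1.55, 1.52, 1.80, 1.80, 1.47, 1.75, 1.85, 1.98),
  covrad  = c(0.31, 0.76, 0.71, 0.66, 1.05, 1.07, 0.57, 1.02, 1.20, 1.39),
  valence = c(1, 4, 3, 2, 2, 3, 1, 1, 1, 1),
  stringsAsFactors = FALSE
)

elementInfo <- function(element, field) {
  i <- match(element, ELEMENT_DATA$element)
  out <- ELEMENT_DATA[[field]][i]
  # unknown elements: carbon-like geometry defaults, zero valence
  out[is.na(out)] <- switch(field, mass = 0, vdw = 1.7, covrad = 0.77,
                            valence = 0, 0)
  out
}

#' Construct a MolStructure
#'
#' @param atoms data.frame with at least element, x, y, z; missing
#'   \code{charge}, \code{aromatic}, \code{nH} columns are filled with
#'   defaults (0, FALSE, 0).
#' @param bonds data.frame with i, j, order; missing \code{aromatic} is
#'   derived from \code{order == 4} (SDF aromatic bond type).
#' @param role "protein" or "ligand".
#' @param name identifier.
#' @return a \linkS4class{MolStructure}
#' @export
molStructure <- function(atoms, bonds = NULL, role = "ligand", name = "") {
  atoms <- as.data.frame(atoms)
  if (is.null(atoms$charge)) atoms$charge <- 0
  if (is.null(atoms$aromatic)) atoms$aromatic <- FALSE
  if (is.null(atoms$nH)) atoms$nH <- 0L
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0L) {
    bonds <- data.frame(i = integer(), j = integer(), order = numeric(),
                        aromatic = logical())
  } else {
    bonds <- as.data.frame(bonds)
    if (is.null(bonds$order)) bonds$order <- 1
    if (is.null(bonds$aromatic)) bonds$aromatic <- bonds$order == 4
  }
  new("MolStructure", atoms = atoms, bonds = bonds, role = role, name = name)
}

nAtoms <- function(mol) nrow(mol@atoms)

coordMatrix <- function(mol) {
  as.matrix(mol@atoms[, c("x", "y", "z"), drop = FALSE])
}

# Remove hydrogens, recording the explicit-H count on the heavy neighbor.
stripHydrogens <- function(mol) {
  a <- mol@atoms
  hIdx <- which(a$element == "H")
  if (!length(hIdx)) return(mol)
  b <- mol@bonds
  nH <- a$nH
  for (r in seq_len(nrow(b))) {
    if (a$element[b$i[r]] == "H" && a$element[b$j[r]] != "H") {
      nH[b$j[r]] <- nH[b$j[r]] + 1L
    } else if (a$element[b$j[r]] == "H" && a$element[b$i[r]] != "H") {
      nH[b$i[r]] <- nH[b$i[r]] + 1L
    }
  }
  keep <- setdiff(seq_len(nrow(a)), hIdx)
  remap <- integer(nrow(a)); remap[keep] <- seq_along(keep)
  a <- a[keep, , drop = FALSE]; a$nH <- nH[keep]
  rownames(a) <- NULL
  bkeep <- b[!(b$i %in% hIdx | b$j %in% hIdx), , drop = FALSE]
  bkeep$i <- remap[bkeep$i]; bkeep$j <- remap[bkeep$j]
  rownames(bkeep) <- NULL
  initialize(mol, atoms = a, bonds = bkeep)
}

bondAdjacency <- function(mol) {
  n <- nAtoms(mol)
  adj <- vector("list", n)
  b <- mol@bonds
  for (r in seq_len(nrow(b))) {
    adj[[b$i[r]]] <- c(adj[[b$i[r]]], b$j[r])
    adj[[b$j[r]]] <- c(adj[[b$j[r]]], b$i[r])
  }
  adj
}

#' Ring perception
#'
#' Returns the set of smallest rings (size 3-8) found by taking, for every
#' bond, the shortest cycle through it (breadth-first search on the bond
#' graph with that bond removed), then de-duplicating by atom set --
#' a symmetrized smallest-set-of-smallest-rings surrogate adequate for
#' drug-like molecules.
#'
#' @param mol a MolStructure
#' @param maxSize largest ring size retained
#' @return list of integer atom-index vectors (in ring order)
#' @export
perceiveRings <- function(mol, maxSize = 8L) {
  b <- mol@bonds
  if (!nrow(b)) return(list())
  g <- igraph::graph_from_edgelist(cbind(b$i, b$j), directed = FALSE)
  if (igraph::vcount(g) < nAtoms(mol)) {
    g <- igraph::add_vertices(g, nAtoms(mol) - igraph::vcount(g))
  }
  rings <- list()
  seen <- character()
  for (r in seq_len(nrow(b))) {
    gg <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(b$i[r], b$j[r])))
    sp <- suppressWarnings(
      igraph::shortest_paths(gg, from = b$i[r], to = b$j[r])$vpath[[1]])
    if (length(sp) >= 2 && length(sp) <= maxSize) {
      ring <- as.integer(sp)
      key <- paste(sort(ring), collapse = ",")
      if (!key %in% seen) {
        seen <- c(seen, key)
        rings[[length(rings) + 1L]] <- ring
      }
    }
  }
  rings
}

# A ring is aromatic when every ring bond is marked aromatic (SDF type 4),
# or when the ring carries an alternating single/double Kekule pattern.
aromaticRings <- function(mol, rings = perceiveRings(mol)) {
  b <- mol@bonds
  bkey <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
  keep <- logical(length(rings))
  for (k in seq_along(rings)) {
    ring <- rings[[k]]
    n <- length(ring)
    if (n < 5 || n > 7) next
    idx <- vapply(seq_len(n), function(t) {
      u <- ring[t]; v <- ring[if (t == n) 1L else t + 1L]
      match(paste(min(u, v), max(u, v)), bkey)
    }, 1L)
    if (anyNA(idx)) next
    ords <- b$order[idx]
    arom <- b$aromatic[idx]
    if (all(arom)) { keep[k] <- TRUE; next }
    if (n %% 2 == 0 && all(ords %in% c(1, 2))) {
      # each ring atom carries exactly one in-ring double bond
      dbl <- idx[ords == 2]
      cnt <- table(factor(c(b$i[dbl], b$j[dbl]), levels = ring))
      keep[k] <- length(dbl) == n / 2 && all(cnt == 1)
    }
  }
  rings[keep]
}

# Flag aromatic atoms/bonds from perceived aromatic rings.
perceiveAromaticity <- function(mol) {
  ar <- aromaticRings(mol)
  if (!length(ar)) return(mol)
  a <- mol@atoms; b <- mol@bonds
  aidx <- unique(unlist(ar))
  a$aromatic[aidx] <- TRUE
  for (ring in ar) {
    n <- length(ring)
    for (t in seq_len(n)) {
      u <- ring[t]; v <- ring[if (t == n) 1L else t + 1L]
      hit <- (b$i == u & b$j == v) | (b$i == v & b$j == u)
      b$aromatic[hit] <- TRUE
    }
  }
  initialize(mol, atoms = a, bonds = b)
}

# Sum of bond orders at each atom (aromatic bonds count 1.5) plus explicit H.
explicitValence <- function(mol) {
  n <- nAtoms(mol)
  b <- mol@bonds
  ord <- ifelse(b$aromatic, 1.5, b$order)
  v <- numeric(n)
  for (r in seq_len(nrow(b))) {
    v[b$i[r]] <- v[b$i[r]] + ord[r]
    v[b$j[r]] <- v[b$j[r]] + ord[r]
  }
  v + mol@atoms$nH
}

implicitValence <- function(mol) {
  pmax(0, elementInfo(mol@atoms$element, "valence") - explicitValence(mol))
}

heavyDegree <- function(mol) {
  n <- nAtoms(mol)
  d <- integer(n)
  b <- mol@bonds
  for (r in seq_len(nrow(b))) {
    d[b$i[r]] <- d[b$i[r]] + 1L
    d[b$j[r]] <- d[b$j[r]] + 1L
  }
  d
}

totalNumH <- function(mol) {
  as.integer(round(mol@atoms$nH + implicitValence(mol)))
}

# sp / sp2 / sp3 heuristics from bond orders; aromatic atoms are sp2.
hybridization <- function(mol) {
  n <- nAtoms(mol)
  b <- mol@bonds
  hasTriple <- logical(n); nDouble <- integer(n)
  for (r in seq_len(nrow(b))) {
    if (!b$aromatic[r] && b$order[r] == 3) {
      hasTriple[c(b$i[r], b$j[r])] <- TRUE
    }
    if (!b$aromatic[r] && b$order[r] == 2) {
      nDouble[b$i[r]] <- nDouble[b$i[r]] + 1L
      nDouble[b$j[r]] <- nDouble[b$j[r]] + 1L
    }
  }
  out <- rep("sp3", n)
  out[nDouble == 1] <- "sp2"
  out[mol@atoms$aromatic] <- "sp2"
  out[hasTriple | nDouble >= 2] <- "sp"
  out[!mol@atoms$element %in% c("C", "N", "O", "S", "P")] <- "other"
  out
}

ringMembership <- function(mol, rings = perceiveRings(mol)) {
  n <- nAtoms(mol)
  inRing <- logical(n)
  sizes <- matrix(FALSE, n, 6L)  # ring sizes 3..8
  for (ring in rings) {
    inRing[ring] <- TRUE
    s <- length(ring)
    if (s >= 3 && s <= 8) sizes[ring, s - 2L] <- TRUE
  }
  list(inRing = inRing, sizes = sizes)
}

hbondDonor <- function(mol) {
  mol@atoms$element %in% c("N", "O", "S") & totalNumH(mol) > 0
}

hbondAcceptor <- function(mol) {
  mol@atoms$element %in% c("N", "O") & mol@atoms$charge <= 0
}

inRingBond <- function(mol, rings = perceiveRings(mol)) {
  b <- mol@bonds
  out <- logical(nrow(b))
  for (ring in rings) {
    n <- length(ring)
    for (t in seq_len(n)) {
      u <- ring[t]; v <- ring[if (t == n) 1L else t + 1L]
      out[(b$i == u & b$j == v) | (b$i == v & b$j == u)] <- TRUE
    }
  }
  out
}

conjugatedBond <- function(mol) {
  # a bond is conjugated when both atoms are sp2/sp or aromatic
  hyb <- hybridization(mol)
  b <- mol@bonds
  ok <- function(i) hyb[i] %in% c("sp", "sp2") | mol@atoms$aromatic[i]
  ok(b$i) & ok(b$j)
}

## ---- maximum common substructure ----------------------------------------

#' Maximum common substructure atom map
#'
#' Finds a maximum common substructure between two molecules via the
#' modular (compatibility) product graph and a maximum clique search
#' (igraph).  Atoms are compatible when element and aromatic flag agree;
#' a pair of atom pairs is compatible when the bonded/non-bonded relation
#' agrees in both molecules.  Suitable for the congeneric, drug-sized
#' ligands this package targets.
#'
#' @param molA,molB MolStructure objects (heavy atoms)
#' @return two-column integer matrix of matched atom indices (A, B)
#' @export
mcsMap <- function(molA, molB) {
  aA <- molA@atoms; aB <- molB@atoms
  cand <- which(outer(aA$element, aB$element, "==") &
                outer(aA$aromatic, aB$aromatic, "=="), arr.ind = TRUE)
  if (!nrow(cand)) stop("no common substructure: ligands are not congeneric")
  bondedA <- matrix(FALSE, nrow(aA), nrow(aA))
  for (r in seq_len(nrow(molA@bonds))) {
    bondedA[molA@bonds$i[r], molA@bonds$j[r]] <- TRUE
    bondedA[molA@bonds$j[r], molA@bonds$i[r]] <- TRUE
  }
  bondedB <- matrix(FALSE, nrow(aB), nrow(aB))
  for (r in seq_len(nrow(molB@bonds))) {
    bondedB[molB@bonds$i[r], molB@bonds$j[r]] <- TRUE
    bondedB[molB@bonds$j[r], molB@bonds$i[r]] <- TRUE
  }
  np <- nrow(cand)
  el <- matrix(0L, 0L, 2L)
  if (np > 1) {
    pairs <- utils::combn(np, 2L)
    keepE <- logical(ncol(pairs))
    for (c1 in seq_len(ncol(pairs))) {
      p <- cand[pairs[1L, c1], ]; q <- cand[pairs[2L, c1], ]
      if (p[1] != q[1] && p[2] != q[2] &&
          bondedA[p[1], q[1]] == bondedB[p[2], q[2]]) {
        keepE[c1] <- TRUE
      }
    }
    el <- t(pairs[, keepE, drop = FALSE])
  }
  g <- igraph::make_empty_graph(np, directed = FALSE)
  if (nrow(el)) g <- igraph::add_edges(g, t(el))
  cl <- igraph::largest_cliques(g)
  if (!length(cl)) stop("no common substructure: ligands are not congeneric")
  best <- as.integer(cl[[1L]])
  map <- cand[best, , drop = FALSE]
  map <- map[order(map[, 1L]), , drop = FALSE]
  colnames(map) <- c("A", "B")
  map
}

#' RMSD over mapped atoms (no superposition: poses share the docking frame)
#' @param molA,molB MolStructure objects
#' @param map two-column index matrix as from \code{mcsMap}
#' @return RMSD in Angstrom
#' @export
mappedRmsd <- function(molA, molB, map) {
  d <- coordMatrix(molA)[map[, 1L], , drop = FALSE] -
       coordMatrix(molB)[map[, 2L], , drop = FALSE]
  sqrt(mean(rowSums(d^2)))
}

## ---- fingerprints --------------------------------------------------------

#' Path-based fingerprints for a vector of SMILES
#'
#' Uses Open Babel's FP2 fingerprint (via ChemmineOB) -- a linear-fragment
#' hashed fingerprint filling the role of the usual 2-D similarity
#' fingerprint.  Unparseable SMILES yield NA entries with a warning.
#'
#' @param smiles character vector
#' @return a ChemmineR \code{FPset}; failed entries are all-zero rows and
#'   their names are recorded in the \code{failed} attribute
#' @export
ligandFingerprints <- function(smiles) {
  nm <- names(smiles)
  if (is.null(nm)) nm <- paste0("L", seq_along(smiles))
  sdfs <- vector("list", length(smiles))
  failed <- character()
  for (k in seq_along(smiles)) {
    sdfs[[k]] <- tryCatch(ChemmineR::smiles2sdf(smiles[k])[[1]],
                          error = function(e) NULL)
    if (is.null(sdfs[[k]])) failed <- c(failed, nm[k])
  }
  ok <- !vapply(sdfs, is.null, TRUE)
  if (!any(ok)) stop("no parseable SMILES")
  if (length(failed)) {
    warning("unparseable SMILES dropped: ", paste(failed, collapse = ", "))
  }
  set <- new("SDFset", SDF = sdfs[ok], ID = nm[ok])
  fp <- ChemmineR::fingerprintOB(set, "FP2")
  attr(fp, "failed") <- failed
  fp
}

#' Tanimoto similarity between two fingerprints in an FPset
#' @param fp FPset from \code{ligandFingerprints}
#' @param i,j names or indices
#' @return similarity in [0, 1]
#' @export
tanimoto <- function(fp, i, j) {
  as.numeric(ChemmineR::fpSim(fp[i], fp[j], method = "Tanimoto", sorted = FALSE))
}

## ---- fragmentation -------------------------------------------------------

#' Retrosynthetic-style ligand fragmentation
#'
#' Splits a ligand into substructures by cutting (i) acyclic single,
#' non-aromatic bonds with at least one end in a ring (ring-attachment
#' points) and (ii) amide C-N single bonds.  This is a rule-based
#' simplification of BRICS-style fragmentation sufficient for
#' substructure-level attribution; a molecule with no cuttable bond
#' yields a single substructure covering the whole ligand.
#'
#' @param mol a ligand MolStructure
#' @return list of integer atom-index vectors partitioning the heavy atoms
#' @export
fragmentLigand <- function(mol) {
  b <- mol@bonds
  n <- nAtoms(mol)
  if (!nrow(b)) return(list(seq_len(n)))
  rings <- perceiveRings(mol)
  ringAtom <- ringMembership(mol, rings)$inRing
  ringBond <- inRingBond(mol, rings)
  # amide carbon: C single-bonded to N and double-bonded to O
  carbonyl <- logical(n)
  for (r in seq_len(nrow(b))) {
    if (!b$aromatic[r] && b$order[r] == 2) {
      ij <- c(b$i[r], b$j[r])
      el <- mol@atoms$element[ij]
      if (setequal(el, c("C", "O"))) carbonyl[ij[el == "C"]] <- TRUE
    }
  }
  cut <- logical(nrow(b))
  for (r in seq_len(nrow(b))) {
    if (ringBond[r] || b$aromatic[r] || b$order[r] != 1) next
    i <- b$i[r]; j <- b$j[r]
    atRing <- ringAtom[i] || ringAtom[j]
    el <- mol@atoms$element[c(i, j)]
    amide <- (carbonyl[i] && el[2] == "N") || (carbonyl[j] && el[1] == "N")
    if (atRing || amide) cut[r] <- TRUE
  }
  keep <- b[!cut, , drop = FALSE]
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(keep)) g <- igraph::add_edges(g, rbind(keep$i, keep$j))
  comp <- igraph::components(g)$membership
  unname(split(seq_len(n), comp))
}
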