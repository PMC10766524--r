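# File IO: PDB via bio3d, SDF via ChemmineR, JSON debugging dumps.

#' Read a protein (or pocket) from PDB
#'
#' Elements are taken from the element column when present, otherwise from
#' the atom name; covalent bonds are inferred from covalent radii (pairs
#' closer than the radius sum plus 0.4 Angstrom), which is sufficient for
#' the pocket pre-encoding graph.
#'
#' @param file path to a PDB file
#' @return a protein \linkS4class{MolStructure}
#' @export
readPocketPDB <- function(file) {
  pdb <- bio3d::read.pdb(file)
  at <- pdb$atom
  el <- at$elesy
  if (is.null(el) || all(is.na(el)) || all(el == "")) {
    el <- sub("[0-9'*]+$", "", sub("^[0-9]+", "", at$elety))
    el <- substr(el, 1L, ifelse(toupper(el) %in% c("CL", "BR"), 2L, 1L))
  }
  el <- paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, 2)))
  el <- trimws(el)
  atoms <- data.frame(element = el, x = at$x, y = at$y, z = at$z,
                      charge = 0, aromatic = FALSE, nH = 0L,
                      resno = at$resno, resid = at$resid, chain = at$chain,
                      stringsAsFactors = FALSE)
  mol <- molStructure(atoms, NULL, role = "protein",
                      name = basename(file))
  mol <- stripHydrogens(mol)
  initialize(mol, bonds = inferBonds(mol))
}

# distance-based covalent bond inference
inferBonds <- function(mol) {
  xyz <- coordMatrix(mol)
  r <- elementInfo(mol@atoms$element, "covrad")
  n <- nrow(xyz)
  out <- list()
  if (n >= 2) {
    d <- as.matrix(stats::dist(xyz))
    thr <- outer(r, r, "+") + 0.4
    hit <- which(d > 0 & d < thr & upper.tri(d), arr.ind = TRUE)
    if (nrow(hit)) {
      out <- data.frame(i = hit[, 1], j = hit[, 2], order = 1,
                        aromatic = FALSE)
    }
  }
  if (!length(out)) {
    out <- data.frame(i = integer(), j = integer(), order = numeric(),
                      aromatic = logical())
  }
  out
}

#' Write a protein/pocket MolStructure to PDB
#' @param mol protein MolStructure
#' @param file output path
#' @export
writePocketPDB <- function(mol, file) {
  a <- mol@atoms
  xyz <- as.numeric(t(coordMatrix(mol)))
  elety <- a$element
  if (!is.null(a$atomName)) elety <- a$atomName
  bio3d::write.pdb(file = file, xyz = xyz,
                   resno = a$resno %||% rep(1L, nrow(a)),
                   resid = a$resid %||% rep("UNK", nrow(a)),
                   elety = elety,
                   chain = a$chain %||% rep("A", nrow(a)),
                   elesy = a$element)
  invisible(file)
}

#' Read ligand poses from an SDF file
#'
#' @param file path to an SDF/MOL file (V2000)
#' @return named list of ligand \linkS4class{MolStructure} objects with
#'   aromaticity perceived; names come from the molecule headers
#' @export
readLigandSDF <- function(file) {
  set <- ChemmineR::read.SDFset(file)
  out <- lapply(seq_along(ChemmineR::sdfid(set)), function(k) {
    molFromSDF(set[[k]], name = ChemmineR::sdfid(set)[k])
  })
  names(out) <- ChemmineR::sdfid(set)
  out
}

molFromSDF <- function(sdf, name = "") {
  ab <- sdf@atomblock
  bb <- sdf@bondblock
  el <- sub("_.*$", "", rownames(ab))
  atoms <- data.frame(element = el,
                      x = ab[, 1], y = ab[, 2], z = ab[, 3],
                      charge = 0, aromatic = FALSE, nH = 0L,
                      stringsAsFactors = FALSE)
  if (nrow(bb)) {
    bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                        order = as.numeric(bb[, 3]))
    bonds$aromatic <- bonds$order == 4
  } else bonds <- NULL
  mol <- molStructure(atoms, bonds, role = "ligand", name = name)
  mol <- stripHydrogens(mol)
  perceiveAromaticity(mol)
}

#' Write ligand poses to an SDF file
#' @param mols list of ligand MolStructure objects
#' @param file output path
#' @param data optional named list of per-ligand datablock vectors
#' @export
writeLigandSDF <- function(mols, file, data = NULL) {
  sdfs <- vector("list", length(mols))
  for (k in seq_along(mols)) {
    mol <- mols[[k]]
    a <- mol@atoms
    ab <- cbind(coordMatrix(mol), matrix(0, nrow(a), 13L))
    rownames(ab) <- paste(a$element, seq_len(nrow(a)), sep = "_")
    colnames(ab) <- c("C1", "C2", "C3", paste0("C", 5:17))
    b <- mol@bonds
    if (nrow(b)) {
      ord <- ifelse(b$aromatic, 4, b$order)
      bb <- cbind(b$i, b$j, ord, matrix(0, nrow(b), 4L))
    } else bb <- matrix(0, 0L, 7L)
    colnames(bb) <- paste0("C", 1:7)
    counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                      nrow(a), nrow(b))
    dat <- if (!is.null(data)) data[[k]] else character()
    if (is.null(dat)) dat <- character()
    sdfs[[k]] <- new("SDF",
                     header = c(Molecule_Name = mol@name, Source = "PocketPairNet",
                                Comment = "", Counts_Line = counts),
                     atomblock = ab, bondblock = bb,
                     datablock = dat)
  }
  ids <- vapply(mols, function(m) m@name, "")
  ids[ids == ""] <- paste0("CMP", which(ids == ""))
  set <- new("SDFset", SDF = sdfs, ID = ids)
  ChemmineR::write.SDF(set, file)
  invisible(file)
}

#' Dump a complex graph to JSON for debugging/visualization
#' @param graph a ComplexGraph
#' @param file output path
#' @export
writeGraphJSON <- function(graph, file) {
  obj <- list(nodes = graph@nodes, edges = graph@edges,
              nodeFeatures = unname(as.data.frame(graph@nodeFeatures)),
              edgeFeatures = unname(as.data.frame(graph@edgeFeatures)))
  jsonlite::write_json(obj, file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}
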