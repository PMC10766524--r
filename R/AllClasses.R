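#' @import methods
NULL

#' Molecular structure container
#'
#' Holds the heavy-atom model of a protein, pocket, or ligand pose:
#' a per-atom table (element, Cartesian coordinates in Angstrom, formal
#' charge, aromatic flag, residue metadata) and a bond table (endpoint
#' indices, order, aromatic flag).  Hydrogens may be present on input but
#' are stripped before any graph is built.
#'
#' @slot atoms data.frame with columns \code{element}, \code{x}, \code{y},
#'   \code{z}, \code{charge}, \code{aromatic}, and optionally
#'   \code{resno}, \code{resid}, \code{chain}.
#' @slot bonds data.frame with columns \code{i}, \code{j}, \code{order},
#'   \code{aromatic} (indices into \code{atoms}).
#' @slot role either \code{"protein"} or \code{"ligand"}.
#' @slot name identifier used in reports.
#' @export
setClass("MolStructure",
         representation(atoms = "data.frame", bonds = "data.frame",
                        role = "character", name = "character"),
         prototype(role = "ligand", name = ""))

setValidity("MolStructure", function(object) {
  a <- object@atoms
  b <- object@bonds
  msg <- character()
  need <- c("element", "x", "y", "z")
  if (!all(need %in% names(a))) {
    msg <- c(msg, "atoms must have element, x, y, z columns")
  } else if (nrow(a) > 0 && !all(is.finite(as.matrix(a[, c("x", "y", "z")])))) {
    msg <- c(msg, "atom coordinates must be finite")
  }
  if (nrow(b) > 0) {
    if (!all(c("i", "j") %in% names(b))) {
      msg <- c(msg, "bonds must have i, j columns")
    } else if (any(b$i < 1 | b$i > nrow(a) | b$j < 1 | b$j > nrow(a))) {
      msg <- c(msg, "bond endpoints must index valid atoms")
    }
  }
  if (!object@role %in% c("protein", "ligand")) {
    msg <- c(msg, "role must be 'protein' or 'ligand'")
  }
  if (length(msg)) msg else TRUE
})

#' Directed pocket-ligand complex graph
#'
#' Nodes are the heavy atoms of the pocket and the ligand plus one virtual
#' node per aromatic ring (at the ring centroid); directed edges are
#' covalent bonds (both directions), virtual distance edges between
#' ligand/pocket atom pairs within the distance cutoff, and virtual
#' aromatic edges between ring atoms and their centroid node.  Feature
#' matrices follow the declared featurization schema; virtual nodes and
#' virtual edges carry all-zero features.
#'
#' @slot nodes data.frame: \code{origin} ("ligand"/"pocket"), \code{virtual},
#'   \code{element}, \code{x},\code{y},\code{z}, \code{atomIdx} (index into
#'   the source structure, NA for virtual nodes).
#' @slot edges data.frame: \code{src}, \code{dst}, \code{kind}
#'   ("covalent"/"virtual_distance"/"virtual_aromatic"), \code{dist}.
#' @slot nodeFeatures numeric matrix, one row per node.
#' @slot edgeFeatures numeric matrix, one row per directed edge.
#' @slot meta list: pocket adjacency, ligand node indices, cutoffs.
#' @export
setClass("ComplexGraph",
         representation(nodes = "data.frame", edges = "data.frame",
                        nodeFeatures = "matrix", edgeFeatures = "matrix",
                        meta = "list"))

setValidity("ComplexGraph", function(object) {
  e <- object@edges
  msg <- character()
  if (nrow(e)) {
    key <- paste(e$src, e$dst, e$kind)
    rev <- paste(e$dst, e$src, e$kind)
    if (!all(rev %in% key)) {
      msg <- c(msg, "every directed edge must have its reverse counterpart")
    }
    vd <- e$kind == "virtual_distance"
    cut <- object@meta$distanceCutoff %||% 5.0
    if (any(vd) && any(e$dist[vd] <= 0 | e$dist[vd] > cut + 1e-9)) {
      msg <- c(msg, "virtual_distance edges must satisfy 0 < dist <= cutoff")
    }
  }
  if (nrow(object@nodeFeatures) != nrow(object@nodes)) {
    msg <- c(msg, "one feature row per node required")
  }
  if (nrow(object@edgeFeatures) != nrow(e)) {
    msg <- c(msg, "one feature row per edge required")
  }
  if (length(msg)) msg else TRUE
})

#' Atom-pairwise statistical potential table
#'
#' Distance-binned inverse-Boltzmann potential \eqn{P(type_k, type_u, d)}
#' over an atom-type alphabet, used as the additive attention bias of the
#' edge-to-edge and edge-to-node blocks: covalent edges receive the
#' constant bias 1, virtual edges with covered types receive
#' \eqn{2\ln P}, and uncovered types fall back to 0.8.
#'
#' @slot types atom-type alphabet (element symbols).
#' @slot breaks distance-bin edges in Angstrom covering (0, cutoff].
#' @slot values strictly positive array \code{[type, type, bin]}, symmetric
#'   in its two type dimensions.
#' @slot covalentBias,fallbackBias the fixed bias constants (1 and 0.8).
#' @export
setClass("PotentialTable",
         representation(types = "character", breaks = "numeric",
                        values = "array", covalentBias = "numeric",
                        fallbackBias = "numeric"),
         prototype(covalentBias = 1.0, fallbackBias = 0.8))

setValidity("PotentialTable", function(object) {
  msg <- character()
  v <- object@values
  nt <- length(object@types)
  nb <- length(object@breaks) - 1L
  if (!all(dim(v) == c(nt, nt, nb))) {
    msg <- c(msg, "values must be a [type, type, bin] array")
  } else {
    if (any(v <= 0)) msg <- c(msg, "all potential values must be > 0")
    for (b in seq_len(nb)) {
      if (max(abs(v[, , b] - t(v[, , b]))) > 1e-12) {
        msg <- c(msg, "potential must be symmetric in its type arguments")
        break
      }
    }
  }
  if (is.unsorted(object@breaks, strictly = TRUE)) {
    msg <- c(msg, "bin edges must be strictly increasing")
  }
  if (length(msg)) msg else TRUE
})

#' A congeneric ligand series with activities and poses
#'
#' @slot seriesId series identifier.
#' @slot ligands data.frame: \code{ligand_id}, \code{smiles}, \code{pic50},
#'   \code{synth_order}, and optionally \code{ic50_nM}, \code{qualifier}.
#' @slot poses named list of ligand \code{MolStructure} objects (3-D poses),
#'   keyed by \code{ligand_id}.
#' @slot pocket the shared pocket \code{MolStructure} (or NULL).
#' @slot truth list of generator ground truth for synthetic series.
#' @export
setClass("CongenericSeries",
         representation(seriesId = "character", ligands = "data.frame",
                        poses = "list", pocket = "ANY", truth = "list"),
         prototype(pocket = NULL, truth = list()))

setValidity("CongenericSeries", function(object) {
  lg <- object@ligands
  msg <- character()
  if (!all(c("ligand_id", "pic50") %in% names(lg))) {
    msg <- c(msg, "ligands need ligand_id and pic50 columns")
  } else {
    if (anyDuplicated(lg$ligand_id)) msg <- c(msg, "ligand ids must be unique")
    if (any(!is.finite(lg$pic50) & !is.na(lg$pic50))) {
      msg <- c(msg, "pic50 must be finite where present")
    }
  }
  if (length(msg)) msg else TRUE
})

#' The Siamese pair network model
#'
#' Configuration, learned parameters (a single copy shared by both Siamese
#' branches) and the statistical-potential table used for attention biases.
#'
#' @slot config list produced by \code{\link{pairNetConfig}}.
#' @slot params named list of numeric parameter matrices.
#' @slot potential a \code{PotentialTable}.
#' @slot state list of bookkeeping (training history, cached graphs).
#' @export
setClass("PairNet",
         representation(config = "list", params = "list",
                        potential = "ANY", state = "list"),
         prototype(state = list()))

#' Reference-anchored inference result for one test ligand
#'
#' @slot ligandId test ligand id.
#' @slot perReference data.frame: \code{reference_id}, \code{y_ref},
#'   \code{delta_hat} (predicted pairwise difference), \code{y_hat}
#'   (per-reference absolute prediction).
#' @slot mean mean of the per-reference absolute predictions.
#' @slot variance population variance (1/N) of those predictions.
#' @export
setClass("InferenceResult",
         representation(ligandId = "character", perReference = "data.frame",
                        mean = "numeric", variance = "numeric"))

setValidity("InferenceResult", function(object) {
  msg <- character()
  if (object@variance < -1e-12) msg <- c(msg, "variance must be >= 0")
  if (nrow(object@perReference) == 1L && abs(object@variance) > 1e-12) {
    msg <- c(msg, "variance must be 0 with exactly one reference")
  }
  if (length(msg)) msg else TRUE
})

#' Active-learning campaign state and log
#'
#' @slot seriesId series being optimized.
#' @slot targetId the ligand to be found (highest activity; earliest
#'   synthesized on ties).
#' @slot referenceIds current reference set.
#' @slot remainingIds candidate pool (disjoint from references).
#' @slot log data.frame: iteration, ligand_id, y_hat, sigma2, score,
#'   cumulative selection count.
#' @slot selectionOrder cumulative picks up to and including the target
#'   (the initial reference counts as 1), NA while running.
#' @export
setClass("CampaignState",
         representation(seriesId = "character", targetId = "character",
                        referenceIds = "character", remainingIds = "character",
                        log = "data.frame", selectionOrder = "numeric"))

setValidity("CampaignState", function(object) {
  if (length(intersect(object@referenceIds, object@remainingIds))) {
    "reference and candidate sets must be disjoint"
  } else TRUE
})

## ---- show methods --------------------------------------------------------

setMethod("show", "MolStructure", function(object) {
  cat(sprintf("MolStructure '%s' (%s): %d heavy atoms, %d bonds\n",
              object@name, object@role,
              sum(object@atoms$element != "H"), nrow(object@bonds)))
})

setMethod("show", "ComplexGraph", function(object) {
  tab <- table(object@edges$kind)
  cat(sprintf("ComplexGraph: %d nodes (%d virtual), %d directed edges\n",
              nrow(object@nodes), sum(object@nodes$virtual), nrow(object@edges)))
  for (k in names(tab)) cat(sprintf("  %s: %d\n", k, tab[[k]]))
})

setMethod("show", "PotentialTable", function(object) {
  cat(sprintf("PotentialTable: %d types, %d bins over (%.2f, %.2f] A\n",
              length(object@types), length(object@breaks) - 1L,
              min(object@breaks), max(object@breaks)))
})

setMethod("show", "CongenericSeries", function(object) {
  cat(sprintf("CongenericSeries '%s': %d ligands, pocket %s\n",
              object@seriesId, nrow(object@ligands),
              if (is.null(object@pocket)) "absent" else "attached"))
})

setMethod("show", "PairNet", function(object) {
  cfg <- object@config
  np <- sum(vapply(object@params, length, 1L))
  cat(sprintf(
    "PairNet: m = %d, L = %d message-passing layers, %d parameters\n",
    cfg$m, cfg$L, np))
})

setMethod("show", "InferenceResult", function(object) {
  cat(sprintf("InferenceResult '%s': mean %.3f, variance %.4f (%d references)\n",
              object@ligandId, object@mean, object@variance,
              nrow(object@perReference)))
})

setMethod("show", "CampaignState", function(object) {
  cat(sprintf("CampaignState '%s': target %s, %d references, %d remaining, %s\n",
              object@seriesId, object@targetId, length(object@referenceIds),
              length(object@remainingIds),
              if (is.na(object@selectionOrder)) "running"
              else sprintf("found at selection order %d", object@selectionOrder)))
})

## ---- accessors -----------------------------------------------------------

#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))
#' @describeIn MolStructure atom table accessor
#' @export
setMethod("atoms", "MolStructure", function(x) x@atoms)
#' @describeIn MolStructure bond table accessor
#' @export
setMethod("bonds", "MolStructure", function(x) x@bonds)

#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))
#' @describeIn ComplexGraph node table accessor
#' @export
setMethod("graphNodes", "ComplexGraph", function(x) x@nodes)
#' @describeIn ComplexGraph edge table accessor
#' @export
setMethod("graphEdges", "ComplexGraph", function(x) x@edges)

#' @export
setGeneric("ligandTable", function(x) standardGeneric("ligandTable"))
#' @describeIn CongenericSeries ligand activity table accessor
#' @export
setMethod("ligandTable", "CongenericSeries", function(x) x@ligands)

#' @export
setGeneric("ligandPoses", function(x) standardGeneric("ligandPoses"))
#' @describeIn CongenericSeries pose list accessor
#' @export
setMethod("ligandPoses", "CongenericSeries", function(x) x@poses)

`%||%` <- function(a, b) if (is.null(a)) b else a
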