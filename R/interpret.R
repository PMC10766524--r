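# Interpretability: attention-map extraction and substructure-mask
# (SME-style) attribution.

#' Extract the attention map of the last edge-to-node layer
#'
#' Runs the Siamese forward pass with attention recording and returns the
#' per-edge attention of the last distance-aware edge-to-node block for
#' both complexes, tagged by edge kind.  Recording does not perturb the
#' predictions.
#'
#' @param model a \linkS4class{PairNet}
#' @param graphI,graphJ complex graphs (or tensors) of the pair
#' @return list with \code{attnI}, \code{attnJ} (data.frames: src, dst,
#'   kind, alpha) and the pair predictions \code{yhat}, \code{phat}
#' @export
extractAttention <- function(model, graphI, graphJ) {
  out <- forwardPair(model, graphI, graphJ, record = TRUE)
  if (is.null(out$attnI)) stop("attention recording failed")
  out[c("attnI", "attnJ", "yhat", "phat")]
}

#' Substructure-mask attribution for a compound
#'
#' Splits the compound into substructures (rule-based retrosynthetic
#' fragmentation by default, or user-supplied atom groups), then re-runs
#' the readout with each substructure's ligand node states zeroed.
#' The attribution of substructure s is yhat - yhat_s, where yhat is the
#' predicted pairwise difference of the compound against the chosen
#' reference ligand; message passing is not re-run, only the readout sees
#' the mask.  Normalized scores (attribution / sum) are guaranteed to lie
#' in [0, 1] and sum to 1 only when all raw attributions are
#' non-negative; with mixed signs the raw scores are authoritative and a
#' warning is emitted.
#'
#' @param model a \linkS4class{PairNet}
#' @param compound ligand MolStructure of the compound to explain
#' @param reference ligand MolStructure of the reference
#' @param pocket shared pocket MolStructure
#' @param fragments optional list of atom-index vectors; default
#'   \code{\link{fragmentLigand}(compound)}
#' @param mergeGroups optional list of integer vectors of fragment indices
#'   to merge (e.g. the two halves of an amide)
#' @return list: \code{substructures}, \code{yhat},
#'   \code{yhatMasked}, \code{attribution}, \code{attributionN}
#' @export
smeAttribution <- function(model, compound, reference, pocket,
                           fragments = NULL, mergeGroups = NULL) {
  compound <- stripHydrogens(compound)
  if (is.null(fragments)) fragments <- fragmentLigand(compound)
  if (!is.null(mergeGroups)) {
    merged <- lapply(mergeGroups, function(g) {
      sort(unique(unlist(fragments[g])))
    })
    rest <- setdiff(seq_along(fragments), unlist(mergeGroups))
    fragments <- c(fragments[rest], merged)
  }
  allAtoms <- sort(unlist(fragments))
  if (!identical(allAtoms, seq_len(nAtoms(compound)))) {
    stop("fragments must partition the compound's heavy atoms")
  }
  gI <- buildComplexGraph(pocket, compound)
  gJ <- buildComplexGraph(pocket, reference)
  gtI <- graphTensors(gI, model@potential)
  gtJ <- graphTensors(gJ, model@potential)
  base <- forwardMasked(model, gtI, gtJ, maskI = NULL)
  yhatMasked <- vapply(fragments, function(fr) {
    mask <- rep(1, length(gtI$ligIdx))
    mask[fr] <- 0  # ligand nodes are ordered by atom index
    forwardMasked(model, gtI, gtJ, maskI = mask)
  }, 1.0)
  attribution <- base - yhatMasked
  total <- sum(attribution)
  attributionN <- if (abs(total) > 1e-12) attribution / total else
    rep(NA_real_, length(attribution))
  if (any(attribution < 0) && any(attribution > 0)) {
    warning("mixed-sign attributions: normalized scores can leave [0, 1]; ",
            "interpret the raw scores")
  }
  list(substructures = fragments, yhat = base, yhatMasked = yhatMasked,
       attribution = attribution, attributionN = attributionN)
}

forwardMasked <- function(model, gtI, gtJ, maskI = NULL) {
  tape <- newTape()
  pv <- paramNodes(tape, model@params)
  out <- forwardPairAD(tape, pv, gtI, gtJ, model@config, maskI = maskI)
  out$yhat$val[1]
}

#' Export attention or attribution results as JSON
#' @param x result of \code{\link{extractAttention}} or
#'   \code{\link{smeAttribution}}
#' @param file output path
#' @export
writeInterpretJSON <- function(x, file) {
  jsonlite::write_json(x, file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}
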