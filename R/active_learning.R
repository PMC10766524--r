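# Acquisition scoring and the iterative lead-optimization campaign
# simulator.

#' Acquisition score
#'
#' First iteration: the predicted activity alone.  Later iterations:
#' predicted activity plus beta times the prediction variance, where beta
#' tunes the exploration-exploitation trade-off (beta > 0 favors
#' exploration, beta < 0 penalizes uncertain picks).
#'
#' @param yhat predicted activity
#' @param sigma2 prediction variance (>= 0)
#' @param beta exploration weight
#' @param nIte iteration number (1-based)
#' @return acquisition score(s)
#' @export
acquisitionScore <- function(yhat, sigma2, beta, nIte) {
  if (any(sigma2 < 0)) stop("sigma2 must be >= 0")
  if (nIte == 1L) yhat else yhat + beta * sigma2
}

#' Acquisition configuration
#' @param beta exploration weight (tested settings: -2, 0, 2)
#' @param picks ligands selected per iteration (3)
#' @param maxIter safety bound on iterations
#' @param countInitialReference whether the initial reference counts as
#'   selection 1 (reporting flag; default TRUE)
#' @export
acquisitionConfig <- function(beta = 0, picks = 3L, maxIter = 100L,
                              countInitialReference = TRUE) {
  stopifnot(picks >= 1L)
  list(beta = beta, picks = as.integer(picks), maxIter = as.integer(maxIter),
       countInitialReference = countInitialReference)
}

#' Model-backed scorer for campaign simulation
#'
#' Returns a scorer closure: at iteration 1 it scores candidates against
#' the single reference with the base model; from iteration 2 on it
#' fine-tunes the model on all pairs among the current references, then
#' scores candidates with reference-anchored mean and variance.
#'
#' @param model a trained \linkS4class{PairNet}
#' @param tensors named tensor list for every ligand of the series
#'   (plain ligand ids)
#' @param labels named pIC50 vector (the simulation oracle reveals the
#'   label of each ligand once it becomes a reference)
#' @param ftConfig fine-tuning configuration
#' @return function(referenceIds, candidateIds, nIte) -> data.frame
#' @export
modelScorer <- function(model, tensors, labels,
                        ftConfig = fineTuneConfig()) {
  force(model); force(tensors); force(labels)
  function(referenceIds, candidateIds, nIte) {
    m <- model
    if (nIte >= 2L && length(referenceIds) >= 2L) {
      m <- fineTunePairNet(m, tensors[referenceIds], labels[referenceIds],
                           ftConfig)
    }
    rankCandidates(m, tensors[referenceIds], labels[referenceIds],
                   tensors[candidateIds])
  }
}

#' Perfect- or noisy-oracle scorer
#'
#' Scores each candidate with its true activity plus seeded Gaussian
#' noise; the variance column carries the (known) noise variance.  Used
#' for campaign sanity checks and as a baseline.
#'
#' @param labels named true pIC50 vector
#' @param noiseSd noise standard deviation (0 = perfect oracle)
#' @param seed RNG seed
#' @return scorer closure as in \code{\link{modelScorer}}
#' @export
oracleScorer <- function(labels, noiseSd = 0, seed = 1L) {
  force(labels); force(noiseSd)
  rng <- seed
  function(referenceIds, candidateIds, nIte) {
    set.seed(rng + nIte)
    data.frame(ligand_id = candidateIds,
               y_hat = labels[candidateIds] +
                 stats::rnorm(length(candidateIds), 0, noiseSd),
               sigma2 = rep(noiseSd^2, length(candidateIds)),
               stringsAsFactors = FALSE)
  }
}

#' Simulate an active-learning lead-optimization campaign
#'
#' The target ligand is the one with the highest activity (earliest
#' synthesized on ties).  Iteration 1 starts from the earliest-synthesized
#' ligand as the sole reference, scores the remaining candidates, and
#' picks the top \code{picks} by acquisition score; picked ligands whose
#' batch does not contain the target become references for the next
#' iteration, where the scorer may fine-tune on all reference pairs.
#' Ties in the acquisition score are broken by ligand id.
#'
#' @param series a \linkS4class{CongenericSeries} with synthesis order
#' @param scorer scorer closure (\code{\link{modelScorer}} or
#'   \code{\link{oracleScorer}})
#' @param config from \code{\link{acquisitionConfig}}
#' @return a \linkS4class{CampaignState} with the per-iteration log and
#'   final selection order
#' @export
runCampaign <- function(series, scorer, config = acquisitionConfig()) {
  lg <- series@ligands
  if (is.null(lg$synth_order) || anyNA(lg$synth_order)) {
    stop("series lacks synthesis-order indices")
  }
  targetId <- lg$ligand_id[order(-lg$pic50, lg$synth_order)][1L]
  refIds <- lg$ligand_id[which.min(lg$synth_order)]
  remaining <- setdiff(lg$ligand_id, refIds)
  count <- if (config$countInitialReference) 1L else 0L
  log <- data.frame()
  selOrder <- NA_real_
  if (targetId == refIds[1L]) {
    selOrder <- count
    remaining <- setdiff(remaining, targetId)
  }
  nIte <- 0L
  while (is.na(selOrder) && length(remaining) && nIte < config$maxIter) {
    nIte <- nIte + 1L
    sc <- scorer(refIds, remaining, nIte)
    sc$score <- acquisitionScore(sc$y_hat, sc$sigma2, config$beta, nIte)
    sc <- sc[order(-sc$score, sc$ligand_id), , drop = FALSE]
    picks <- utils::head(sc, config$picks)
    picks$iteration <- nIte
    picks$cumulative <- count + seq_len(nrow(picks))
    log <- rbind(log, picks)
    count <- count + nrow(picks)
    if (targetId %in% picks$ligand_id) {
      selOrder <- picks$cumulative[picks$ligand_id == targetId]
    } else {
      refIds <- c(refIds, picks$ligand_id)
      remaining <- setdiff(remaining, picks$ligand_id)
    }
  }
  new("CampaignState", seriesId = series@seriesId, targetId = targetId,
      referenceIds = refIds,
      remainingIds = setdiff(remaining, c(refIds, targetId)),
      log = log, selectionOrder = as.numeric(selOrder))
}
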