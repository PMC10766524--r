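# Reference-anchored inference with uncertainty, unit conversions, and
# evaluation metrics.

GAS_CONSTANT_KCAL <- 1.987e-3  # kcal K^-1 mol^-1
TEMPERATURE_K <- 297
RT_LN10 <- GAS_CONSTANT_KCAL * TEMPERATURE_K * log(10)

#' Anchor pairwise predictions to absolute affinities
#'
#' Given predicted pairwise differences \eqn{\hat y^{(i,u)}} of each
#' reference i against the test ligand u and the known reference labels
#' \eqn{y^{(i)}}, the per-reference absolute predictions are
#' \eqn{\hat y_i^{(u)} = y^{(i)} - \hat y^{(i,u)}}; the final prediction
#' is their mean and the uncertainty their population variance (1/N).
#'
#' @param deltaHat numeric vector of pairwise predictions (reference minus
#'   test ligand), optionally named by reference id
#' @param refLabels numeric vector of reference pIC50 values (same order)
#' @param ligandId test ligand id (for reporting)
#' @return an \linkS4class{InferenceResult}
#' @export
inferAbsolute <- function(deltaHat, refLabels, ligandId = "u") {
  n <- length(refLabels)
  if (n < 1L) stop("at least one reference required")
  stopifnot(length(deltaHat) == n)
  perRef <- refLabels - deltaHat
  mu <- mean(perRef)
  s2 <- mean((mu - perRef)^2)  # population variance (1/N)
  ids <- names(deltaHat) %||% paste0("ref", seq_len(n))
  new("InferenceResult", ligandId = ligandId,
      perReference = data.frame(reference_id = ids, y_ref = refLabels,
                                delta_hat = deltaHat, y_hat = perRef,
                                stringsAsFactors = FALSE),
      mean = mu, variance = s2)
}

#' Convert a binding free energy to the pIC50 scale
#'
#' pIC50 = -log10(exp(dG / (R T))) with R = 1.987e-3 kcal/(K mol) and
#' T = 297 K (non-competitive binding assumption).
#' @param dG free energy in kcal/mol
#' @return pIC50-scale value
#' @export
dgToPic50 <- function(dG) {
  -log10(exp(dG / (GAS_CONSTANT_KCAL * TEMPERATURE_K)))
}

#' Convert a pIC50-scale quantity to kcal/mol
#' @param pic50 value in pIC50 units
#' @return value in kcal/mol (factor RT ln 10)
#' @export
pic50ToKcal <- function(pic50) pic50 * RT_LN10

#' Root-mean-square error
#' @param y,yhat equal-length numeric vectors
#' @return sqrt(mean((y - yhat)^2))
#' @export
rmse <- function(y, yhat) {
  if (!length(y) || length(y) != length(yhat)) stop("empty or unequal input")
  sqrt(mean((y - yhat)^2))
}

#' Pairwise root-mean-square error
#'
#' RMSE over paired samples (pair labels vs pair predictions); identical
#' in form to \code{\link{rmse}} applied to the pairwise residual vector.
#' @param deltaTrue,deltaHat pairwise labels and predictions
#' @param unit "pic50" or "kcal" (kcal applies the RT ln 10 factor)
#' @export
rmsePw <- function(deltaTrue, deltaHat, unit = c("pic50", "kcal")) {
  unit <- match.arg(unit)
  out <- rmse(deltaTrue, deltaHat)
  if (unit == "kcal") out <- pic50ToKcal(out)
  out
}

#' Pearson and Spearman correlation
#'
#' Thin wrappers with the degenerate-input contract: fewer than three
#' samples or a constant vector raises an error (the correlation is
#' undefined there).  Spearman uses average ranks on ties.
#' @param y,yhat numeric vectors
#' @return the correlation coefficient
#' @export
pearsonR <- function(y, yhat) {
  if (length(y) < 3L) stop("need at least 3 samples")
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0) stop("constant input")
  stats::cor(y, yhat, method = "pearson")
}

#' @rdname pearsonR
#' @export
spearmanRho <- function(y, yhat) {
  if (length(y) < 3L) stop("need at least 3 samples")
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0) stop("constant input")
  stats::cor(y, yhat, method = "spearman")
}

#' Lead-optimization campaign metrics
#'
#' @param experimentalOrder position at which the experimental synthesis
#'   order reached the target compound
#' @param modelOrder position at which the model-guided selection reached it
#' @param nLigands series size
#' @return list with \code{advantageOrder} (difference),
#'   \code{advantageRatio} (difference / nLigands x 100, the percentage of
#'   resources saved) and \code{efficiencyImprovementRatio}
#'   (difference / modelOrder x 100)
#' @export
leadOptMetrics <- function(experimentalOrder, modelOrder, nLigands) {
  stopifnot(experimentalOrder >= 1, modelOrder >= 1,
            nLigands >= max(experimentalOrder, modelOrder))
  adv <- experimentalOrder - modelOrder
  list(advantageOrder = adv,
       advantageRatio = adv / nLigands * 100,
       efficiencyImprovementRatio = adv / modelOrder * 100)
}

#' Score candidate ligands against a reference set
#'
#' Runs the Siamese forward pass for every (reference, candidate) pair and
#' anchors the pairwise predictions to absolute pIC50 values.
#'
#' @param model a \linkS4class{PairNet}
#' @param refTensors named list of reference graph tensors (names = ids)
#' @param refLabels named numeric vector of reference pIC50 values
#' @param candTensors named list of candidate graph tensors
#' @return data.frame: ligand_id, y_hat (mean), sigma2 (population
#'   variance); the per-candidate \linkS4class{InferenceResult}s are
#'   attached as the \code{results} attribute
#' @export
rankCandidates <- function(model, refTensors, refLabels, candTensors) {
  stopifnot(length(refTensors) >= 1L,
            all(names(refTensors) %in% names(refLabels)))
  results <- vector("list", length(candTensors))
  for (ci in seq_along(candTensors)) {
    dh <- vapply(names(refTensors), function(rid) {
      forwardPair(model, refTensors[[rid]], candTensors[[ci]])$yhat
    }, 1.0)
    results[[ci]] <- inferAbsolute(dh, refLabels[names(refTensors)],
                                   ligandId = names(candTensors)[ci])
  }
  out <- data.frame(
    ligand_id = names(candTensors),
    y_hat = vapply(results, function(r) r@mean, 1.0),
    sigma2 = vapply(results, function(r) r@variance, 1.0),
    stringsAsFactors = FALSE)
  attr(out, "results") <- results
  out
}

#' Evaluate ranking metrics on a series with random reference selection
#'
#' Mirrors the reporting convention of repeating the test with randomly
#' drawn references to absorb reference-choice randomness: for each
#' repeat, \code{nRefs} reference ligands are drawn, the remaining ligands
#' are scored, and Pearson R, Spearman rho and RMSE are computed on the
#' anchored predictions.
#'
#' @param model a \linkS4class{PairNet}
#' @param tensors named list of graph tensors for every ligand
#' @param labels named pIC50 vector
#' @param nRefs references per repeat
#' @param nRepeats number of repeats (default 10)
#' @param seed RNG seed
#' @return data.frame with one row per repeat: pearson, spearman, rmse
#' @export
evaluateSeries <- function(model, tensors, labels, nRefs = 1L,
                           nRepeats = 10L, seed = 1L) {
  ids <- names(tensors)
  stopifnot(length(ids) > nRefs + 2L)
  set.seed(seed)
  rows <- lapply(seq_len(nRepeats), function(rep) {
    refs <- sample(ids, nRefs)
    cand <- setdiff(ids, refs)
    sc <- rankCandidates(model, tensors[refs], labels, tensors[cand])
    data.frame(repeat_id = rep,
               pearson = pearsonR(labels[cand], sc$y_hat),
               spearman = spearmanRho(labels[cand], sc$y_hat),
               rmse = rmse(labels[cand], sc$y_hat))
  })
  do.call(rbind, rows)
}
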