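# Hybrid-loss training, early stopping, and the few-shot fine-tuning
# protocol.

#' Training configuration
#'
#' Defaults follow the reference protocol for full-scale training: batch
#' size 96, learning rate 5e-7, 5.75 epochs (implemented as a step budget
#' of ceiling(5.75 x steps per epoch)), validation every 0.25 epoch.
#' Desk-scale experiments pass smaller/faster values explicitly.
#'
#' @param alpha weight of the classification (entropy) loss term (1)
#' @param batchSize mini-batch size (96)
#' @param lr learning rate (5e-7)
#' @param epochs training epochs, may be fractional (5.75)
#' @param evalUnit early-stopping evaluation unit in epochs (0.25)
#' @param patience early-stopping patience in evaluation units (8)
#' @param clip gradient-norm clip (5)
#' @param seed RNG seed
#' @return named list
#' @export
trainConfig <- function(alpha = 1, batchSize = 96L, lr = 5e-7,
                        epochs = 5.75, evalUnit = 0.25, patience = 8L,
                        clip = 5, seed = 1L) {
  stopifnot(alpha >= 0, batchSize >= 1L)
  list(alpha = alpha, batchSize = as.integer(batchSize), lr = lr,
       epochs = epochs, evalUnit = evalUnit, patience = as.integer(patience),
       clip = clip, seed = as.integer(seed))
}

#' Fine-tuning configuration
#'
#' Few-shot protocol: batch size 30, 10 epochs, learning rate 1e-5, and
#' no auxiliary classification task (the classification head is frozen).
#' @inheritParams trainConfig
#' @export
fineTuneConfig <- function(batchSize = 30L, epochs = 10, lr = 1e-5,
                           clip = 5, seed = 1L) {
  list(alpha = 0, batchSize = as.integer(batchSize), lr = lr,
       epochs = epochs, evalUnit = Inf, patience = 0L, clip = clip,
       seed = as.integer(seed), freezeCls = TRUE)
}

#' Hybrid training loss
#'
#' Mean squared error on the predicted pairwise difference plus
#' \code{alpha} times the binary cross-entropy of the ranking head.
#' Tie pairs (label exactly 0) are excluded from the entropy term.
#'
#' @param yhat predicted pairwise differences
#' @param ytil true pairwise differences
#' @param phat predicted probabilities that ligand i is more active
#' @param alpha classification weight (1)
#' @return scalar loss
#' @export
hybridLoss <- function(yhat, ytil, phat, alpha = 1) {
  mse <- mean((yhat - ytil)^2)
  keep <- ytil != 0
  ent <- 0
  if (alpha > 0 && any(keep)) {
    cls <- as.numeric(ytil[keep] > 0)
    p <- pmin(pmax(phat[keep], 1e-12), 1 - 1e-12)
    ent <- mean(-(cls * log(p) + (1 - cls) * log(1 - p)))
  }
  mse + alpha * ent
}

## ---- optimizer -----------------------------------------------------------

adamInit <- function(params) {
  list(m = lapply(params, function(w) w * 0),
       v = lapply(params, function(w) w * 0), t = 0L)
}

adamStep <- function(params, grads, state, lr, clip = 5,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                     freeze = character()) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), 1.0)))
  scale <- if (is.finite(gn) && gn > clip) clip / gn else 1
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    if (nm %in% freeze) next
    g <- grads[[nm]] * scale
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / corr1
    vhat <- state$v[[nm]] / corr2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# one optimization step on a batch of pairs; returns loss and new params
batchStep <- function(params, cfg, batch, tensors, tcfg, adam,
                      freeze = character()) {
  tape <- newTape()
  pv <- paramNodes(tape, params)
  lossNode <- NULL
  nEnt <- 0L
  entNode <- NULL
  for (r in seq_len(nrow(batch))) {
    gi <- tensors[[batch$keyI[r]]]
    gj <- tensors[[batch$keyJ[r]]]
    out <- forwardPairAD(tape, pv, gi, gj, cfg, training = TRUE)
    resid <- adSub(tape, out$yhat, adConst(tape, matrix(batch$label[r], 1, 1)))
    sq <- adMul(tape, resid, resid)
    lossNode <- if (is.null(lossNode)) sq else adAdd(tape, lossNode, sq)
    if (tcfg$alpha > 0 && batch$label[r] != 0) {
      cls <- as.numeric(batch$label[r] > 0)
      p <- out$phat
      bce <- if (cls == 1) {
        adScale(tape, adLog(tape, p), -1)
      } else {
        adScale(tape, adLog(tape,
          adSub(tape, adConst(tape, matrix(1, 1, 1)), p)), -1)
      }
      entNode <- if (is.null(entNode)) bce else adAdd(tape, entNode, bce)
      nEnt <- nEnt + 1L
    }
  }
  total <- adScale(tape, lossNode, 1 / nrow(batch))
  if (!is.null(entNode)) {
    total <- adAdd(tape, total,
                   adScale(tape, entNode, tcfg$alpha / nEnt))
  }
  if (!is.finite(total$val[1])) {
    stop("training diverged: non-finite loss (try a lower learning rate)")
  }
  adBackward(tape, total)
  grads <- lapply(pv, function(nd) {
    if (is.null(nd$grad)) nd$val * 0 else nd$grad
  })
  upd <- adamStep(params, grads, adam, tcfg$lr, tcfg$clip, freeze = freeze)
  list(params = upd$params, adam = upd$state, loss = total$val[1])
}

# validation loss: pairwise RMSE over a pair table
validationRmsePw <- function(params, cfg, pairs, tensors) {
  preds <- vapply(seq_len(nrow(pairs)), function(r) {
    tape <- newTape()
    pv <- paramNodes(tape, params)
    out <- forwardPairAD(tape, pv, tensors[[pairs$keyI[r]]],
                         tensors[[pairs$keyJ[r]]], cfg)
    out$yhat$val[1]
  }, 1.0)
  rmsePw(pairs$label, preds)
}

pairKeys <- function(pairs) {
  pairs$keyI <- paste(pairs$series_id, pairs$i, sep = "::")
  pairs$keyJ <- paste(pairs$series_id, pairs$j, sep = "::")
  pairs
}

#' Precompute graph tensors for every ligand of a set of series
#'
#' Builds the pocket-ligand complex graph for each pose and caches its
#' static tensors, keyed by \code{"seriesId::ligandId"}.
#' @param model a PairNet (supplies the potential table)
#' @param seriesList list of \linkS4class{CongenericSeries} with poses and
#'   pockets attached
#' @return named list of tensor lists
#' @export
prepareSeriesTensors <- function(model, seriesList) {
  out <- list()
  for (s in seriesList) {
    pocket <- s@pocket
    for (id in names(s@poses)) {
      g <- buildComplexGraph(pocket, s@poses[[id]])
      out[[paste(s@seriesId, id, sep = "::")]] <-
        graphTensors(g, model@potential)
    }
  }
  out
}

#' Assign whole series to cross-validation folds
#'
#' Folds never split a congeneric series: assignment is by series id.
#' @param seriesIds character vector of series ids
#' @param k number of folds
#' @param seed RNG seed
#' @return named integer vector of fold ids
#' @export
seriesFolds <- function(seriesIds, k = 5L, seed = 1L) {
  ids <- unique(seriesIds)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), length(ids)))
  stats::setNames(fold[match(seriesIds, ids)], seriesIds)
}

#' Train the pair network
#'
#' Seeded mini-batch optimization with Adam; when validation pairs are
#' supplied, the pairwise RMSE is evaluated every \code{evalUnit} epochs
#' and the best-validation parameters are returned (early stopping with
#' the configured patience).
#'
#' @param model a \linkS4class{PairNet}
#' @param pairs training pair table (\code{series_id}, \code{i}, \code{j},
#'   \code{label})
#' @param tensors named tensor list from \code{\link{prepareSeriesTensors}}
#' @param config from \code{\link{trainConfig}}
#' @param valPairs optional validation pair table
#' @return the trained \linkS4class{PairNet}; the per-step loss log and
#'   validation history are stored in \code{model@state$history}
#' @export
trainPairNet <- function(model, pairs, tensors, config = trainConfig(),
                         valPairs = NULL) {
  stopifnot(nrow(pairs) >= 1L)
  pairs <- pairKeys(pairs)
  if (!is.null(valPairs)) valPairs <- pairKeys(valPairs)
  cfg <- model@config
  params <- model@params
  adam <- adamInit(params)
  stepsPerEpoch <- max(1L, ceiling(nrow(pairs) / config$batchSize))
  nSteps <- ceiling(config$epochs * stepsPerEpoch)
  evalEvery <- max(1L, round(config$evalUnit * stepsPerEpoch))
  set.seed(config$seed)
  best <- list(params = params, val = Inf)
  badEvals <- 0L
  log <- data.frame()
  ord <- integer()
  for (step in seq_len(nSteps)) {
    if (length(ord) < config$batchSize) {
      ord <- c(ord, sample(nrow(pairs)))
    }
    idx <- ord[seq_len(min(config$batchSize, length(ord)))]
    ord <- ord[-seq_len(min(config$batchSize, length(ord)))]
    res <- batchStep(params, cfg, pairs[idx, , drop = FALSE], tensors,
                     config, adam)
    params <- res$params; adam <- res$adam
    row <- data.frame(step = step, split = "train", loss = res$loss,
                      val = NA_real_)
    if (!is.null(valPairs) && is.finite(config$evalUnit) &&
        step %% evalEvery == 0L) {
      v <- validationRmsePw(params, cfg, valPairs, tensors)
      row$val <- v
      if (v < best$val - 1e-9) {
        best <- list(params = params, val = v)
        badEvals <- 0L
      } else {
        badEvals <- badEvals + 1L
        if (badEvals >= config$patience) {
          log <- rbind(log, row)
          break
        }
      }
    }
    log <- rbind(log, row)
  }
  if (!is.null(valPairs) && is.finite(best$val)) params <- best$params
  out <- model
  out@params <- params
  out@state$history <- log
  out@state$bestVal <- best$val
  out
}

#' Few-shot fine-tuning on reference ligands
#'
#' Forms all pairs among the reference ligands only (both directions),
#' optimizes the regression loss alone (the auxiliary classification head
#' is frozen and its parameters are untouched), and returns the updated
#' model.  The references are retained for anchored inference.
#'
#' @param model a trained \linkS4class{PairNet}
#' @param refTensors named tensor list for the reference ligands
#' @param refLabels named pIC50 vector
#' @param config from \code{\link{fineTuneConfig}}
#' @return fine-tuned \linkS4class{PairNet}
#' @export
fineTunePairNet <- function(model, refTensors, refLabels,
                            config = fineTuneConfig()) {
  ids <- names(refTensors)
  if (length(ids) < 2L) stop("need at least two reference ligands")
  stopifnot(all(ids %in% names(refLabels)))
  idx <- utils::combn(length(ids), 2L)
  pairs <- data.frame(
    series_id = "ft",
    i = c(ids[idx[1L, ]], ids[idx[2L, ]]),
    j = c(ids[idx[2L, ]], ids[idx[1L, ]]), stringsAsFactors = FALSE)
  pairs$label <- refLabels[pairs$i] - refLabels[pairs$j]
  keyed <- stats::setNames(refTensors, paste("ft", ids, sep = "::"))
  freeze <- grep("^cls_", names(model@params), value = TRUE)
  cfgFT <- config
  cfgFT$alpha <- 0
  pairs <- pairKeys(pairs)
  params <- model@params
  adam <- adamInit(params)
  stepsPerEpoch <- max(1L, ceiling(nrow(pairs) / cfgFT$batchSize))
  nSteps <- ceiling(cfgFT$epochs * stepsPerEpoch)
  set.seed(cfgFT$seed)
  for (step in seq_len(nSteps)) {
    idxB <- sample(nrow(pairs), min(cfgFT$batchSize, nrow(pairs)))
    res <- batchStep(params, model@config, pairs[idxB, , drop = FALSE],
                     keyed, cfgFT, adam, freeze = freeze)
    params <- res$params; adam <- res$adam
  }
  out <- model
  out@params <- params
  out@state$fineTuned <- TRUE
  out@state$referenceIds <- ids
  out
}
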