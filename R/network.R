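# The Siamese pair network: pocket pre-encoding (GCN), initial encodings,
# alternating distance/angle-aware edge-to-edge (DAEE) and distance-aware
# edge-to-node (DEN) attention blocks, attentive super-node readout, the
# pair representation x_i (+) x_j (+) (x_i - x_j), and two independent
# three-layer feedforward heads (regression on delta-pIC50 and a logistic
# ranking head).  Both branches share one parameter set.

#' Network configuration
#'
#' @param m hidden width (must be even: the intermediate edge encoding
#'   lives in dimension m/2)
#' @param L number of message-passing layers (each = one DAEE + one DEN)
#' @param precodeDepth GCN layers applied to the pocket alone
#' @param readoutSteps attentive readout timesteps
#' @param dropout dropout rate on pre-residual branches during training
#' @param leakySlope LeakyReLU negative slope
#' @param seed RNG seed for parameter initialization
#' @return named list of settings
#' @export
pairNetConfig <- function(m = 96L, L = 3L, precodeDepth = 2L,
                          readoutSteps = 2L, dropout = 0.1,
                          leakySlope = 0.01, seed = 1L) {
  stopifnot(m %% 2L == 0L, L >= 1L, precodeDepth >= 0L, readoutSteps >= 1L)
  list(m = as.integer(m), L = as.integer(L),
       precodeDepth = as.integer(precodeDepth),
       readoutSteps = as.integer(readoutSteps),
       dropout = dropout, leakySlope = leakySlope, seed = as.integer(seed),
       lNode = attr(atomFeatureSchema(), "width"),
       lEdge = attr(bondFeatureSchema(), "width"))
}

glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

#' Initialize a PairNet model
#'
#' @param config from \code{\link{pairNetConfig}}
#' @param potential a \linkS4class{PotentialTable} (default: the bundled
#'   table)
#' @return a \linkS4class{PairNet}
#' @export
initPairNet <- function(config = pairNetConfig(),
                        potential = defaultPotential()) {
  m <- config$m; ln <- config$lNode; le <- config$lEdge
  set.seed(config$seed)
  p <- list()
  for (d in seq_len(config$precodeDepth)) {
    p[[paste0("pre", d, ".W")]] <- glorot(ln, ln)
    p[[paste0("pre", d, ".b")]] <- matrix(0, 1, ln)
  }
  p$Winode <- glorot(ln, m);       p$binode <- matrix(0, 1, m)
  p$Wiedge <- glorot(le, m / 2L);  p$biedge <- matrix(0, 1, m / 2L)
  p$Wi <- glorot(m + m / 2L, m);   p$bi <- matrix(0, 1, m)
  for (l in seq_len(config$L)) {
    pre <- function(s) paste0("l", l, ".", s)
    p[[pre("Wq_e")]] <- glorot(m, m); p[[pre("bq_e")]] <- matrix(0, 1, m)
    p[[pre("Wk_e")]] <- glorot(m, m); p[[pre("bk_e")]] <- matrix(0, 1, m)
    p[[pre("Wang")]] <- glorot(6L, m)
    p[[pre("wedge")]] <- glorot(m, 1L)
    p[[pre("We1")]] <- glorot(m, m);  p[[pre("We2")]] <- glorot(m, m)
    p[[pre("eln1.g")]] <- matrix(1, 1, m); p[[pre("eln1.b")]] <- matrix(0, 1, m)
    p[[pre("eln2.g")]] <- matrix(1, 1, m); p[[pre("eln2.b")]] <- matrix(0, 1, m)
    p[[pre("Wq_n")]] <- glorot(m, m); p[[pre("bq_n")]] <- matrix(0, 1, m)
    p[[pre("Wk_n")]] <- glorot(m, m); p[[pre("bk_n")]] <- matrix(0, 1, m)
    p[[pre("wnode")]] <- glorot(m, 1L)
    p[[pre("Wn1")]] <- glorot(m, m);  p[[pre("Wn2")]] <- glorot(m, m)
    p[[pre("nln1.g")]] <- matrix(1, 1, m); p[[pre("nln1.b")]] <- matrix(0, 1, m)
    p[[pre("nln2.g")]] <- matrix(1, 1, m); p[[pre("nln2.b")]] <- matrix(0, 1, m)
  }
  p$Watt <- glorot(2L * m, m); p$batt <- matrix(0, 1, m)
  p$watt <- glorot(m, 1L)
  p$Wctx <- glorot(m, m)
  for (g in c("z", "r", "h")) {
    p[[paste0("gruW", g)]] <- glorot(m, m)
    p[[paste0("gruU", g)]] <- glorot(m, m)
    p[[paste0("grub", g)]] <- matrix(0, 1, m)
  }
  for (head in c("reg", "cls")) {
    p[[paste0(head, "_W1")]] <- glorot(3L * m, m)
    p[[paste0(head, "_b1")]] <- matrix(0, 1, m)
    p[[paste0(head, "_W2")]] <- glorot(m, m)
    p[[paste0(head, "_b2")]] <- matrix(0, 1, m)
    p[[paste0(head, "_W3")]] <- glorot(m, 1L)
    p[[paste0(head, "_b3")]] <- matrix(0, 1, 1L)
  }
  new("PairNet", config = config, params = p, potential = potential)
}

## ---- static graph tensors ------------------------------------------------

#' Precompute the static tensors of a complex graph
#'
#' Gathers everything the forward pass needs that does not depend on the
#' parameters: feature matrices, the pocket GCN adjacency, the edge-pair
#' (KU) index table with angle-domain one-hots, and the potential biases
#' of both attention blocks.
#'
#' @param graph a \linkS4class{ComplexGraph}
#' @param potential a \linkS4class{PotentialTable}
#' @return list of tensors consumed by the forward pass
#' @export
graphTensors <- function(graph, potential) {
  e <- graph@edges; nd <- graph@nodes
  N <- nrow(nd); E <- nrow(e)
  nP <- graph@meta$nPocket
  xyz <- as.matrix(nd[, c("x", "y", "z")])

  # pocket GCN: symmetric-normalized adjacency with self-loops over the
  # pocket covalent subgraph
  A <- diag(nP)
  cov <- e$kind == "covalent" & e$src <= nP & e$dst <= nP
  if (any(cov)) A[cbind(e$src[cov], e$dst[cov])] <- 1
  dinv <- 1 / sqrt(rowSums(A))
  Ahat <- A * outer(dinv, dinv)

  # KU table: for target edge t = (u -> v), neighbor edges f = (k -> u), k != v
  bySrcDst <- split(seq_len(E), e$dst)
  tgt <- integer(); nbr <- integer()
  for (t in seq_len(E)) {
    fs <- bySrcDst[[as.character(e$src[t])]]
    if (is.null(fs)) next
    fs <- fs[e$src[fs] != e$dst[t]]
    if (length(fs)) {
      tgt <- c(tgt, rep.int(t, length(fs)))
      nbr <- c(nbr, fs)
    }
  }
  if (length(tgt)) {
    a <- xyz[e$src[nbr], , drop = FALSE] - xyz[e$src[tgt], , drop = FALSE]
    b <- xyz[e$dst[tgt], , drop = FALSE] - xyz[e$src[tgt], , drop = FALSE]
    na <- sqrt(rowSums(a^2)); nb2 <- sqrt(rowSums(b^2))
    ct <- rowSums(a * b) / pmax(na * nb2, 1e-12)
    theta <- acos(pmin(pmax(ct, -1), 1))
    angOneHot <- angleDivider(theta)
    eeBias <- pairwiseBias(potential, nd$element[e$src[nbr]],
                           nd$element[e$dst[nbr]], e$dist[nbr], e$kind[nbr])
  } else {
    angOneHot <- matrix(0, 0L, 6L); eeBias <- numeric(); theta <- numeric()
  }
  nvBias <- pairwiseBias(potential, nd$element[e$src],
                         nd$element[e$dst], e$dist, e$kind)

  ligIdx <- graph@meta$ligandIdx  # ligand heavy atoms (readout set)
  list(N = N, E = E, nP = nP,
       pocketXYZ = xyz[seq_len(nP), , drop = FALSE],
       X = graph@nodeFeatures, Xe = graph@edgeFeatures,
       Ahat = Ahat, src = e$src, dst = e$dst,
       kind = e$kind,
       eeTgt = tgt, eeNbr = nbr, eeAng = angOneHot, eeBias = eeBias,
       theta = theta, nvBias = nvBias, ligIdx = ligIdx,
       ligandName = graph@meta$ligandName %||% "")
}

## ---- forward pass on a tape ----------------------------------------------

paramNodes <- function(tape, params) {
  lapply(params, function(w) adVar(tape, w))
}

dropMask <- function(dim1, dim2, rate) {
  if (rate <= 0) return(NULL)
  matrix(stats::rbinom(dim1 * dim2, 1L, 1 - rate) / (1 - rate), dim1, dim2)
}

# Res(z) = LayerNorm(z); applied twice per block as printed, with dropout
# on the pre-residual branch during training.
resBlock <- function(tape, h, branch, pv, pre1, pre2, training, rate) {
  if (training && rate > 0) {
    branch <- adMask(tape, branch,
                     dropMask(nrow(branch$val), ncol(branch$val), rate))
  }
  z <- adAdd(tape, h, branch)
  z <- adLayerNorm(tape, z, pv[[paste0(pre1, ".g")]], pv[[paste0(pre1, ".b")]])
  adLayerNorm(tape, z, pv[[paste0(pre2, ".g")]], pv[[paste0(pre2, ".b")]])
}

# Full single-graph encoder.  Returns the graph-level vector (1 x m node)
# and, when record = TRUE, the attention values of the last DEN layer.
forwardGraphAD <- function(tape, pv, gt, cfg, mask = NULL,
                           training = FALSE, record = FALSE) {
  slope <- cfg$leakySlope
  # pocket pre-encoding on raw features, before graph-level message passing
  if (gt$nP > 0 && cfg$precodeDepth > 0) {
    AhatN <- adConst(tape, gt$Ahat)
    Hp <- adConst(tape, gt$X[seq_len(gt$nP), , drop = FALSE])
    for (d in seq_len(cfg$precodeDepth)) {
      Hp <- adRelu(tape, adAddBias(tape,
        adMatmul(tape, AhatN, adMatmul(tape, Hp, pv[[paste0("pre", d, ".W")]])),
        pv[[paste0("pre", d, ".b")]]))
    }
    Xrest <- adConst(tape, gt$X[-seq_len(gt$nP), , drop = FALSE])
    X <- adRbind(tape, Hp, Xrest)
  } else {
    X <- adConst(tape, gt$X)
  }

  # initial hidden representations
  hv <- adRelu(tape, adAddBias(tape, adMatmul(tape, X, pv$Winode), pv$binode))
  XeN <- adConst(tape, gt$Xe)
  xep <- adRelu(tape, adAddBias(tape, adMatmul(tape, XeN, pv$Wiedge), pv$biedge))
  he <- adRelu(tape, adAddBias(tape,
    adMatmul(tape, adConcatCols(tape, adGather(tape, hv, gt$src), xep), pv$Wi),
    pv$bi))

  attn <- NULL
  for (l in seq_len(cfg$L)) {
    pre <- function(s) paste0("l", l, ".", s)
    # --- DAEE: edge-to-edge attention with angle embedding and potential bias
    q <- adAddBias(tape, adMatmul(tape, he, pv[[pre("Wq_e")]]), pv[[pre("bq_e")]])
    k <- adAddBias(tape, adMatmul(tape, he, pv[[pre("Wk_e")]]), pv[[pre("bk_e")]])
    if (length(gt$eeTgt)) {
      qp <- adGather(tape, q, gt$eeTgt)
      kp <- adGather(tape, k, gt$eeNbr)
      ang <- adMatmul(tape, adConst(tape, gt$eeAng), pv[[pre("Wang")]])
      eps <- adMatmul(tape,
        adLeakyRelu(tape, adAdd(tape, adAdd(tape, qp, kp), ang), slope),
        pv[[pre("wedge")]])
      epsP <- adAdd(tape, eps, adConst(tape, matrix(gt$eeBias, ncol = 1L)))
      alphaE <- adSegmentSoftmax(tape, epsP, gt$eeTgt)
      msgE <- adSegmentSum(tape, adMulRows(tape, kp, alphaE), gt$eeTgt, gt$E)
    } else {
      msgE <- adConst(tape, matrix(0, gt$E, cfg$m))
    }
    branch <- adMatmul(tape, adRelu(tape, adMatmul(tape, msgE, pv[[pre("We1")]])),
                       pv[[pre("We2")]])
    he <- resBlock(tape, he, branch, pv, pre("eln1"), pre("eln2"),
                   training, cfg$dropout)

    # --- DEN: edge-to-node attention using same-layer edge states
    qn <- adAddBias(tape, adMatmul(tape, hv, pv[[pre("Wq_n")]]), pv[[pre("bq_n")]])
    kn <- adAddBias(tape, adMatmul(tape, hv, pv[[pre("Wk_n")]]), pv[[pre("bk_n")]])
    qv <- adGather(tape, qn, gt$dst)
    ku <- adGather(tape, kn, gt$src)
    epsN <- adMatmul(tape, adLeakyRelu(tape, adAdd(tape, qv, ku), slope),
                     pv[[pre("wnode")]])
    epsNP <- adAdd(tape, epsN, adConst(tape, matrix(gt$nvBias, ncol = 1L)))
    alphaN <- adSegmentSoftmax(tape, epsNP, gt$dst)
    msgN <- adSegmentSum(tape, adMulRows(tape, he, alphaN), gt$dst, gt$N)
    branchN <- adMatmul(tape, adRelu(tape, adMatmul(tape, msgN, pv[[pre("Wn1")]])),
                        pv[[pre("Wn2")]])
    hv <- resBlock(tape, hv, branchN, pv, pre("nln1"), pre("nln2"),
                   training, cfg$dropout)
    if (record && l == cfg$L) {
      attn <- data.frame(src = gt$src, dst = gt$dst, kind = gt$kind,
                         alpha = as.numeric(alphaN$val))
    }
  }

  # --- attentive super-node readout over the ligand atoms
  if (!length(gt$ligIdx)) stop("readout requires at least one ligand node")
  Hl <- adGather(tape, hv, gt$ligIdx)
  n <- length(gt$ligIdx)
  if (!is.null(mask)) {
    Hl <- adMask(tape, Hl, matrix(rep(mask, cfg$m), n, cfg$m))
  }
  s <- adMeanRows(tape, Hl)
  ones <- adConst(tape, matrix(1, n, 1L))
  grp <- rep(1L, n)
  for (t in seq_len(cfg$readoutSteps)) {
    Srep <- adMatmul(tape, ones, s)
    sc <- adMatmul(tape,
      adLeakyRelu(tape, adAddBias(tape,
        adMatmul(tape, adConcatCols(tape, Srep, Hl), pv$Watt), pv$batt), slope),
      pv$watt)
    a <- adSegmentSoftmax(tape, sc, grp)
    ctx <- adSegmentSum(tape, adMulRows(tape,
      adMatmul(tape, Hl, pv$Wctx), a), grp, 1L)
    z <- adSigmoid(tape, adAddBias(tape, adAdd(tape,
      adMatmul(tape, ctx, pv$gruWz), adMatmul(tape, s, pv$gruUz)), pv$grubz))
    r <- adSigmoid(tape, adAddBias(tape, adAdd(tape,
      adMatmul(tape, ctx, pv$gruWr), adMatmul(tape, s, pv$gruUr)), pv$grubr))
    htil <- adTanh(tape, adAddBias(tape, adAdd(tape,
      adMatmul(tape, ctx, pv$gruWh),
      adMatmul(tape, adMul(tape, r, s), pv$gruUh)), pv$grubh))
    oneRow <- adConst(tape, matrix(1, 1L, cfg$m))
    s <- adAdd(tape, adMul(tape, adSub(tape, oneRow, z), s),
               adMul(tape, z, htil))
  }
  list(x = s, attn = attn)
}

# pair representation and the two heads
predictHeadsAD <- function(tape, pv, xi, xj) {
  xt <- adConcatCols(tape, adConcatCols(tape, xi, xj), adSub(tape, xi, xj))
  head <- function(prefix, squash) {
    h <- adRelu(tape, adAddBias(tape,
      adMatmul(tape, xt, pv[[paste0(prefix, "_W1")]]), pv[[paste0(prefix, "_b1")]]))
    h <- adRelu(tape, adAddBias(tape,
      adMatmul(tape, h, pv[[paste0(prefix, "_W2")]]), pv[[paste0(prefix, "_b2")]]))
    out <- adAddBias(tape,
      adMatmul(tape, h, pv[[paste0(prefix, "_W3")]]), pv[[paste0(prefix, "_b3")]])
    if (squash) adSigmoid(tape, out) else out
  }
  list(xt = xt, yhat = head("reg", FALSE), phat = head("cls", TRUE))
}

forwardPairAD <- function(tape, pv, gtI, gtJ, cfg, training = FALSE,
                          record = FALSE, maskI = NULL, maskJ = NULL) {
  fi <- forwardGraphAD(tape, pv, gtI, cfg, mask = maskI,
                       training = training, record = record)
  fj <- forwardGraphAD(tape, pv, gtJ, cfg, mask = maskJ,
                       training = training, record = record)
  out <- predictHeadsAD(tape, pv, fi$x, fj$x)
  out$attnI <- fi$attn; out$attnJ <- fj$attn
  out$xi <- fi$x; out$xj <- fj$x
  out
}

## ---- user-facing inference ----------------------------------------------

checkSharedPocket <- function(gtI, gtJ) {
  same <- gtI$nP == gtJ$nP &&
    isTRUE(all.equal(gtI$pocketXYZ, gtJ$pocketXYZ, tolerance = 1e-8)) &&
    isTRUE(all.equal(gtI$X[seq_len(gtI$nP), , drop = FALSE],
                     gtJ$X[seq_len(gtJ$nP), , drop = FALSE],
                     tolerance = 1e-8))
  if (!same) {
    warning("the two complexes do not share an identical pocket")
  }
  invisible(same)
}

#' Pair representation of two graph-level vectors
#' @param xi,xj numeric vectors of equal length m
#' @return numeric vector of length 3m: xi, xj, xi - xj
#' @export
pairRepresentation <- function(xi, xj) {
  if (length(xi) != length(xj)) stop("dimension mismatch")
  c(xi, xj, xi - xj)
}

#' Run the Siamese forward pass on a pair of complexes
#'
#' @param model a \linkS4class{PairNet}
#' @param graphI,graphJ \linkS4class{ComplexGraph} objects (or precomputed
#'   tensor lists from \code{\link{graphTensors}}) sharing the pocket
#' @param record record the attention of the last edge-to-node layer
#' @return list with \code{yhat} (predicted delta-pIC50, ligand i minus
#'   ligand j), \code{phat} (probability that i is more active), graph
#'   vectors \code{xi}, \code{xj}, and attention tables when recorded
#' @export
forwardPair <- function(model, graphI, graphJ, record = FALSE) {
  gtI <- if (is(graphI, "ComplexGraph")) {
    graphTensors(graphI, model@potential)
  } else graphI
  gtJ <- if (is(graphJ, "ComplexGraph")) {
    graphTensors(graphJ, model@potential)
  } else graphJ
  checkSharedPocket(gtI, gtJ)
  tape <- newTape()
  pv <- paramNodes(tape, model@params)
  out <- forwardPairAD(tape, pv, gtI, gtJ, model@config, record = record)
  list(yhat = as.numeric(out$yhat$val), phat = as.numeric(out$phat$val),
       xi = as.numeric(out$xi$val), xj = as.numeric(out$xj$val),
       attnI = out$attnI, attnJ = out$attnJ)
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the configuration, the parameters and the
#' potential table.
#' @param model a PairNet
#' @param file path
#' @export
saveCheckpoint <- function(model, file) {
  saveRDS(list(config = model@config, params = model@params,
               potential = model@potential, state = model@state), file)
  invisible(file)
}

#' @rdname saveCheckpoint
#' @return \code{loadCheckpoint} returns the restored \linkS4class{PairNet}
#' @export
loadCheckpoint <- function(file) {
  obj <- readRDS(file)
  new("PairNet", config = obj$config, params = obj$params,
      potential = obj$potential, state = obj$state %||% list())
}
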