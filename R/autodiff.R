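# Minimal reverse-mode automatic differentiation on dense matrices.
#
# The network in this package is small (graphs of tens to hundreds of nodes,
# hidden widths of order 10-100), so a tape of matrix operations evaluated in
# plain R is fast enough for desk-scale training while keeping every gradient
# exact.  All values are numeric matrices; vectors are carried as n x 1 or
# 1 x n matrices.  Gradients are verified against central finite differences
# in the test suite.

newTape <- function() {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 256L)
  tape$n <- 0L
  tape
}

adNode <- function(tape, val, parents = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- nd
  nd
}

#' @noRd
adConst <- function(tape, x) adNode(tape, asMat(x))

# leaf whose gradient is collected (model parameter)
adVar <- function(tape, x) adNode(tape, asMat(x))

asMat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

accGrad <- function(nd, g) {
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
  invisible(NULL)
}

# Run the backward sweep from scalar node `out`.
adBackward <- function(tape, out) {
  stopifnot(length(out$val) == 1L)
  out$grad <- matrix(1, 1L, 1L)
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$backfn) && !is.null(nd$grad)) nd$backfn(nd)
  }
  invisible(NULL)
}

## ---- primitive operations ------------------------------------------------

adMatmul <- function(tape, a, b) {
  adNode(tape, a$val %*% b$val, list(a, b), function(nd) {
    accGrad(a, nd$grad %*% t(b$val))
    accGrad(b, t(a$val) %*% nd$grad)
  })
}

adAdd <- function(tape, a, b) {
  stopifnot(all(dim(a$val) == dim(b$val)))
  adNode(tape, a$val + b$val, list(a, b), function(nd) {
    accGrad(a, nd$grad)
    accGrad(b, nd$grad)
  })
}

# add a 1 x k bias row to every row of an n x k matrix
adAddBias <- function(tape, a, b) {
  stopifnot(ncol(a$val) == ncol(b$val), nrow(b$val) == 1L)
  adNode(tape, sweep(a$val, 2L, as.numeric(b$val), "+"), list(a, b),
         function(nd) {
           accGrad(a, nd$grad)
           accGrad(b, matrix(colSums(nd$grad), 1L))
         })
}

adSub <- function(tape, a, b) {
  stopifnot(all(dim(a$val) == dim(b$val)))
  adNode(tape, a$val - b$val, list(a, b), function(nd) {
    accGrad(a, nd$grad)
    accGrad(b, -nd$grad)
  })
}

adMul <- function(tape, a, b) {
  stopifnot(all(dim(a$val) == dim(b$val)))
  adNode(tape, a$val * b$val, list(a, b), function(nd) {
    accGrad(a, nd$grad * b$val)
    accGrad(b, nd$grad * a$val)
  })
}

adScale <- function(tape, a, s) {
  adNode(tape, a$val * s, list(a), function(nd) accGrad(a, nd$grad * s))
}

adRelu <- function(tape, a) {
  adNode(tape, pmax(a$val, 0), list(a), function(nd) {
    accGrad(a, nd$grad * (a$val > 0))
  })
}

adLeakyRelu <- function(tape, a, slope = 0.01) {
  pos <- a$val > 0
  fac <- pos + slope * !pos
  adNode(tape, a$val * fac, list(a), function(nd) {
    accGrad(a, nd$grad * fac)
  })
}

adSigmoid <- function(tape, a) {
  s <- 1 / (1 + exp(-a$val))
  adNode(tape, s, list(a), function(nd) accGrad(a, nd$grad * s * (1 - s)))
}

adTanh <- function(tape, a) {
  s <- tanh(a$val)
  adNode(tape, s, list(a), function(nd) accGrad(a, nd$grad * (1 - s^2)))
}

adConcatCols <- function(tape, a, b) {
  stopifnot(nrow(a$val) == nrow(b$val))
  ka <- ncol(a$val)
  adNode(tape, cbind(a$val, b$val), list(a, b), function(nd) {
    accGrad(a, nd$grad[, seq_len(ka), drop = FALSE])
    accGrad(b, nd$grad[, -seq_len(ka), drop = FALSE])
  })
}

adRbind <- function(tape, a, b) {
  stopifnot(ncol(a$val) == ncol(b$val))
  na <- nrow(a$val)
  adNode(tape, rbind(a$val, b$val), list(a, b), function(nd) {
    accGrad(a, nd$grad[seq_len(na), , drop = FALSE])
    accGrad(b, nd$grad[-seq_len(na), , drop = FALSE])
  })
}

# X[idx, ] with scatter-add backward
adGather <- function(tape, a, idx) {
  adNode(tape, a$val[idx, , drop = FALSE], list(a), function(nd) {
    g <- matrix(0, nrow(a$val), ncol(a$val))
    gs <- rowsum(nd$grad, group = idx)
    g[as.integer(rownames(gs)), ] <- gs
    accGrad(a, g)
  })
}

# sum rows of X within groups 1..ngroups; empty groups give zero rows
adSegmentSum <- function(tape, a, group, ngroups) {
  val <- matrix(0, ngroups, ncol(a$val))
  gs <- rowsum(a$val, group = group)
  val[as.integer(rownames(gs)), ] <- gs
  adNode(tape, val, list(a), function(nd) {
    accGrad(a, nd$grad[group, , drop = FALSE])
  })
}

# multiply row i of X by v[i] (v an n x 1 node)
adMulRows <- function(tape, a, v) {
  stopifnot(nrow(a$val) == nrow(v$val), ncol(v$val) == 1L)
  w <- as.numeric(v$val)
  adNode(tape, a$val * w, list(a, v), function(nd) {
    accGrad(a, nd$grad * w)
    accGrad(v, matrix(rowSums(nd$grad * a$val), ncol = 1L))
  })
}

# softmax of an n x 1 score vector within integer groups
adSegmentSoftmax <- function(tape, a, group) {
  stopifnot(ncol(a$val) == 1L)
  x <- as.numeric(a$val)
  # order-of-first-appearance group index so rowsum() can do the segmented
  # reductions in C; the global max shift is numerically safe for the
  # moderate logit ranges attention produces
  u <- unique(group)
  idx <- match(group, u)
  ex <- exp(x - max(x))
  ssum <- rowsum(ex, idx, reorder = FALSE)
  p <- ex / ssum[idx]
  adNode(tape, matrix(p, ncol = 1L), list(a), function(nd) {
    g <- as.numeric(nd$grad)
    dot <- rowsum(g * p, idx, reorder = FALSE)
    accGrad(a, matrix(p * (g - dot[idx]), ncol = 1L))
  })
}

# row-wise layer normalization with learned 1 x k gain and bias
adLayerNorm <- function(tape, a, gamma, beta, eps = 1e-5) {
  x <- a$val
  k <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  val <- sweep(xhat * rep(as.numeric(gamma$val), each = nrow(x)), 2L,
               as.numeric(beta$val), "+")
  adNode(tape, val, list(a, gamma, beta), function(nd) {
    g <- nd$grad
    accGrad(gamma, matrix(colSums(g * xhat), 1L))
    accGrad(beta, matrix(colSums(g), 1L))
    dxh <- g * rep(as.numeric(gamma$val), each = nrow(x))
    t1 <- rowSums(dxh)
    t2 <- rowSums(dxh * xhat)
    accGrad(a, inv * (dxh - t1 / k - xhat * t2 / k))
  })
}

adMean <- function(tape, a) {
  n <- length(a$val)
  adNode(tape, matrix(mean(a$val), 1L, 1L), list(a), function(nd) {
    accGrad(a, matrix(as.numeric(nd$grad) / n, nrow(a$val), ncol(a$val)))
  })
}

adSum <- function(tape, a) {
  adNode(tape, matrix(sum(a$val), 1L, 1L), list(a), function(nd) {
    accGrad(a, matrix(as.numeric(nd$grad), nrow(a$val), ncol(a$val)))
  })
}

adMeanRows <- function(tape, a) {
  n <- nrow(a$val)
  adNode(tape, matrix(colMeans(a$val), 1L), list(a), function(nd) {
    accGrad(a, matrix(rep(as.numeric(nd$grad) / n, each = n), n))
  })
}

adLog <- function(tape, a) {
  adNode(tape, log(a$val), list(a), function(nd) accGrad(a, nd$grad / a$val))
}

# elementwise multiply by a constant mask (dropout; mask built by caller)
adMask <- function(tape, a, mask) {
  adNode(tape, a$val * mask, list(a), function(nd) accGrad(a, nd$grad * mask))
}
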