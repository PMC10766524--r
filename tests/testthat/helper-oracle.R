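# Straight-line re-implementation of the printed update equations,
# independent of the package's vectorized tape engine.  Works on any
# small complex graph: neighborhood sets, angles, biases, attention and
# residual blocks are all recomputed here with explicit per-edge loops.
# The potential table is assumed to cover no real atom type, so every
# virtual edge receives the fallback bias (0.8) and covalent edges 1.

manualGraphForward <- function(params, cfg, graph, mask = NULL) {
  nd <- graph@nodes; ed <- graph@edges
  N <- nrow(nd); E <- nrow(ed)
  m <- cfg$m
  xyz <- as.matrix(nd[, c("x", "y", "z")])
  lrelu <- function(z) ifelse(z > 0, z, cfg$leakySlope * z)
  LN <- function(z, g, b) {
    mu <- mean(z); v <- mean((z - mu)^2)
    (z - mu) / sqrt(v + 1e-5) * as.numeric(g) + as.numeric(b)
  }
  rowv <- function(x) as.numeric(x)

  X <- graph@nodeFeatures
  # pocket pre-encoding: GCN with self-loops on the pocket covalent graph
  pIdx <- which(nd$origin == "pocket" & !nd$virtual)
  if (cfg$precodeDepth > 0 && length(pIdx)) {
    A <- diag(length(pIdx))
    for (r in seq_len(E)) {
      if (ed$kind[r] == "covalent" && ed$src[r] %in% pIdx &&
          ed$dst[r] %in% pIdx) {
        A[match(ed$src[r], pIdx), match(ed$dst[r], pIdx)] <- 1
      }
    }
    dinv <- 1 / sqrt(rowSums(A))
    Ah <- A * outer(dinv, dinv)
    H <- X[pIdx, , drop = FALSE]
    for (d in seq_len(cfg$precodeDepth)) {
      H <- pmax(Ah %*% H %*% params[[paste0("pre", d, ".W")]] +
                  matrix(params[[paste0("pre", d, ".b")]], nrow(H),
                         ncol(X), byrow = TRUE), 0)
    }
    X[pIdx, ] <- H
  }

  # initial hidden representations
  h <- t(vapply(seq_len(N), function(v) {
    pmax(rowv(X[v, ] %*% params$Winode) + rowv(params$binode), 0)
  }, numeric(m)))
  he <- t(vapply(seq_len(E), function(e) {
    xp <- pmax(rowv(graph@edgeFeatures[e, ] %*% params$Wiedge) +
                 rowv(params$biedge), 0)
    pmax(rowv(c(h[ed$src[e], ], xp) %*% params$Wi) + rowv(params$bi), 0)
  }, numeric(m)))

  bias <- ifelse(ed$kind == "covalent", 1, 0.8)
  attn <- rep(NA_real_, E)
  for (l in seq_len(cfg$L)) {
    pre <- function(s) paste0("l", l, ".", s)
    q <- he %*% params[[pre("Wq_e")]] +
      matrix(params[[pre("bq_e")]], E, m, byrow = TRUE)
    k <- he %*% params[[pre("Wk_e")]] +
      matrix(params[[pre("bk_e")]], E, m, byrow = TRUE)
    heNew <- he
    for (e in seq_len(E)) {
      KU <- which(ed$dst == ed$src[e] & ed$src != ed$dst[e])
      msg <- numeric(m)
      if (length(KU)) {
        eps <- vapply(KU, function(f) {
          a <- xyz[ed$src[f], ] - xyz[ed$src[e], ]
          b <- xyz[ed$dst[e], ] - xyz[ed$src[e], ]
          ct <- sum(a * b) / max(sqrt(sum(a^2)) * sqrt(sum(b^2)), 1e-12)
          theta <- acos(min(max(ct, -1), 1))
          dom <- min(floor(theta / (pi / 6)), 5) + 1
          sum(params[[pre("wedge")]] *
                lrelu(q[e, ] + k[f, ] + params[[pre("Wang")]][dom, ]))
        }, 1.0)
        epsP <- eps + bias[KU]
        al <- exp(epsP - max(epsP)); al <- al / sum(al)
        for (t in seq_along(KU)) msg <- msg + al[t] * k[KU[t], ]
      }
      branch <- rowv(pmax(rowv(msg %*% params[[pre("We1")]]), 0) %*%
                       params[[pre("We2")]])
      z <- LN(he[e, ] + branch, params[[pre("eln1.g")]], params[[pre("eln1.b")]])
      heNew[e, ] <- LN(z, params[[pre("eln2.g")]], params[[pre("eln2.b")]])
    }
    he <- heNew

    qn <- h %*% params[[pre("Wq_n")]] +
      matrix(params[[pre("bq_n")]], N, m, byrow = TRUE)
    kn <- h %*% params[[pre("Wk_n")]] +
      matrix(params[[pre("bk_n")]], N, m, byrow = TRUE)
    hNew <- h
    for (v in seq_len(N)) {
      UV <- which(ed$dst == v)
      msg <- numeric(m)
      if (length(UV)) {
        eps <- vapply(UV, function(e) {
          sum(params[[pre("wnode")]] * lrelu(qn[v, ] + kn[ed$src[e], ]))
        }, 1.0)
        epsP <- eps + bias[UV]
        al <- exp(epsP - max(epsP)); al <- al / sum(al)
        if (l == cfg$L) attn[UV] <- al
        for (t in seq_along(UV)) msg <- msg + al[t] * he[UV[t], ]
      }
      branch <- rowv(pmax(rowv(msg %*% params[[pre("Wn1")]]), 0) %*%
                       params[[pre("Wn2")]])
      z <- LN(h[v, ] + branch, params[[pre("nln1.g")]], params[[pre("nln1.b")]])
      hNew[v, ] <- LN(z, params[[pre("nln2.g")]], params[[pre("nln2.b")]])
    }
    h <- hNew
  }

  # attentive super-node readout over ligand heavy atoms
  ligIdx <- which(nd$origin == "ligand" & !nd$virtual)
  Hl <- h[ligIdx, , drop = FALSE]
  if (!is.null(mask)) Hl <- Hl * mask
  s <- colMeans(Hl)
  for (t in seq_len(cfg$readoutSteps)) {
    sc <- vapply(seq_len(nrow(Hl)), function(i) {
      sum(params$watt * lrelu(rowv(c(s, Hl[i, ]) %*% params$Watt) +
                                rowv(params$batt)))
    }, 1.0)
    al <- exp(sc - max(sc)); al <- al / sum(al)
    ctx <- numeric(cfg$m)
    for (i in seq_len(nrow(Hl))) {
      ctx <- ctx + al[i] * rowv(Hl[i, ] %*% params$Wctx)
    }
    sig <- function(z) 1 / (1 + exp(-z))
    z <- sig(rowv(ctx %*% params$gruWz) + rowv(s %*% params$gruUz) +
               rowv(params$grubz))
    r <- sig(rowv(ctx %*% params$gruWr) + rowv(s %*% params$gruUr) +
               rowv(params$grubr))
    htil <- tanh(rowv(ctx %*% params$gruWh) + rowv((r * s) %*% params$gruUh) +
                   rowv(params$grubh))
    s <- (1 - z) * s + z * htil
  }
  list(x = s, attn = attn)
}

manualPairForward <- function(model, graphI, graphJ, maskI = NULL) {
  params <- model@params; cfg <- model@config
  fi <- manualGraphForward(params, cfg, graphI, maskI)
  fj <- manualGraphForward(params, cfg, graphJ)
  xt <- c(fi$x, fj$x, fi$x - fj$x)
  head <- function(prefix) {
    h <- pmax(as.numeric(xt %*% params[[paste0(prefix, "_W1")]]) +
                as.numeric(params[[paste0(prefix, "_b1")]]), 0)
    h <- pmax(as.numeric(h %*% params[[paste0(prefix, "_W2")]]) +
                as.numeric(params[[paste0(prefix, "_b2")]]), 0)
    as.numeric(h %*% params[[paste0(prefix, "_W3")]]) +
      as.numeric(params[[paste0(prefix, "_b3")]])
  }
  yhat <- head("reg")
  phat <- 1 / (1 + exp(-head("cls")))
  list(yhat = yhat, phat = phat, xi = fi$x, xj = fj$x,
       attnI = fi$attn, attnJ = fj$attn)
}
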