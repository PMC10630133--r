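# Internal neural-network machinery for the conditional VAE: parameter
# initialization, forward pass, analytic gradients, and Adam updates.
# Parameters live in a flat named list of matrices/vectors; condition
# embedding tables are entries "emb.<covariate>" with condition rownames.

.LN_EPS <- 1e-5
.LV_CLAMP <- 12          # |log-variance| bound for numerical safety

.hiddenWidth <- function(cfg, G) {
  if (identical(cfg$hiddenWidth, "auto")) max(4L, round(sqrt(G))) else as.integer(cfg$hiddenWidth)
}

# covLevels: named list, condition names per covariate (declaration order).
.initParams <- function(cfg, G, covLevels) {
  H <- .hiddenWidth(cfg, G)
  D <- cfg$latentDim
  Edims <- rep_len(cfg$embeddingDim, length(covLevels))
  names(Edims) <- names(covLevels)
  Etot <- sum(Edims)
  he <- function(fi, fo) matrix(stats::rnorm(fi * fo, 0, sqrt(2 / fi)), fi, fo)
  xav <- function(fi, fo) matrix(stats::rnorm(fi * fo, 0, sqrt(1 / fi)), fi, fo)
  p <- list()
  din <- G + Etot
  for (i in seq_len(cfg$encoderDepth)) {
    p[[paste0("enc.W", i)]] <- he(din, H)
    p[[paste0("enc.b", i)]] <- numeric(H)
    if (cfg$norm == "layer") {
      p[[paste0("enc.g", i)]] <- rep(1, H)
      p[[paste0("enc.bt", i)]] <- numeric(H)
    }
    din <- H
  }
  p$Wmu <- xav(H, D); p$bmu <- numeric(D)
  p$Wlv <- xav(H, D); p$blv <- numeric(D)
  din <- D + Etot
  for (i in seq_len(cfg$decoderDepth)) {
    p[[paste0("dec.W", i)]] <- he(din, H)
    p[[paste0("dec.b", i)]] <- numeric(H)
    if (cfg$norm == "layer") {
      p[[paste0("dec.g", i)]] <- rep(1, H)
      p[[paste0("dec.bt", i)]] <- numeric(H)
    }
    din <- H
  }
  p$Wout <- xav(H, G); p$cout <- numeric(G)
  if (cfg$likelihood == "nb") p$ltheta <- numeric(G)
  for (nm in names(covLevels)) {
    E <- Edims[[nm]]
    L <- length(covLevels[[nm]])
    emb <- matrix(stats::rnorm(L * E, 0, 1 / sqrt(E)), L, E)
    rownames(emb) <- covLevels[[nm]]
    p[[paste0("emb.", nm)]] <- emb
  }
  attr(p, "embeddingDims") <- Edims
  attr(p, "hiddenWidth") <- H
  p
}

# Concatenate embedding rows for each covariate, declaration order.
.embBlock <- function(params, covKeys, condIdx) {
  blocks <- lapply(covKeys, function(key)
    params[[paste0("emb.", key)]][condIdx[[key]], , drop = FALSE])
  do.call(cbind, blocks)
}

# One MLP stack (encoder or decoder trunk). Returns output and caches.
.mlpForward <- function(params, prefix, depth, norm, X) {
  caches <- vector("list", depth)
  H <- X
  for (i in seq_len(depth)) {
    W <- params[[paste0(prefix, ".W", i)]]
    b <- params[[paste0(prefix, ".b", i)]]
    A <- sweep(H %*% W, 2L, b, "+")
    if (norm == "layer") {
      g <- params[[paste0(prefix, ".g", i)]]
      bt <- params[[paste0(prefix, ".bt", i)]]
      m <- rowMeans(A)
      C <- A - m
      s <- sqrt(rowMeans(C^2) + .LN_EPS)
      Nh <- C / s
      Y <- sweep(sweep(Nh, 2L, g, "*"), 2L, bt, "+")
    } else {
      Nh <- NULL; s <- NULL
      Y <- A
    }
    Hn <- pmax(Y, 0)
    caches[[i]] <- list(Hin = H, Nh = Nh, s = s, mask = Y > 0)
    H <- Hn
  }
  list(H = H, caches = caches)
}

# Backward through one MLP stack. dH: gradient at the stack output.
# Accumulates parameter grads into `grads` (an environment-like list) and
# returns list(grads, dX).
.mlpBackward <- function(params, prefix, depth, norm, caches, dH, grads) {
  for (i in rev(seq_len(depth))) {
    cc <- caches[[i]]
    dY <- dH * cc$mask
    if (norm == "layer") {
      g <- params[[paste0(prefix, ".g", i)]]
      grads[[paste0(prefix, ".g", i)]] <- colSums(dY * cc$Nh)
      grads[[paste0(prefix, ".bt", i)]] <- colSums(dY)
      dNh <- sweep(dY, 2L, g, "*")
      dA <- (dNh - rowMeans(dNh) - cc$Nh * rowMeans(dNh * cc$Nh)) / cc$s
    } else {
      dA <- dY
    }
    W <- params[[paste0(prefix, ".W", i)]]
    grads[[paste0(prefix, ".W", i)]] <- crossprod(cc$Hin, dA)
    grads[[paste0(prefix, ".b", i)]] <- colSums(dA)
    dH <- dA %*% t(W)
  }
  list(grads = grads, dX = dH)
}

# Full forward pass. eps = NULL means inference mode (z = mu).
.forwardPass <- function(params, cfg, Xlog, condIdx, lib, eps = NULL) {
  covKeys <- cfg$covariateKeys
  S <- .embBlock(params, covKeys, condIdx)
  Xin <- cbind(Xlog, S)
  enc <- .mlpForward(params, "enc", cfg$encoderDepth, cfg$norm, Xin)
  mu <- sweep(enc$H %*% params$Wmu, 2L, params$bmu, "+")
  lvraw <- sweep(enc$H %*% params$Wlv, 2L, params$blv, "+")
  lv <- pmin(pmax(lvraw, -.LV_CLAMP), .LV_CLAMP)
  z <- if (is.null(eps)) mu else mu + exp(0.5 * lv) * eps
  Zin <- cbind(z, S)
  dec <- .mlpForward(params, "dec", cfg$decoderDepth, cfg$norm, Zin)
  O <- sweep(dec$H %*% params$Wout, 2L, params$cout, "+")
  P <- .rowSoftmax(O)
  rate <- P * lib                     # lib recycles down columns (per cell)
  list(S = S, Xin = Xin, enc = enc, mu = mu, lv = lv, lvMask = abs(lvraw) < .LV_CLAMP,
       z = z, Zin = Zin, dec = dec, P = P, rate = rate,
       theta = if (cfg$likelihood == "nb") exp(params$ltheta) else NULL)
}

# Minkowski distance of latent rows to assigned prototypes, plus gradient.
# Z: n x D; Pm: n x D matrix of each row's prototype. Returns list(d, grad).
.minkowskiRows <- function(Z, Pm, ord) {
  Dif <- Z - Pm
  Ab <- abs(Dif)
  d <- rowSums(Ab^ord)^(1 / ord)
  pos <- d > 0
  grad <- matrix(0, nrow(Z), ncol(Z))
  if (any(pos)) {
    sc <- d[pos]^(1 - ord)
    grad[pos, ] <- sc * (Ab[pos, , drop = FALSE]^(ord - 1) *
                           sign(Dif[pos, , drop = FALSE]))
  }
  list(d = d, grad = grad)
}

# Prototype loss on a batch: mean over batch cells of summed per-level
# distances (unlabeled cells contribute 0). protos: named list per level of
# labeled prototype matrices; labels: named list per level of batch labels.
# Evaluated at the latent means; gradient returned w.r.t. them.
.protoLossGrad <- function(Mu, labels, protos, ord, unlabeled) {
  n <- nrow(Mu)
  total <- 0
  grad <- matrix(0, n, ncol(Mu))
  for (lv in names(protos)) {
    Pm <- protos[[lv]]
    if (is.null(Pm) || !nrow(Pm)) next
    lab <- labels[[lv]]
    use <- which(lab != unlabeled)
    if (!length(use)) next
    miss <- setdiff(unique(lab[use]), rownames(Pm))
    if (length(miss))
      .stopf("labeled cell(s) with no prototype at level '%s': %s",
             lv, paste(miss, collapse = ", "))
    mk <- .minkowskiRows(Mu[use, , drop = FALSE],
                         Pm[lab[use], , drop = FALSE], ord)
    total <- total + sum(mk$d)
    grad[use, ] <- grad[use, ] + mk$grad
  }
  list(loss = total / n, grad = grad / n)
}

# Loss and analytic gradients for one minibatch.
# X raw counts, Xlog encoder input, both n x G; eps n x D or NULL.
.lossGrads <- function(params, cfg, X, Xlog, lib, condIdx, eps, klWeight,
                       protos = NULL, labels = NULL, eta = 0) {
  n <- nrow(X)
  fw <- .forwardPass(params, cfg, Xlog, condIdx, lib, eps)
  grads <- list()
  if (cfg$likelihood == "nb") {
    Th <- matrix(fw$theta, n, ncol(X), byrow = TRUE)
    Mu <- fw$rate
    recon <- lgamma(X + Th) - lgamma(Th) - lgamma(X + 1) +
      Th * (log(Th) - log(Th + Mu))
    pos <- X > 0
    recon[pos] <- recon[pos] + X[pos] * (log(Mu[pos]) - log(Th[pos] + Mu[pos]))
    reconPC <- rowSums(-recon)
    dRate <- ((Th + X) / (Th + Mu) - ifelse(pos, X / Mu, 0)) / n
    dTh <- -(digamma(X + Th) - digamma(Th) + log(Th) + 1 -
               log(Th + Mu) - (Th + X) / (Th + Mu)) / n
    grads$ltheta <- colSums(dTh) * fw$theta
  } else {
    Mu <- fw$rate
    pos <- X > 0
    reconPC <- rowSums(Mu + lgamma(X + 1) - ifelse(pos, X * log(Mu), 0))
    dRate <- (1 - ifelse(pos, X / Mu, 0)) / n
  }
  klPC <- 0.5 * rowSums(fw$mu^2 + exp(fw$lv) - 1 - fw$lv)

  # softmax + library-size chain
  dP <- dRate * lib
  dO <- fw$P * (dP - rowSums(dP * fw$P))
  grads$Wout <- crossprod(fw$dec$H, dO)
  grads$cout <- colSums(dO)
  bk <- .mlpBackward(params, "dec", cfg$decoderDepth, cfg$norm,
                     fw$dec$caches, dO %*% t(params$Wout), grads)
  grads <- bk$grads
  D <- cfg$latentDim
  dZin <- bk$dX
  dz <- dZin[, seq_len(D), drop = FALSE]
  dSdec <- dZin[, -seq_len(D), drop = FALSE]

  protoTerm <- 0
  dmuProto <- 0
  if (eta > 0 && !is.null(protos)) {
    pl <- .protoLossGrad(fw$mu, labels, protos, cfg$minkowskiP, cfg$unlabeled)
    protoTerm <- pl$loss
    dmuProto <- eta * pl$grad
  }
  dmu <- dz + klWeight * fw$mu / n + dmuProto
  dlvKL <- klWeight * 0.5 * (exp(fw$lv) - 1) / n
  dlv <- dlvKL + if (is.null(eps)) 0 else dz * (0.5 * exp(0.5 * fw$lv) * eps)
  dlv <- dlv * fw$lvMask

  grads$Wmu <- crossprod(fw$enc$H, dmu)
  grads$bmu <- colSums(dmu)
  grads$Wlv <- crossprod(fw$enc$H, dlv)
  grads$blv <- colSums(dlv)
  dEncH <- dmu %*% t(params$Wmu) + dlv %*% t(params$Wlv)
  bk2 <- .mlpBackward(params, "enc", cfg$encoderDepth, cfg$norm,
                      fw$enc$caches, dEncH, grads)
  grads <- bk2$grads
  G <- ncol(Xlog)
  dSenc <- bk2$dX[, -seq_len(G), drop = FALSE]

  # scatter embedding gradients back to their condition rows
  dS <- dSenc + dSdec
  off <- 0L
  for (key in cfg$covariateKeys) {
    nm <- paste0("emb.", key)
    E <- ncol(params[[nm]])
    block <- dS[, off + seq_len(E), drop = FALSE]
    off <- off + E
    gm <- matrix(0, nrow(params[[nm]]), E, dimnames = dimnames(params[[nm]]))
    agg <- rowsum(block, group = condIdx[[key]])
    gm[as.integer(rownames(agg)), ] <- agg
    grads[[nm]] <- gm
  }

  recon <- mean(reconPC)
  kl <- mean(klPC)
  list(recon = recon, kl = kl, proto = protoTerm,
       total = recon + klWeight * kl + eta * protoTerm,
       grads = grads, mu = fw$mu)
}

.adamInit <- function(params) {
  zero <- lapply(params, function(p) p * 0)
  list(m = zero, v = zero, t = 0L)
}

# One Adam step. frozenParams: names skipped entirely; frozenEmbRows: named
# list covariate -> integer rows whose gradient is zeroed (their Adam state
# starts and stays at zero, so the rows remain bitwise unchanged).
.adamStep <- function(params, grads, st, lr, frozenParams = character(),
                      frozenEmbRows = list(), b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - b1^st$t
  c2 <- 1 - b2^st$t
  for (nm in names(grads)) {
    if (nm %in% frozenParams) next
    g <- grads[[nm]]
    if (startsWith(nm, "emb.")) {
      rows <- frozenEmbRows[[sub("^emb\\.", "", nm)]]
      if (length(rows)) g[rows, ] <- 0
    }
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + eps)
  }
  list(params = params, state = st)
}
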