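# Internal neural-network engine for the KDeep predictors.
#
# Pure-R, batch-vectorised implementations of: valid-padding 1-D
# convolution over encoded rows, ReLU, non-overlapping max pooling,
# inverted dropout, additive (location-free) attention, BiLSTM, two dense
# layers, sigmoid binary cross-entropy, and Adam. Analytic gradients are
# verified against finite differences in the test suite.

.sigm <- function(x) 1 / (1 + exp(-x))
.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

.glorot <- function(nr, nc) {
  l <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -l, l), nr, nc)
}

.poolLen <- function(cfg) {
  P <- cfg@inputRows - cfg@filterWidth + 1L
  max(P %/% cfg@poolSize, 1L)
}

.nnInitParams <- function(cfg) {
  K <- cfg@nFilters; Fw <- cfg@filterWidth; C <- cfg@inputCols
  U <- cfg@lstmUnits; D <- cfg@denseUnits; A <- cfg@attnUnits
  Q <- .poolLen(cfg)
  p <- list(convW = .glorot(Fw * C, K), convB = numeric(K))
  if (cfg@useAttention) {
    p$attnW <- .glorot(K, A)
    p$attnB <- numeric(A)
    p$attnV <- .glorot(A, 1L)
  }
  for (dir in c("f", "b")) {
    p[[paste0("lstmWx", dir)]] <- .glorot(K, 4L * U)
    p[[paste0("lstmWh", dir)]] <- .glorot(U, 4L * U)
    b <- numeric(4L * U)
    b[(U + 1L):(2L * U)] <- 1  # forget gate opens at init
    p[[paste0("lstmB", dir)]] <- b
  }
  # flattened per-position BiLSTM outputs feed the dense classifier;
  # slightly positive bias keeps ReLU units live at initialisation
  p$dense1W <- .glorot(Q * 2L * U, D); p$dense1B <- rep(0.01, D)
  p$dense2W <- .glorot(D, cfg@nOutputs); p$dense2B <- numeric(cfg@nOutputs)
  p
}

# im2col for valid 1-D convolution over rows: (n,S,C) -> (n*P, Fw*C)
.im2col <- function(X, Fw) {
  n <- dim(X)[1]; S <- dim(X)[2]; C <- dim(X)[3]
  P <- S - Fw + 1L
  out <- matrix(0, n * P, Fw * C)
  for (f in seq_len(Fw))
    out[, ((f - 1L) * C + 1L):(f * C)] <-
      matrix(X[, f:(f + P - 1L), , drop = FALSE], n * P, C)
  out
}

.lstmForward <- function(Wx, Wh, b, Xseq) {
  n <- dim(Xseq)[1]; Q <- dim(Xseq)[2]; U <- nrow(Wh)
  iI <- 1:U; fI <- U + 1:U; gI <- 2L * U + 1:U; oI <- 3L * U + 1:U
  h <- matrix(0, n, U); cc <- matrix(0, n, U)
  steps <- vector("list", Q)
  hseq <- array(0, c(n, Q, U))
  for (t in seq_len(Q)) {
    xt <- matrix(Xseq[, t, ], n)
    z <- sweep(xt %*% Wx + h %*% Wh, 2, b, `+`)
    i <- .sigm(z[, iI, drop = FALSE]); f <- .sigm(z[, fI, drop = FALSE])
    g <- tanh(z[, gI, drop = FALSE]); o <- .sigm(z[, oI, drop = FALSE])
    cPrev <- cc; hPrev <- h
    cc <- f * cPrev + i * g
    h <- o * tanh(cc)
    hseq[, t, ] <- h
    steps[[t]] <- list(xt = xt, i = i, f = f, g = g, o = o,
                       cPrev = cPrev, hPrev = hPrev, tanhc = tanh(cc))
  }
  list(h = h, hseq = hseq, steps = steps)
}

# reverse each strand's first Qv[i] time steps in place (zeros beyond);
# an involution, used to run the backward LSTM over valid positions only
.revRows <- function(arr, Qv) {
  n <- dim(arr)[1]; Q <- dim(arr)[2]; K <- dim(arr)[3]
  out <- array(0, dim(arr))
  for (t in seq_len(Q)) {
    v <- which(Qv >= t)
    if (!length(v)) next
    src <- Qv[v] - t + 1L
    idx <- cbind(rep(v, K), rep(src, K), rep(seq_len(K), each = length(v)))
    out[cbind(rep(v, K), t, rep(seq_len(K), each = length(v)))] <- arr[idx]
  }
  out
}

# BPTT with a gradient entering at every hidden state (dHseq: n x Q x U)
.lstmBackward <- function(Wx, Wh, cache, dHseq) {
  steps <- cache$steps
  Q <- length(steps)
  n <- dim(dHseq)[1]; U <- nrow(Wh); K <- nrow(Wx)
  dWx <- matrix(0, K, 4L * U); dWh <- matrix(0, U, 4L * U)
  db <- numeric(4L * U)
  dXseq <- array(0, c(n, Q, K))
  dh <- matrix(0, n, U); dc <- matrix(0, n, U)
  for (t in rev(seq_len(Q))) {
    dh <- dh + matrix(dHseq[, t, ], n)
    s <- steps[[t]]
    do <- dh * s$tanhc
    dc <- dc + dh * s$o * (1 - s$tanhc^2)
    di <- dc * s$g; dg <- dc * s$i; df <- dc * s$cPrev
    dcPrev <- dc * s$f
    dz <- cbind(di * s$i * (1 - s$i),
                df * s$f * (1 - s$f),
                dg * (1 - s$g^2),
                do * s$o * (1 - s$o))
    dWx <- dWx + crossprod(s$xt, dz)
    dWh <- dWh + crossprod(s$hPrev, dz)
    db <- db + colSums(dz)
    dXseq[, t, ] <- dz %*% t(Wx)
    dh <- dz %*% t(Wh)
    dc <- dcPrev
  }
  list(dWx = dWx, dWh = dWh, db = db, dXseq = dXseq)
}

# Full forward pass. mask: n x S logical (padding rows are a right suffix).
# dropMasks: NULL (inference / gradient check) or list(cnn=, lstm=) of
# pre-sampled inverted-dropout multipliers.
.nnForward <- function(p, cfg, X, mask, dropMasks = NULL) {
  n <- dim(X)[1]; S <- dim(X)[2]; C <- dim(X)[3]
  Fw <- cfg@filterWidth; K <- cfg@nFilters; M <- cfg@poolSize
  if (S != cfg@inputRows)
    stop(sprintf("encoded row count %d does not match the model's input size %d",
                 S, cfg@inputRows))
  P <- S - Fw + 1L
  Q <- max(P %/% M, 1L)
  Xcol <- .im2col(X, Fw)
  Z <- sweep(Xcol %*% p$convW, 2, p$convB, `+`)
  A <- Z * (Z > 0)
  # a conv site is valid when every spanned row is real
  nSites <- pmax(rowSums(mask) - Fw + 1L, 0L)
  siteValid <- outer(nSites, seq_len(P), `>=`)       # n x P
  Aarr <- array(A, c(n, P, K)) * array(siteValid, c(n, P, K))
  pooled <- array(0, c(n, Q, K))
  amax <- array(1L, c(n, Q, K))
  poolValid <- matrix(FALSE, n, Q)
  for (q in seq_len(Q)) {
    w <- ((q - 1L) * M + 1L):min(q * M, P)
    bm <- matrix(Aarr[, w[1L], ], n); bi <- matrix(w[1L], n, K)
    for (j in w[-1L]) {
      cur <- matrix(Aarr[, j, ], n)
      upd <- cur > bm
      bm[upd] <- cur[upd]; bi[upd] <- j
    }
    pooled[, q, ] <- bm; amax[, q, ] <- bi
    poolValid[, q] <- siteValid[, w[1L]]
  }
  H <- pooled
  if (!is.null(dropMasks)) H <- H * dropMasks$cnn
  attn <- NULL
  if (cfg@useAttention) {
    Hmat <- matrix(H, n * Q)
    U1 <- tanh(sweep(Hmat %*% p$attnW, 2, p$attnB, `+`))
    E <- matrix(U1 %*% p$attnV, n, Q)
    E[!poolValid] <- -Inf
    Emax <- apply(E, 1, max)
    W0 <- exp(E - Emax)
    alpha <- W0 / rowSums(W0)                         # n x Q, rows sum to 1
    Hatt <- H * array(alpha, c(n, Q, K))
    attn <- list(Hpre = H, U1 = U1, alpha = alpha, poolValid = poolValid)
    H <- Hatt
  }
  # BiLSTM over valid pooled positions; the backward direction consumes
  # each strand's positions in per-strand reversed order so right-padding
  # cannot influence any real position (exact batch invariance)
  Qv <- pmax(rowSums(poolValid), 1L)
  lf <- .lstmForward(p$lstmWxf, p$lstmWhf, p$lstmBf, H)
  lb <- .lstmForward(p$lstmWxb, p$lstmWhb, p$lstmBb, .revRows(H, Qv))
  # flatten per-position [forward; backward] states into the classifier
  hbOrig <- .revRows(lb$hseq, Qv)          # backward states at original positions
  Ulen <- dim(lf$hseq)[3]
  Hl <- cbind(matrix(lf$hseq, n, Q * Ulen), matrix(hbOrig, n, Q * Ulen))
  if (!is.null(dropMasks)) Hl <- Hl * dropMasks$lstm
  D1z <- sweep(Hl %*% p$dense1W, 2, p$dense1B, `+`)
  D1 <- D1z * (D1z > 0)
  logits <- sweep(D1 %*% p$dense2W, 2, p$dense2B, `+`)
  list(yhat = .sigm(logits), logits = logits,
       cache = list(Xcol = Xcol, Aarr = Aarr, amax = amax, P = P, Q = Q,
                    Qv = Qv, siteValid = siteValid, poolValid = poolValid,
                    pooled = pooled, H = H, attn = attn, lf = lf, lb = lb,
                    Hl = Hl, D1z = D1z, D1 = D1, dropMasks = dropMasks))
}

# mean binary cross-entropy from logits (numerically stable)
.bceLoss <- function(logits, Y) mean(.softplus(logits) - Y * logits)

# Backward pass; returns gradient list matching names(p)
.nnBackward <- function(p, cfg, fw, Y) {
  ca <- fw$cache
  n <- nrow(Y); K <- cfg@nFilters
  Q <- ca$Q; P <- ca$P; M <- cfg@poolSize
  dlogits <- (fw$yhat - Y) / length(Y)
  g <- list()
  g$dense2W <- crossprod(ca$D1, dlogits)
  g$dense2B <- colSums(dlogits)
  dD1 <- dlogits %*% t(p$dense2W) * (ca$D1z > 0)
  g$dense1W <- crossprod(ca$Hl, dD1)
  g$dense1B <- colSums(dD1)
  dHl <- dD1 %*% t(p$dense1W)
  if (!is.null(ca$dropMasks)) dHl <- dHl * ca$dropMasks$lstm
  U <- cfg@lstmUnits
  Qv <- ca$Qv
  dHseqF <- array(dHl[, seq_len(Q * U), drop = FALSE], c(n, Q, U))
  dHseqB <- .revRows(array(dHl[, Q * U + seq_len(Q * U), drop = FALSE],
                           c(n, Q, U)), Qv)
  bf <- .lstmBackward(p$lstmWxf, p$lstmWhf, ca$lf, dHseqF)
  bb <- .lstmBackward(p$lstmWxb, p$lstmWhb, ca$lb, dHseqB)
  g$lstmWxf <- bf$dWx; g$lstmWhf <- bf$dWh; g$lstmBf <- bf$db
  g$lstmWxb <- bb$dWx; g$lstmWhb <- bb$dWh; g$lstmBb <- bb$db
  # un-reverse the backward direction's input gradient per strand
  dH <- bf$dXseq + .revRows(bb$dXseq, Qv)            # grad wrt post-attention H
  if (cfg@useAttention) {
    at <- ca$attn
    alpha <- at$alpha
    dalpha <- matrix(0, n, Q)
    for (q in seq_len(Q))
      dalpha[, q] <- rowSums(matrix(dH[, q, ] * at$Hpre[, q, ], n))
    dHpre <- dH * array(alpha, c(n, Q, K))
    dE <- alpha * (dalpha - rowSums(alpha * dalpha))  # softmax backward
    dE[!at$poolValid] <- 0
    dEvec <- as.vector(dE)                            # n*Q
    g$attnV <- crossprod(at$U1, dEvec)
    dU1 <- (cbind(dEvec) %*% t(p$attnV)) * (1 - at$U1^2)
    Hmat <- matrix(at$Hpre, n * Q)
    g$attnW <- crossprod(Hmat, dU1)
    g$attnB <- colSums(dU1)
    dHmat <- dU1 %*% t(p$attnW)
    dH <- dHpre + array(dHmat, c(n, Q, K))
  }
  if (!is.null(ca$dropMasks)) dH <- dH * ca$dropMasks$cnn
  # scatter pooled gradients back to argmax conv sites
  dA <- numeric(n * P * K)
  Iarr <- array(rep(seq_len(n), Q * K), c(n, Q, K))
  Karr <- array(rep(seq_len(K), each = n * Q), c(n, Q, K))
  lin <- Iarr + (ca$amax - 1L) * n + (Karr - 1L) * n * P
  dA[as.vector(lin)] <- as.vector(dH)
  dZ <- dA * as.vector(ca$Aarr > 0)
  dZmat <- matrix(dZ, n * P, K)
  g$convW <- crossprod(ca$Xcol, dZmat)
  g$convB <- colSums(dZmat)
  g[names(p)]
}

.adamInit <- function(p) list(m = lapply(p, function(x) x * 0),
                              v = lapply(p, function(x) x * 0), t = 0L)

.adamStep <- function(p, g, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(p)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mh <- st$m[[nm]] / (1 - beta1^st$t)
    vh <- st$v[[nm]] / (1 - beta2^st$t)
    p[[nm]] <- p[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(p = p, st = st)
}

.sampleDropMasks <- function(cfg, n, Q) {
  mk <- function(dims, rate) {
    if (rate <= 0) return(array(1, dims))
    array((stats::runif(prod(dims)) >= rate) / (1 - rate), dims)
  }
  list(cnn = mk(c(n, Q, cfg@nFilters), cfg@dropoutCnn),
       lstm = mk(c(n, 2L * Q * cfg@lstmUnits), cfg@dropoutLstm))
}
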