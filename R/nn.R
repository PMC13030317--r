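# Minimal deterministic neural-network engine for multichannel windows.
#
# Tensors are base-R arrays (batch B, time T, channels C); a (B,T,C) array
# flattens to a (B*T, C) matrix without copying semantics issues because the
# first two dims combine in storage order, so every convolution reduces to a
# small number of BLAS matmuls (one per kernel tap). Each layer is a list
# with a $par list of trainable arrays; layer_fwd returns (out, cache),
# layer_bwd returns (dx, dpar) with dpar mirroring $par. Residual blocks
# recurse, so the whole network is an ordered list of layers.

flat2 <- function(a) { d <- dim(a); dim(a) <- c(d[1] * d[2], d[3]); a }

sigm <- function(x) 1 / (1 + exp(-x))

layer_conv1d <- function(cin, cout, k, dilation = 1L, causal = FALSE) {
  par <- list()
  sdw <- sqrt(2 / (k * cin))
  for (kk in seq_len(k))
    par[[paste0("W", kk)]] <- matrix(stats::rnorm(cin * cout, 0, sdw),
                                     cin, cout)
  par$b <- numeric(cout)
  list(type = "conv1d", k = k, dilation = as.integer(dilation),
       causal = causal, cin = cin, cout = cout, par = par)
}

conv1d_fwd <- function(lay, X) {
  d <- dim(X); B <- d[1]; Tt <- d[2]
  pad <- (lay$k - 1L) * lay$dilation
  pl <- if (lay$causal) pad else pad %/% 2L
  Xp <- array(0, c(B, Tt + pad, lay$cin))
  Xp[, pl + seq_len(Tt), ] <- X
  OutF <- matrix(0, B * Tt, lay$cout)
  for (kk in seq_len(lay$k)) {
    Xk <- Xp[, (kk - 1L) * lay$dilation + seq_len(Tt), , drop = FALSE]
    dim(Xk) <- c(B * Tt, lay$cin)
    OutF <- OutF + Xk %*% lay$par[[kk]]
  }
  OutF <- sweep(OutF, 2, lay$par$b, "+")
  dim(OutF) <- c(B, Tt, lay$cout)
  list(out = OutF, cache = list(Xp = Xp, B = B, Tt = Tt, pl = pl))
}

conv1d_bwd <- function(lay, cache, dout) {
  B <- cache$B; Tt <- cache$Tt
  dOutF <- dout; dim(dOutF) <- c(B * Tt, lay$cout)
  dpar <- list(); dpar$b <- colSums(dOutF)
  dXp <- array(0, dim(cache$Xp))
  for (kk in seq_len(lay$k)) {
    idx <- (kk - 1L) * lay$dilation + seq_len(Tt)
    Xk <- cache$Xp[, idx, , drop = FALSE]
    dim(Xk) <- c(B * Tt, lay$cin)
    dpar[[paste0("W", kk)]] <- crossprod(Xk, dOutF)
    dXk <- dOutF %*% t(lay$par[[kk]])
    dim(dXk) <- c(B, Tt, lay$cin)
    dXp[, idx, ] <- dXp[, idx, , drop = FALSE] + dXk
  }
  dX <- dXp[, cache$pl + seq_len(Tt), , drop = FALSE]
  list(dx = dX, dpar = dpar[c(paste0("W", seq_len(lay$k)), "b")])
}

layer_bn <- function(c, momentum = 0.9, eps = 1e-5) {
  list(type = "bn", c = c, momentum = momentum, eps = eps,
       par = list(gamma = rep(1, c), beta = numeric(c)),
       state = list(mean = numeric(c), var = rep(1, c)))
}

bn_fwd <- function(lay, X, train) {
  d <- dim(X); XF <- flat2(X); N <- nrow(XF)
  if (train) {
    mu <- colMeans(XF)
    va <- colMeans(XF^2) - mu^2
  } else {
    mu <- lay$state$mean; va <- lay$state$var
  }
  inv <- 1 / sqrt(va + lay$eps)
  xhat <- sweep(sweep(XF, 2, mu, "-"), 2, inv, "*")
  out <- sweep(sweep(xhat, 2, lay$par$gamma, "*"), 2, lay$par$beta, "+")
  dim(out) <- d
  new_state <- if (train) list(
    mean = lay$momentum * lay$state$mean + (1 - lay$momentum) * mu,
    var = lay$momentum * lay$state$var + (1 - lay$momentum) * va) else
      lay$state
  list(out = out,
       cache = list(xhat = xhat, inv = inv, d = d, N = N, train = train),
       state = new_state)
}

bn_bwd <- function(lay, cache, dout) {
  dF <- dout; dim(dF) <- c(cache$N, lay$c)
  dgamma <- colSums(dF * cache$xhat)
  dbeta <- colSums(dF)
  if (cache$train) {
    dxhat <- sweep(dF, 2, lay$par$gamma, "*")
    t1 <- sweep(dxhat, 2, colMeans(dxhat), "-")
    t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*")
    dX <- sweep(t1 - t2, 2, cache$inv, "*")
  } else {
    dX <- sweep(sweep(dF, 2, lay$par$gamma, "*"), 2, cache$inv, "*")
  }
  dim(dX) <- cache$d
  list(dx = dX, dpar = list(gamma = dgamma, beta = dbeta))
}

layer_relu <- function() list(type = "relu", par = list())

layer_maxpool <- function() list(type = "maxpool", par = list())

maxpool_fwd <- function(lay, X) {
  d <- dim(X); Tout <- d[2] %/% 2L
  i1 <- seq(1L, 2L * Tout, by = 2L)
  A <- X[, i1, , drop = FALSE]; Bb <- X[, i1 + 1L, , drop = FALSE]
  mask <- A >= Bb
  list(out = pmax(A, Bb),
       cache = list(mask = mask, d = d, Tout = Tout, i1 = i1))
}

maxpool_bwd <- function(lay, cache, dout) {
  dX <- array(0, cache$d)
  dX[, cache$i1, ] <- dout * cache$mask
  dX[, cache$i1 + 1L, ] <- dout * !cache$mask
  list(dx = dX, dpar = list())
}

layer_avgpool <- function(f) list(type = "avgpool", f = as.integer(f),
                                  par = list())

avgpool_fwd <- function(lay, X) {
  d <- dim(X); f <- lay$f; Tout <- d[2] %/% f
  out <- array(0, c(d[1], Tout, d[3]))
  for (j in seq_len(f))
    out <- out + X[, (seq_len(Tout) - 1L) * f + j, , drop = FALSE]
  list(out = out / f, cache = list(d = d, Tout = Tout))
}

avgpool_bwd <- function(lay, cache, dout) {
  dX <- array(0, cache$d); f <- lay$f
  for (j in seq_len(f))
    dX[, (seq_len(cache$Tout) - 1L) * f + j, ] <- dout / f
  list(dx = dX, dpar = list())
}

layer_gap <- function() list(type = "gap", par = list())

gap_fwd <- function(lay, X) {
  d <- dim(X)
  out <- matrix(0, d[1], d[3])
  for (t in seq_len(d[2])) out <- out + X[, t, ]
  list(out = out / d[2], cache = list(d = d))
}

gap_bwd <- function(lay, cache, dout) {
  d <- cache$d
  dX <- array(0, d)
  for (t in seq_len(d[2])) dX[, t, ] <- dout / d[2]
  list(dx = dX, dpar = list())
}

layer_dropout <- function(p) list(type = "dropout", p = p, par = list())

layer_dense <- function(cin, cout, init = c("he", "glorot")) {
  init <- match.arg(init)
  sdw <- if (init == "he") sqrt(2 / cin) else sqrt(1 / cin)
  list(type = "dense", cin = cin, cout = cout,
       par = list(W = matrix(stats::rnorm(cin * cout, 0, sdw), cin, cout),
                  b = numeric(cout)))
}

layer_lstm <- function(cin, h) {
  s <- sqrt(1 / h)
  b <- numeric(4 * h); b[(h + 1):(2 * h)] <- 1  # forget-gate bias
  list(type = "lstm", cin = cin, h = h,
       par = list(Wx = matrix(stats::runif(cin * 4 * h, -s, s), cin, 4 * h),
                  Wh = matrix(stats::runif(h * 4 * h, -s, s), h, 4 * h),
                  b = b))
}

lstm_fwd <- function(lay, X) {
  d <- dim(X); B <- d[1]; Tt <- d[2]; H <- lay$h
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  steps <- vector("list", Tt)
  ii <- seq_len(H); fi <- H + ii; gi <- 2L * H + ii; oi <- 3L * H + ii
  for (t in seq_len(Tt)) {
    xt <- X[, t, , drop = FALSE]; dim(xt) <- c(B, lay$cin)
    Z <- sweep(xt %*% lay$par$Wx + h %*% lay$par$Wh, 2, lay$par$b, "+")
    i <- sigm(Z[, ii, drop = FALSE]); f <- sigm(Z[, fi, drop = FALSE])
    g <- tanh(Z[, gi, drop = FALSE]); o <- sigm(Z[, oi, drop = FALSE])
    cprev <- cc
    cc <- f * cprev + i * g
    tc <- tanh(cc)
    steps[[t]] <- list(xt = xt, hprev = h, cprev = cprev, i = i, f = f,
                       g = g, o = o, tc = tc)
    h <- o * tc
  }
  list(out = h, cache = list(steps = steps, d = d))
}

lstm_bwd <- function(lay, cache, dout) {
  d <- cache$d; B <- d[1]; Tt <- d[2]; H <- lay$h
  dWx <- 0 * lay$par$Wx; dWh <- 0 * lay$par$Wh; db <- 0 * lay$par$b
  dX <- array(0, d)
  dh <- dout; dc <- matrix(0, B, H)
  for (t in rev(seq_len(Tt))) {
    st <- cache$steps[[t]]
    do <- dh * st$tc
    dc <- dc + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g; df <- dc * st$cprev; dg <- dc * st$i
    dZ <- cbind(di * st$i * (1 - st$i), df * st$f * (1 - st$f),
                dg * (1 - st$g^2), do * st$o * (1 - st$o))
    dWx <- dWx + crossprod(st$xt, dZ)
    dWh <- dWh + crossprod(st$hprev, dZ)
    db <- db + colSums(dZ)
    dX[, t, ] <- dZ %*% t(lay$par$Wx)
    dh <- dZ %*% t(lay$par$Wh)
    dc <- dc * st$f
  }
  list(dx = dX, dpar = list(Wx = dWx, Wh = dWh, b = db))
}

layer_gru <- function(cin, h) {
  s <- sqrt(1 / h)
  list(type = "gru", cin = cin, h = h,
       par = list(Wx = matrix(stats::runif(cin * 3 * h, -s, s), cin, 3 * h),
                  Wh = matrix(stats::runif(h * 3 * h, -s, s), h, 3 * h),
                  b = numeric(3 * h)))
}

gru_fwd <- function(lay, X) {
  d <- dim(X); B <- d[1]; Tt <- d[2]; H <- lay$h
  h <- matrix(0, B, H)
  steps <- vector("list", Tt)
  zi <- seq_len(H); ri <- H + zi; ni <- 2L * H + zi
  for (t in seq_len(Tt)) {
    xt <- X[, t, , drop = FALSE]; dim(xt) <- c(B, lay$cin)
    A <- sweep(xt %*% lay$par$Wx, 2, lay$par$b, "+")
    Hh <- h %*% lay$par$Wh
    z <- sigm(A[, zi, drop = FALSE] + Hh[, zi, drop = FALSE])
    r <- sigm(A[, ri, drop = FALSE] + Hh[, ri, drop = FALSE])
    n <- tanh(A[, ni, drop = FALSE] + r * Hh[, ni, drop = FALSE])
    hprev <- h
    h <- (1 - z) * n + z * hprev
    steps[[t]] <- list(xt = xt, hprev = hprev, z = z, r = r, n = n,
                       Hhn = Hh[, ni, drop = FALSE])
  }
  list(out = h, cache = list(steps = steps, d = d))
}

gru_bwd <- function(lay, cache, dout) {
  d <- cache$d; B <- d[1]; Tt <- d[2]; H <- lay$h
  dWx <- 0 * lay$par$Wx; dWh <- 0 * lay$par$Wh; db <- 0 * lay$par$b
  dX <- array(0, d)
  dh <- dout
  for (t in rev(seq_len(Tt))) {
    st <- cache$steps[[t]]
    dz <- dh * (st$hprev - st$n)
    dn <- dh * (1 - st$z)
    dhprev <- dh * st$z
    dn_pre <- dn * (1 - st$n^2)
    dr <- dn_pre * st$Hhn
    dHh_n <- dn_pre * st$r
    dz_pre <- dz * st$z * (1 - st$z)
    dr_pre <- dr * st$r * (1 - st$r)
    dA <- cbind(dz_pre, dr_pre, dn_pre)
    dHh <- cbind(dz_pre, dr_pre, dHh_n)
    dWx <- dWx + crossprod(st$xt, dA)
    db <- db + colSums(dA)
    dWh <- dWh + crossprod(st$hprev, dHh)
    dX[, t, ] <- dA %*% t(lay$par$Wx)
    dh <- dhprev + dHh %*% t(lay$par$Wh)
  }
  list(dx = dX, dpar = list(Wx = dWx, Wh = dWh, b = db))
}

# Residual TCN block: two dilated causal convs with ReLU + dropout, added to
# a (possibly 1x1-projected) skip path, then a final ReLU.
layer_residual <- function(layers, cin, cout) {
  par <- list()
  if (cin != cout)
    par$Wproj <- matrix(stats::rnorm(cin * cout, 0, sqrt(1 / cin)),
                        cin, cout)
  list(type = "residual", layers = layers, cin = cin, cout = cout, par = par)
}

layer_fwd <- function(lay, X, train) {
  switch(lay$type,
    conv1d = conv1d_fwd(lay, X),
    bn = bn_fwd(lay, X, train),
    relu = {
      mask <- X > 0
      list(out = X * mask, cache = list(mask = mask))
    },
    maxpool = maxpool_fwd(lay, X),
    avgpool = avgpool_fwd(lay, X),
    gap = gap_fwd(lay, X),
    dropout = {
      if (train && lay$p > 0) {
        mask <- array(stats::runif(length(X)) >= lay$p, dim(X)) / (1 - lay$p)
        list(out = X * mask, cache = list(mask = mask))
      } else list(out = X, cache = list(mask = NULL))
    },
    dense = list(out = sweep(X %*% lay$par$W, 2, lay$par$b, "+"),
                 cache = list(X = X)),
    lstm = lstm_fwd(lay, X),
    gru = gru_fwd(lay, X),
    residual = {
      inner <- net_fwd(lay$layers, X, train)
      res <- if (is.null(lay$par$Wproj)) X else {
        d <- dim(X); XF <- flat2(X)
        r <- XF %*% lay$par$Wproj; dim(r) <- c(d[1], d[2], lay$cout); r
      }
      pre <- inner$out + res
      mask <- pre > 0
      list(out = pre * mask,
           cache = list(inner = inner, mask = mask, X = X),
           layers = inner$layers)
    },
    stop("unknown layer type: ", lay$type))
}

layer_bwd <- function(lay, cache, dout) {
  switch(lay$type,
    conv1d = conv1d_bwd(lay, cache, dout),
    bn = bn_bwd(lay, cache, dout),
    relu = list(dx = dout * cache$mask, dpar = list()),
    maxpool = maxpool_bwd(lay, cache, dout),
    avgpool = avgpool_bwd(lay, cache, dout),
    gap = gap_bwd(lay, cache, dout),
    dropout = list(dx = if (is.null(cache$mask)) dout else dout * cache$mask,
                   dpar = list()),
    dense = list(dx = dout %*% t(lay$par$W),
                 dpar = list(W = crossprod(cache$X, dout),
                             b = colSums(dout))),
    lstm = lstm_bwd(lay, cache, dout),
    gru = gru_bwd(lay, cache, dout),
    residual = {
      dpre <- dout * cache$mask
      dpar <- list()
      if (is.null(lay$par$Wproj)) {
        dres <- dpre
      } else {
        d <- dim(cache$X)
        dpreF <- dpre; dim(dpreF) <- c(d[1] * d[2], lay$cout)
        XF <- flat2(cache$X)
        dpar$Wproj <- crossprod(XF, dpreF)
        dres <- dpreF %*% t(lay$par$Wproj)
        dim(dres) <- d
      }
      ib <- net_bwd(lay$layers, cache$inner$caches, dpre)
      dpar$layers <- ib$grads
      list(dx = dres + ib$dx, dpar = dpar)
    },
    stop("unknown layer type: ", lay$type))
}

# Forward/backward over an ordered layer list. net_fwd returns the possibly
# state-updated layers (batch-norm running statistics).
net_fwd <- function(layers, X, train) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_fwd(layers[[i]], X, train)
    X <- r$out
    caches[[i]] <- r$cache
    if (!is.null(r$state)) layers[[i]]$state <- r$state
    if (!is.null(r$layers)) layers[[i]]$layers <- r$layers
  }
  list(out = X, caches = caches, layers = layers)
}

net_bwd <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_bwd(layers[[i]], caches[[i]], dout)
    dout <- r$dx
    grads[[i]] <- r$dpar
  }
  list(dx = dout, grads = grads)
}

# Class-weighted softmax cross-entropy. y: integer class index (1-based),
# wts: per-class weights. Returns loss and dlogits.
softmax_xent <- function(logits, y, wts) {
  m <- apply(logits, 1, max)
  ex <- exp(logits - m)
  probs <- ex / rowSums(ex)
  n <- nrow(logits)
  wi <- wts[y]
  eps <- 1e-12
  loss <- sum(wi * -log(probs[cbind(seq_len(n), y)] + eps)) / sum(wi)
  dlog <- probs
  dlog[cbind(seq_len(n), y)] <- dlog[cbind(seq_len(n), y)] - 1
  dlog <- dlog * (wi / sum(wi))
  list(loss = loss, probs = probs, dlogits = dlog)
}

softmax_probs <- function(logits) {
  m <- apply(logits, 1, max)
  ex <- exp(logits - m)
  ex / rowSums(ex)
}

# Adam update, recursing through layer parameter lists (and residual
# sub-layers). state mirrors the parameter structure with m/v slots.
adam_init <- function(layers) {
  lapply(layers, function(lay) {
    st <- lapply(lay$par, function(p) list(m = 0 * p, v = 0 * p))
    if (lay$type == "residual") st$layers <- adam_init(lay$layers)
    st
  })
}

adam_step <- function(layers, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(layers[[i]]$par)) {
      if (is.null(g[[nm]])) next
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[nm]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[nm]]^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[i]]$par[[nm]] <- layers[[i]]$par[[nm]] -
        lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[nm]] <- st
    }
    if (layers[[i]]$type == "residual" && !is.null(g$layers)) {
      r <- adam_step(layers[[i]]$layers, g$layers, state[[i]]$layers, lr, t,
                     beta1, beta2, eps)
      layers[[i]]$layers <- r$layers
      state[[i]]$layers <- r$state
    }
  }
  list(layers = layers, state = state)
}

count_params <- function(layers) {
  sum(vapply(layers, function(lay) {
    n <- sum(vapply(lay$par, length, integer(1)))
    if (lay$type == "residual") n <- n + count_params(lay$layers)
    n
  }, numeric(1)))
}
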