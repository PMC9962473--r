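# Numerical engine of the count-regression network: strided valid
# convolutions computed as per-offset BLAS matrix products, ReLU, global
# average pooling with a single-unit dense head, full backpropagation and an
# RMSprop update. Everything is plain base R on h x w x C arrays, which is
# adequate for the desk-scale reduced backbone.

# 2^p x 2^p average pooling (p in {1, 2, 4, ...}), trailing rows/cols dropped
pool_avg <- function(x, p) {
  if (p == 1L) return(x)
  h <- (dim(x)[1] %/% p) * p; w <- (dim(x)[2] %/% p) * p
  x <- x[seq_len(h), seq_len(w), , drop = FALSE]
  acc <- array(0, c(h %/% p, w %/% p, dim(x)[3]))
  for (di in 0:(p - 1)) for (dj in 0:(p - 1))
    acc <- acc + x[seq(1 + di, h, p), seq(1 + dj, w, p), , drop = FALSE]
  acc / p^2
}

# input standardization: [0, 255] -> [-1, 1], then fixed average pooling
prepare_input <- function(image, pool) {
  pool_avg(image / 127.5 - 1, pool)
}

conv_fwd <- function(x, W, b, stride = 2L) {
  h <- dim(x)[1]; w <- dim(x)[2]; cin <- dim(x)[3]
  k <- dim(W)[1]; cout <- length(b)
  oh <- (h - k) %/% stride + 1L; ow <- (w - k) %/% stride + 1L
  ri <- seq(1L, by = stride, length.out = oh)
  ci <- seq(1L, by = stride, length.out = ow)
  outm <- matrix(b, oh * ow, cout, byrow = TRUE)
  for (di in 0:(k - 1)) for (dj in 0:(k - 1)) {
    Xm <- matrix(x[ri + di, ci + dj, ], oh * ow, cin)
    Wm <- matrix(W[di + 1, dj + 1, , ], cin, cout)
    outm <- outm + Xm %*% Wm
  }
  array(outm, c(oh, ow, cout))
}

conv_bwd <- function(x, W, stride, dout, need_dx = TRUE) {
  h <- dim(x)[1]; w <- dim(x)[2]; cin <- dim(x)[3]
  k <- dim(W)[1]; cout <- dim(W)[4]
  oh <- dim(dout)[1]; ow <- dim(dout)[2]
  ri <- seq(1L, by = stride, length.out = oh)
  ci <- seq(1L, by = stride, length.out = ow)
  doutm <- matrix(dout, oh * ow, cout)
  dW <- array(0, dim(W))
  db <- colSums(doutm)
  dx <- if (need_dx) array(0, dim(x)) else NULL
  for (di in 0:(k - 1)) for (dj in 0:(k - 1)) {
    Xm <- matrix(x[ri + di, ci + dj, ], oh * ow, cin)
    dW[di + 1, dj + 1, , ] <- crossprod(Xm, doutm)
    if (need_dx) {
      Wm <- matrix(W[di + 1, dj + 1, , ], cin, cout)
      dx[ri + di, ci + dj, ] <- dx[ri + di, ci + dj, , drop = FALSE] +
        array(tcrossprod(doutm, Wm), c(oh, ow, cin))
    }
  }
  list(dW = dW, db = db, dx = dx)
}

# forward through the conv stack; returns the final (post-ReLU) feature map
# and, when keep_cache, the per-layer inputs and ReLU masks for backprop
cnn_features <- function(params, x, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(params$conv)) else NULL
  for (l in seq_along(params$conv)) {
    layer <- params$conv[[l]]
    pre <- conv_fwd(x, layer$W, layer$b, layer$stride)
    mask <- pre > 0
    act <- pre * mask
    if (keep_cache) caches[[l]] <- list(x = x, mask = mask)
    x <- act
  }
  list(feat = x, caches = caches)
}

# scalar head: global average pooling + single-unit dense
cnn_head <- function(params, feat) {
  g <- colMeans(matrix(feat, ncol = dim(feat)[3]))
  list(yhat = sum(params$head$w * g) + params$head$b, gap = g)
}

cnn_forward <- function(params, x, keep_cache = FALSE) {
  fs <- cnn_features(params, x, keep_cache)
  hd <- cnn_head(params, fs$feat)
  list(yhat = hd$yhat, gap = hd$gap, feat = fs$feat, caches = fs$caches)
}

# backprop of d(loss)/d(yhat) = dy into parameter gradients
cnn_backward <- function(params, fwd, dy) {
  nconv <- length(params$conv)
  feat <- fwd$feat
  npos <- prod(dim(feat)[1:2])
  grads <- list(head = list(w = dy * fwd$gap, b = dy), conv = vector("list", nconv))
  dfeat <- array(rep(dy * params$head$w / npos, each = npos), dim(feat))
  dcur <- dfeat
  for (l in rev(seq_len(nconv))) {
    cache <- fwd$caches[[l]]
    dpre <- dcur * cache$mask
    bk <- conv_bwd(cache$x, params$conv[[l]]$W, params$conv[[l]]$stride,
                   dpre, need_dx = l > 1L)
    grads$conv[[l]] <- list(dW = bk$dW, db = bk$db)
    dcur <- bk$dx
  }
  grads
}

# elementwise RMSprop: state and params share the same nested shape
rmsprop_step <- function(params, grads, state, lr, rho = 0.9, eps = 1e-8) {
  upd <- function(p, g, s) {
    s <- rho * s + (1 - rho) * g^2
    list(p = p - lr * g / (sqrt(s) + eps), s = s)
  }
  for (l in seq_along(params$conv)) {
    uW <- upd(params$conv[[l]]$W, grads$conv[[l]]$dW, state$conv[[l]]$W)
    ub <- upd(params$conv[[l]]$b, grads$conv[[l]]$db, state$conv[[l]]$b)
    params$conv[[l]]$W <- uW$p; state$conv[[l]]$W <- uW$s
    params$conv[[l]]$b <- ub$p; state$conv[[l]]$b <- ub$s
  }
  uw <- upd(params$head$w, grads$head$w, state$head$w)
  ub <- upd(params$head$b, grads$head$b, state$head$b)
  params$head$w <- uw$p; state$head$w <- uw$s
  params$head$b <- ub$p; state$head$b <- ub$s
  list(params = params, state = state)
}

zero_like_params <- function(params) {
  list(conv = lapply(params$conv, function(l)
    list(W = array(0, dim(l$W)), b = numeric(length(l$b)))),
    head = list(w = numeric(length(params$head$w)), b = 0))
}

# He-normal initialization of the conv stack and head
init_params <- function(widths, kernel = 3L, stride = 2L, in_channels = 3L,
                        seed = 1L) {
  with_seed(seed, {
    conv <- vector("list", length(widths))
    cin <- in_channels
    for (l in seq_along(widths)) {
      cout <- widths[l]
      sd <- sqrt(2 / (kernel * kernel * cin))
      conv[[l]] <- list(
        W = array(stats::rnorm(kernel * kernel * cin * cout, 0, sd),
                  c(kernel, kernel, cin, cout)),
        b = numeric(cout), stride = stride)
      cin <- cout
    }
    head <- list(w = stats::rnorm(cin, 0, sqrt(1 / cin)), b = 0)
    list(conv = conv, head = head)
  })
}
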