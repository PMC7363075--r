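# Compact CPU convolutional-network engine.
#
# All learnable layers are stride-1 "same" convolutions realised as
# im2col + matrix product, with hand-written backward passes.  Feature maps
# are stored column-major: 2D maps as (H, W, C) arrays, 3D maps as
# (D, H, W, C) arrays.  Batched 3D maps (patch classifier) are stored as
# matrices with sample-major row blocks: sample i occupies rows
# (i-1)*DHW + 1:DHW, one column per channel, so channel concatenation is
# cbind and 1x1x1 convolutions are plain matrix products.

# ---------------------------------------------------------------- RNG scope
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Derive a reproducible 31-bit sub-seed from a parent seed and a stream name.
sub_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h * 9973) %% 2147483563) + 1L
}

# ------------------------------------------------------------ initialisers
glorot_uniform <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

conv_init <- function(ksp, cin, cout) {
  # ksp: spatial kernel size product (k^2 or k^3)
  list(W = glorot_uniform(ksp * cin, ksp * cout, c(ksp * cin, cout)),
       b = numeric(cout))
}

dense_init <- function(nin, nout) {
  list(W = glorot_uniform(nin, nout, c(nin, nout)), b = numeric(nout))
}

# fast column-wise ops on matrices (avoid sweep's aperm overhead)
addcol <- function(X, v) X + rep(v, each = nrow(X))
mulcol <- function(X, v) X * rep(v, each = nrow(X))

# -------------------------------------------------------- 2D/3D primitives
conv2d_f <- function(x, W, b, k) {
  d <- dim(x)
  P <- cpp_im2col2d(as.vector(x), d[1], d[2], d[3], k)
  Y <- addcol(P %*% W, b)
  list(y = array(Y, c(d[1], d[2], ncol(W))), P = P, dims = d, k = k)
}

conv2d_b <- function(cache, W, dy) {
  d <- cache$dims
  dY <- matrix(dy, nrow = d[1] * d[2])
  dW <- crossprod(cache$P, dY)
  db <- colSums(dY)
  dX <- cpp_col2im2d(dY %*% t(W), d[1], d[2], d[3], cache$k)
  list(dx = array(dX, d), dW = dW, db = db)
}

conv3d_f <- function(x, W, b, k) {
  d <- dim(x)
  P <- cpp_im2col3d(as.vector(x), d[1], d[2], d[3], d[4], k)
  Y <- addcol(P %*% W, b)
  list(y = array(Y, c(d[1], d[2], d[3], ncol(W))), P = P, dims = d, k = k)
}

conv3d_b <- function(cache, W, dy) {
  d <- cache$dims
  dY <- matrix(dy, nrow = d[1] * d[2] * d[3])
  dW <- crossprod(cache$P, dY)
  db <- colSums(dY)
  dX <- cpp_col2im3d(dY %*% t(W), d[1], d[2], d[3], d[4], cache$k)
  list(dx = array(dX, d), dW = dW, db = db)
}

relu_f <- function(x) list(y = pmax(x, 0), mask = x > 0)
relu_b <- function(cache, dy) dy * cache$mask

sigmoid <- function(x) 1 / (1 + exp(-x))

# ------------------------------------------------------------- U-Net (2D)
# Encoder-decoder with two pooling levels and skip connections; kernel size
# and per-level filter widths from the config; sigmoid single-channel output.
unet_init <- function(filters, k, cin = 1L, nd = 2L) {
  ksp <- k^nd
  f1 <- filters[1]; f2 <- filters[2]; f3 <- filters[3]
  list(e1 = conv_init(ksp, cin, f1),
       e2 = conv_init(ksp, f1, f2),
       e3 = conv_init(ksp, f2, f3),
       d2 = conv_init(ksp, f3 + f2, f2),
       d1 = conv_init(ksp, f2 + f1, f1),
       out = conv_init(1L, f1, 1L))
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  nd <- length(da)
  array(c(a, b), c(da[-nd], da[nd] + db[nd]))
}

split_ch <- function(x, n1) {
  d <- dim(x); nd <- length(d)
  m <- matrix(x, ncol = d[nd])
  list(array(m[, seq_len(n1)], c(d[-nd], n1)),
       array(m[, -seq_len(n1)], c(d[-nd], d[nd] - n1)))
}

unet2d_forward <- function(par, x, k) {
  c1 <- conv2d_f(x, par$e1$W, par$e1$b, k); r1 <- relu_f(c1$y)
  d1 <- dim(r1$y)
  p1 <- cpp_maxpool2d(as.vector(r1$y), d1[1], d1[2], d1[3])
  p1y <- array(p1$y, c(d1[1] / 2, d1[2] / 2, d1[3]))
  c2 <- conv2d_f(p1y, par$e2$W, par$e2$b, k); r2 <- relu_f(c2$y)
  d2 <- dim(r2$y)
  p2 <- cpp_maxpool2d(as.vector(r2$y), d2[1], d2[2], d2[3])
  p2y <- array(p2$y, c(d2[1] / 2, d2[2] / 2, d2[3]))
  c3 <- conv2d_f(p2y, par$e3$W, par$e3$b, k); r3 <- relu_f(c3$y)
  d3 <- dim(r3$y)
  u2 <- array(cpp_upsample2d(as.vector(r3$y), d3[1], d3[2], d3[3]),
              c(d3[1] * 2, d3[2] * 2, d3[3]))
  m2 <- concat_ch(u2, r2$y)
  c4 <- conv2d_f(m2, par$d2$W, par$d2$b, k); r4 <- relu_f(c4$y)
  d4 <- dim(r4$y)
  u1 <- array(cpp_upsample2d(as.vector(r4$y), d4[1], d4[2], d4[3]),
              c(d4[1] * 2, d4[2] * 2, d4[3]))
  m1 <- concat_ch(u1, r1$y)
  c5 <- conv2d_f(m1, par$d1$W, par$d1$b, k); r5 <- relu_f(c5$y)
  co <- conv2d_f(r5$y, par$out$W, par$out$b, 1L)
  prob <- sigmoid(co$y[, , 1])
  list(out = prob,
       cache = list(c1 = c1, r1 = r1, p1 = p1, c2 = c2, r2 = r2, p2 = p2,
                    c3 = c3, r3 = r3, c4 = c4, r4 = r4, c5 = c5, r5 = r5,
                    co = co, d1 = d1, d2 = d2, d3 = d3, d4 = d4))
}

# dz: gradient w.r.t. the pre-sigmoid logits (H x W)
unet2d_backward <- function(par, cache, dz, k) {
  g <- list()
  bo <- conv2d_b(cache$co, par$out$W, array(dz, dim(cache$co$y)))
  g$out <- list(W = bo$dW, b = bo$db)
  d5 <- relu_b(cache$r5, bo$dx)
  b5 <- conv2d_b(cache$c5, par$d1$W, d5)
  g$d1 <- list(W = b5$dW, b = b5$db)
  sp <- split_ch(b5$dx, dim(cache$r4$y)[3])
  du1 <- sp[[1]]; dr1_skip <- sp[[2]]
  d4 <- dim(cache$r4$y)
  dd4 <- array(cpp_upsample2d_bw(as.vector(du1), d4[1], d4[2], d4[3]), d4)
  d4r <- relu_b(cache$r4, dd4)
  b4 <- conv2d_b(cache$c4, par$d2$W, d4r)
  g$d2 <- list(W = b4$dW, b = b4$db)
  sp <- split_ch(b4$dx, dim(cache$r3$y)[3])
  du2 <- sp[[1]]; dr2_skip <- sp[[2]]
  d3 <- dim(cache$r3$y)
  dd3 <- array(cpp_upsample2d_bw(as.vector(du2), d3[1], d3[2], d3[3]), d3)
  d3r <- relu_b(cache$r3, dd3)
  b3 <- conv2d_b(cache$c3, par$e3$W, d3r)
  g$e3 <- list(W = b3$dW, b = b3$db)
  d2 <- cache$d2
  dp2 <- cpp_maxpool_bw(as.vector(b3$dx), cache$p2$idx, prod(d2))
  d2r <- relu_b(cache$r2, array(dp2, d2) + dr2_skip)
  b2 <- conv2d_b(cache$c2, par$e2$W, d2r)
  g$e2 <- list(W = b2$dW, b = b2$db)
  d1 <- cache$d1
  dp1 <- cpp_maxpool_bw(as.vector(b2$dx), cache$p1$idx, prod(d1))
  d1r <- relu_b(cache$r1, array(dp1, d1) + dr1_skip)
  b1 <- conv2d_b(cache$c1, par$e1$W, d1r)
  g$e1 <- list(W = b1$dW, b = b1$db)
  g
}

unet3d_forward <- function(par, x, k) {
  c1 <- conv3d_f(x, par$e1$W, par$e1$b, k); r1 <- relu_f(c1$y)
  d1 <- dim(r1$y)
  p1 <- cpp_maxpool3d(as.vector(r1$y), d1[1], d1[2], d1[3], d1[4], 2L, 2L, 2L)
  p1y <- array(p1$y, c(d1[1:3] / 2, d1[4]))
  c2 <- conv3d_f(p1y, par$e2$W, par$e2$b, k); r2 <- relu_f(c2$y)
  d2 <- dim(r2$y)
  p2 <- cpp_maxpool3d(as.vector(r2$y), d2[1], d2[2], d2[3], d2[4], 2L, 2L, 2L)
  p2y <- array(p2$y, c(d2[1:3] / 2, d2[4]))
  c3 <- conv3d_f(p2y, par$e3$W, par$e3$b, k); r3 <- relu_f(c3$y)
  d3 <- dim(r3$y)
  u2 <- array(cpp_upsample3d(as.vector(r3$y), d3[1], d3[2], d3[3], d3[4]),
              c(d3[1:3] * 2, d3[4]))
  m2 <- concat_ch(u2, r2$y)
  c4 <- conv3d_f(m2, par$d2$W, par$d2$b, k); r4 <- relu_f(c4$y)
  d4 <- dim(r4$y)
  u1 <- array(cpp_upsample3d(as.vector(r4$y), d4[1], d4[2], d4[3], d4[4]),
              c(d4[1:3] * 2, d4[4]))
  m1 <- concat_ch(u1, r1$y)
  c5 <- conv3d_f(m1, par$d1$W, par$d1$b, k); r5 <- relu_f(c5$y)
  co <- conv3d_f(r5$y, par$out$W, par$out$b, 1L)
  prob <- sigmoid(co$y[, , , 1])
  list(out = prob,
       cache = list(c1 = c1, r1 = r1, p1 = p1, c2 = c2, r2 = r2, p2 = p2,
                    c3 = c3, r3 = r3, c4 = c4, r4 = r4, c5 = c5, r5 = r5,
                    co = co, d1 = d1, d2 = d2, d3 = d3, d4 = d4))
}

unet3d_backward <- function(par, cache, dz, k) {
  g <- list()
  bo <- conv3d_b(cache$co, par$out$W, array(dz, dim(cache$co$y)))
  g$out <- list(W = bo$dW, b = bo$db)
  d5 <- relu_b(cache$r5, bo$dx)
  b5 <- conv3d_b(cache$c5, par$d1$W, d5)
  g$d1 <- list(W = b5$dW, b = b5$db)
  sp <- split_ch(b5$dx, dim(cache$r4$y)[4])
  du1 <- sp[[1]]; dr1_skip <- sp[[2]]
  d4 <- dim(cache$r4$y)
  dd4 <- array(cpp_upsample3d_bw(as.vector(du1), d4[1], d4[2], d4[3], d4[4]), d4)
  d4r <- relu_b(cache$r4, dd4)
  b4 <- conv3d_b(cache$c4, par$d2$W, d4r)
  g$d2 <- list(W = b4$dW, b = b4$db)
  sp <- split_ch(b4$dx, dim(cache$r3$y)[4])
  du2 <- sp[[1]]; dr2_skip <- sp[[2]]
  d3 <- dim(cache$r3$y)
  dd3 <- array(cpp_upsample3d_bw(as.vector(du2), d3[1], d3[2], d3[3], d3[4]), d3)
  d3r <- relu_b(cache$r3, dd3)
  b3 <- conv3d_b(cache$c3, par$e3$W, d3r)
  g$e3 <- list(W = b3$dW, b = b3$db)
  d2 <- cache$d2
  dp2 <- cpp_maxpool_bw(as.vector(b3$dx), cache$p2$idx, prod(d2))
  d2r <- relu_b(cache$r2, array(dp2, d2) + dr2_skip)
  b2 <- conv3d_b(cache$c2, par$e2$W, d2r)
  g$e2 <- list(W = b2$dW, b = b2$db)
  d1 <- cache$d1
  dp1 <- cpp_maxpool_bw(as.vector(b2$dx), cache$p1$idx, prod(d1))
  d1r <- relu_b(cache$r1, array(dp1, d1) + dr1_skip)
  b1 <- conv3d_b(cache$c1, par$e1$W, d1r)
  g$e1 <- list(W = b1$dW, b = b1$db)
  g
}

# ------------------------------------------------------- batched 3D helpers
# Batched maps: matrix (N*DHW) x C, sample-major row blocks.  Convolutions
# loop over samples (im2col per sample, no concatenation of the patch
# matrices) to keep allocations small.

bconv3_f <- function(X, W, b, sp, k) {
  if (k == 1L) {
    Y <- addcol(X %*% W, b)
    return(list(y = Y, P = X, k = 1L))
  }
  n <- nrow(X) / prod(sp)
  P <- cpp_im2col3d_batch(X, n, sp[1], sp[2], sp[3], ncol(X), k)
  list(y = addcol(P %*% W, b), P = P, k = k)
}

bconv3_b <- function(cache, W, dY, sp, k, cin) {
  db <- colSums(dY)
  dW <- crossprod(cache$P, dY)
  if (k == 1L) return(list(dx = dY %*% t(W), dW = dW, db = db))
  n <- nrow(dY) / prod(sp)
  dX <- cpp_col2im3d_batch(dY %*% t(W), n, sp[1], sp[2], sp[3], cin, k)
  list(dx = dX, dW = dW, db = db)
}

bpool_f <- function(X, sp, pool) {
  n <- nrow(X) / prod(sp)
  r <- cpp_maxpool3d_batch(X, n, sp[1], sp[2], sp[3], ncol(X),
                           pool[1], pool[2], pool[3])
  list(y = r$y, idx = r$idx, n = n, sp = sp, spo = sp %/% pool, C = ncol(X))
}

bpool_b <- function(cache, dY) {
  cpp_maxpool3d_batch_bw(dY, cache$idx, cache$n, prod(cache$sp),
                         prod(cache$spo))
}

# ---------------------------------------------------------- batch norm
# Trainable gamma/beta live in the parameter tree; running statistics are a
# separate state list updated in training-mode forward passes.
bn_par_init <- function(C) list(gamma = rep(1, C), beta = numeric(C))
bn_state_init <- function(C) list(rmean = numeric(C), rvar = rep(1, C))

bn_f <- function(X, par, state, train, momentum = 0.99, eps = 1e-3) {
  if (train) {
    mu <- colMeans(X)
    xc <- addcol(X, -mu)
    va <- colMeans(xc^2)
    state$rmean <- momentum * state$rmean + (1 - momentum) * mu
    state$rvar <- momentum * state$rvar + (1 - momentum) * va
  } else {
    mu <- state$rmean; va <- state$rvar
    xc <- addcol(X, -mu)
  }
  istd <- 1 / sqrt(va + eps)
  xn <- mulcol(xc, istd)
  Y <- addcol(mulcol(xn, par$gamma), par$beta)
  list(y = Y, cache = list(xn = xn, istd = istd, gamma = par$gamma),
       state = state)
}

bn_b <- function(cache, dY, train = TRUE) {
  n <- nrow(dY)
  dgamma <- colSums(dY * cache$xn)
  dbeta <- colSums(dY)
  dxn <- mulcol(dY, cache$gamma)
  if (train) {
    dX <- mulcol(addcol(dxn, -colMeans(dxn)) -
                   mulcol(cache$xn, colMeans(dxn * cache$xn)),
                 cache$istd)
  } else {
    dX <- mulcol(dxn, cache$istd)
  }
  list(dx = dX, gamma = dgamma, beta = dbeta)
}

# ------------------------------------------------------------------- Adam
adam_init <- function(params) {
  flat <- unlist(params)
  list(m = numeric(length(flat)), v = numeric(length(flat)), t = 0)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  p <- unlist(params)
  g <- unlist(grads)
  state$t <- state$t + 1
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  mh <- state$m / (1 - beta1^state$t)
  vh <- state$v / (1 - beta2^state$t)
  p <- p - lr * mh / (sqrt(vh) + eps)
  list(params = utils::relist(p, params), state = state)
}
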