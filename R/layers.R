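# Network primitives. Activations are 4-d arrays with dim (H, W, C, N):
# rows, columns, channels, batch. Convolutions are 3x3, stride 1, zero
# padding 1 ("same"); pooling is 2x2, stride 2. The heavy kernels (conv and
# pool, forward and backward) are compiled (src/cnn_ops.cpp); the *_ref
# functions below are independent pure-R implementations kept as oracles for
# the test suite. Batch normalization, the fully connected head and the
# softmax/cross-entropy stay in R. All backward passes are exact gradients,
# verified against finite differences in the tests.

conv_forward <- function(x, wmat, b) {
  conv3x3_fwd_cpp(x, wmat, b)
}

# Returns gradients dw (Cout x 9Cin), db, and dx (same shape as x; NULL
# when not requested).
conv_backward <- function(x, dy, wmat, want_dx = TRUE) {
  conv3x3_bwd_cpp(x, dy, wmat, want_dx)
}

pool_forward <- function(x) {
  pool2_fwd_cpp(x)
}

pool_backward <- function(dy, pf) {
  pool2_bwd_cpp(dy, pf$sel, pf$in_dim)
}

relu_forward <- function(x) pmax(x, 0)
relu_backward <- function(dy, x) dy * (x > 0)

# ---- pure-R reference implementations (test oracles) ----

pad_array <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  xp
}

# Index matrix mapping the padded array of one sample to the im2col column
# matrix; rows ordered (dr, dc, channel), dr fastest.
im2col_index <- function(H, W, C, k = 3L, pad = 1L) {
  Hp <- H + 2L * pad
  Wp <- W + 2L * pad
  off <- as.vector(outer(
    as.vector(outer(0:(k - 1L), (0:(k - 1L)) * Hp, "+")),
    (0:(C - 1L)) * Hp * Wp, "+"
  ))
  base <- as.vector(outer(seq_len(H), (seq_len(W) - 1L) * Hp, "+"))
  outer(off, base, "+")
}

conv_forward_ref <- function(x, wmat, b, pad = 1L) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  xp <- pad_array(x, pad)
  idx <- im2col_index(H, W, C, pad = pad)
  per <- prod(dim(xp)[1:3])
  idxf <- rep.int(as.vector(idx), N) +
    rep((0:(N - 1L)) * per, each = length(idx))
  cols <- matrix(xp[idxf], nrow = nrow(idx))
  out <- wmat %*% cols + b
  aperm(array(out, c(nrow(wmat), H, W, N)), c(2L, 3L, 1L, 4L))
}

pool_forward_ref <- function(x) {
  d <- dim(x)
  Ho <- d[1] %/% 2L; Wo <- d[2] %/% 2L
  ri <- seq_len(Ho) * 2L - 1L
  ci <- seq_len(Wo) * 2L - 1L
  pmax(x[ri, ci, , , drop = FALSE], x[ri + 1L, ci, , , drop = FALSE],
       x[ri, ci + 1L, , , drop = FALSE], x[ri + 1L, ci + 1L, , , drop = FALSE])
}

# ---- batch normalization ----

# Per-channel normalization over (H, W, N), trainable scale/shift,
# exponential running statistics for inference. Internally the (H, W, C, N)
# array is viewed as a (H*W) x (C*N) matrix whose columns cycle through
# channels fastest; per-channel statistics are row means of the C x N
# reshape of its column means.
per_channel <- function(colstats, C) rowMeans(matrix(colstats, C))

# Channel-broadcast a length-C vector over the (H*W) x (C*N) matrix view:
# R recycles the length H*W*C expansion exactly N times.
chan_expand <- function(v, HW) rep(v, each = HW)

bn_forward <- function(x, gamma, beta, run_mean, run_var,
                       train = TRUE, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  C <- d[3]; N <- d[4]; HW <- d[1] * d[2]
  xm <- matrix(x, nrow = HW)
  if (train) {
    mu <- per_channel(colMeans(xm), C)
    xc <- xm - chan_expand(mu, HW)
    va <- per_channel(colMeans(xc^2), C)
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * va
  } else {
    mu <- run_mean
    va <- run_var
    xc <- xm - chan_expand(mu, HW)
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * chan_expand(inv, HW)
  ym <- xhat * chan_expand(gamma, HW) + chan_expand(beta, HW)
  list(y = array(ym, d), xhat = xhat, inv = inv,
       run_mean = run_mean, run_var = run_var)
}

bn_backward <- function(dy, bf, gamma) {
  d <- dim(dy)
  C <- d[3]; N <- d[4]; HW <- d[1] * d[2]
  dym <- matrix(dy, nrow = HW)
  m <- HW * N
  dgamma <- rowSums(matrix(colSums(dym * bf$xhat), C))
  dbeta <- rowSums(matrix(colSums(dym), C))
  dxhat <- dym * chan_expand(gamma, HW)
  c1 <- rowSums(matrix(colSums(dxhat), C))
  c2 <- rowSums(matrix(colSums(dxhat * bf$xhat), C))
  dxm <- (dxhat - chan_expand(c1 / m, HW) -
            bf$xhat * chan_expand(c2 / m, HW)) * chan_expand(bf$inv, HW)
  list(dx = array(dxm, d), dgamma = dgamma, dbeta = dbeta)
}

# ---- fully connected head ----

fc_forward <- function(x, w, b) w %*% x + as.vector(b)

fc_backward <- function(dy, x, w) {
  list(dw = dy %*% t(x), db = rowSums(dy), dx = t(w) %*% dy)
}

# Softmax over rows of a (K x N) logit matrix.
softmax <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max))
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

# Mean categorical cross-entropy and its logit gradient. `labels` are 1..K.
softmax_ce <- function(z, labels) {
  p <- softmax(z)
  n <- ncol(p)
  picked <- p[cbind(labels, seq_len(n))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dz <- p
  dz[cbind(labels, seq_len(n))] <- dz[cbind(labels, seq_len(n))] - 1
  list(loss = loss, probs = p, dz = dz / n)
}
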