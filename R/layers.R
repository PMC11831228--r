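# Low-level network layers on H x W x C arrays (batch size 1).  The
# convolution kernels live in src/conv.cpp; transposed convolution reuses
# them through the adjoint relations, with its weights stored in the
# layout of the mirrored (downsampling) convolution.

K_SIZE <- 4L  # all convolutions are 4x4, pix2pix-style

conv_forward <- function(x, W, b, stride = 2L, pad = 1L) {
  nn_conv_fwd(x, W, b, K_SIZE, as.integer(stride), as.integer(pad))
}

conv_backward <- function(x, W, gout, stride = 2L, pad = 1L) {
  nn_conv_bwd(x, W, gout, K_SIZE, as.integer(stride), as.integer(pad), TRUE)
}

tconv_forward <- function(x, W, b, out_h, out_w) {
  n_out <- length(b)
  out <- nn_conv_bwd_data(W, x, K_SIZE, 2L, 1L,
                          as.integer(out_h), as.integer(out_w),
                          as.integer(n_out))
  sweep(out, 3, b, "+")
}

tconv_backward <- function(x, gout, W) {
  gx <- nn_conv_fwd(gout, W, numeric(nrow(W)), K_SIZE, 2L, 1L)
  gWb <- nn_conv_bwd(gout, W, x, K_SIZE, 2L, 1L, FALSE)
  gb <- apply(gout, 3, sum)
  list(gx = gx, gW = gWb$gW, gb = gb)
}

# Instance normalization: per-channel standardization over the spatial
# plane, learnable scale/shift.  Stable at batch size 1.
INORM_EPS <- 1e-5

inorm_forward <- function(x, gamma, beta) {
  d <- dim(x)
  n <- d[1] * d[2]
  mu <- apply(x, 3, mean)
  v <- apply(x, 3, function(s) sum((s - mean(s))^2)) / n
  istd <- 1 / sqrt(v + INORM_EPS)
  xhat <- sweep(sweep(x, 3, mu, "-"), 3, istd, "*")
  y <- sweep(sweep(xhat, 3, gamma, "*"), 3, beta, "+")
  list(y = y, xhat = xhat, istd = istd)
}

inorm_backward <- function(cache, gamma, g) {
  d <- dim(g)
  n <- d[1] * d[2]
  xhat <- cache$xhat
  ggamma <- vapply(seq_len(d[3]), function(c) sum(g[, , c] * xhat[, , c]),
                   numeric(1))
  gbeta <- apply(g, 3, sum)
  gx <- g
  for (c in seq_len(d[3])) {
    gc <- g[, , c]
    xh <- xhat[, , c]
    gx[, , c] <- gamma[c] * cache$istd[c] *
      (gc - mean(gc) - xh * mean(gc * xh))
  }
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

lrelu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
lrelu_bwd <- function(x, g, slope = 0.2) ifelse(x > 0, g, slope * g)
relu_bwd <- function(x, g) ifelse(x > 0, g, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

# Adam over arbitrarily nested lists of numeric arrays (the parameter
# trees of the two networks).
adam_init <- function(params) {
  walk <- function(p) {
    if (is.list(p)) lapply(p, walk)
    else list(m = p * 0, v = p * 0)
  }
  list(t = 0L, s = walk(params))
}

adam_step <- function(params, grads, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, s) {
    if (is.list(p) && !all(c("m", "v") %in% names(s))) {
      out <- Map(walk, p, g, s)
      list(p = lapply(out, `[[`, "p"), s = lapply(out, `[[`, "s"))
    } else {
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g^2
      mhat <- s$m / (1 - beta1^t)
      vhat <- s$v / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), s = s)
    }
  }
  out <- walk(params, grads, state$s)
  list(params = out$p, state = list(t = t, s = out$s))
}

# elementwise sum of two same-shaped gradient trees
grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(a)) Map(grad_add, a, b) else a + b
}

grad_scale <- function(a, k) {
  if (is.list(a)) lapply(a, grad_scale, k = k) else a * k
}
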