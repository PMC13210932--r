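# Minimal neural-network primitives with hand-derived backward passes.
#
# Batched 1-D sequence features use a flat (B*T) x C matrix layout with row
# r = (b-1)*T + t, so temporal shifts are row shifts with per-sample
# boundary masking and all heavy lifting is BLAS matrix multiplication.
# Every *_fwd returns the output plus the cache its *_bwd needs; backward
# passes return input gradients and parameter gradients.

# ---- temporal shifts -------------------------------------------------------

# (shift_prev X)[r] = X[r-1], zero at each sample's first frame
shift_prev <- function(X, B, T) {
  Y <- rbind(0, X[-nrow(X), , drop = FALSE])
  Y[(0:(B - 1L)) * T + 1L, ] <- 0
  Y
}

# (shift_next X)[r] = X[r+1], zero at each sample's last frame
shift_next <- function(X, B, T) {
  Y <- rbind(X[-1L, , drop = FALSE], 0)
  Y[(1:B) * T, ] <- 0
  Y
}

# ---- dense -----------------------------------------------------------------

dense_fwd <- function(X, W, b) {
  list(Y = X %*% W + matrix(b, nrow(X), length(b), byrow = TRUE), X = X)
}

dense_bwd <- function(dY, cache, W) {
  list(dX = dY %*% t(W), dW = crossprod(cache$X, dY), db = colSums(dY))
}

# ---- same-padded width-3 temporal convolution ------------------------------

# W is (3*Cin) x Cout with row blocks [prev | current | next]
conv3_fwd <- function(X, W, b, B, T) {
  Xc <- cbind(shift_prev(X, B, T), X, shift_next(X, B, T))
  list(Y = Xc %*% W + matrix(b, nrow(X), length(b), byrow = TRUE), Xc = Xc)
}

conv3_bwd <- function(dY, cache, W, B, T) {
  Cin <- nrow(W) / 3L
  dXc <- dY %*% t(W)
  i1 <- seq_len(Cin); i2 <- Cin + i1; i3 <- 2L * Cin + i1
  # adjoint of shift_prev is shift_next and vice versa
  dX <- shift_next(dXc[, i1, drop = FALSE], B, T) +
    dXc[, i2, drop = FALSE] +
    shift_prev(dXc[, i3, drop = FALSE], B, T)
  list(dX = dX, dW = crossprod(cache$Xc, dY), db = colSums(dY))
}

# ---- resampling ------------------------------------------------------------

# keep odd frames (1, 3, ...) of each sample; T must be even
downsample_rows <- function(B, T) {
  as.vector(outer(seq(1L, T, by = 2L), (0:(B - 1L)) * T, "+"))
}

down_fwd <- function(X, B, T) X[downsample_rows(B, T), , drop = FALSE]

down_bwd <- function(dY, B, T) {
  dX <- matrix(0, B * T, ncol(dY))
  dX[downsample_rows(B, T), ] <- dY
  dX
}

# nearest-neighbour x2 upsampling along time
up_fwd <- function(X, B, T) {
  idx <- rep(seq_len(B * T), each = 2L)
  X[idx, , drop = FALSE]
}

up_bwd <- function(dY, B, T) {
  odd <- seq(1L, 2L * B * T, by = 2L)
  dY[odd, , drop = FALSE] + dY[odd + 1L, , drop = FALSE]
}

# ---- activations -----------------------------------------------------------

silu_fwd <- function(x) {
  s <- 1 / (1 + exp(-x))
  list(Y = x * s, x = x, s = s)
}

silu_bwd <- function(dY, cache) {
  dY * (cache$s * (1 + cache$x * (1 - cache$s)))
}

# exact (erf-based) GELU: x * Phi(x); smooth, so finite-difference gradient
# checks are clean everywhere
gelu_fwd <- function(x) {
  Phi <- stats::pnorm(x)
  list(Y = x * Phi, x = x, Phi = Phi)
}
gelu_bwd <- function(dY, cache) {
  dY * (cache$Phi + cache$x * stats::dnorm(cache$x))
}

# elu(x) + 1: the positive kernel feature map used by linear attention
phi_fwd <- function(x) {
  e <- exp(pmin(x, 0))
  list(Y = ifelse(x > 0, x + 1, e), d = ifelse(x > 0, 1, e))
}

# ---- layer normalization (per row) -----------------------------------------

layernorm_fwd <- function(X, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  Y <- sweep(xhat, 2, gamma, "*")
  Y <- sweep(Y, 2, beta, "+")
  list(Y = Y, xhat = xhat, inv = inv, xc = xc)
}

layernorm_bwd <- function(dY, cache, gamma) {
  C <- ncol(dY)
  dxhat <- sweep(dY, 2, gamma, "*")
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  # dX = inv * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat)) per row
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dX <- cache$inv * (dxhat - m1 - cache$xhat * m2)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# ---- dropout ---------------------------------------------------------------

dropout_fwd <- function(X, p, train) {
  if (!train || p <= 0) return(list(Y = X, mask = NULL))
  mask <- matrix(stats::runif(length(X)) >= p, nrow(X), ncol(X)) / (1 - p)
  list(Y = X * mask, mask = mask)
}

dropout_bwd <- function(dY, cache) {
  if (is.null(cache$mask)) dY else dY * cache$mask
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# ---- parameter initialisation ----------------------------------------------

init_mat <- function(nin, nout, scale = NULL) {
  s <- scale %||% sqrt(2 / nin)
  matrix(stats::rnorm(nin * nout, 0, s), nin, nout)
}

zeros_mat <- function(nin, nout) matrix(0, nin, nout)

# accumulate gradient matrices by name into an environment
acc_grad <- function(env, nm, g) {
  cur <- env$g[[nm]]
  env$g[[nm]] <- if (is.null(cur)) g else cur + g
  invisible(NULL)
}
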