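#' Conditioning configuration for classifier-free training
#'
#' Holds the learnable class-embedding table `E` (`K x d`), the learnable
#' null embedding representing the unconditional branch, and the Bernoulli
#' gate probability `p` with which the *conditional* branch is selected
#' during training (the condition is dropped with probability `1 - p`).
#'
#' @param K number of classes.
#' @param d embedding dimension (even).
#' @param drop_prob gate probability `p` (default 0.5).
#' @param init_sd sd of the Gaussian initialisation of the embeddings.
#' @return object of class `conditioning_config`.
#' @export
conditioning_config <- function(K, d, drop_prob = 0.5, init_sd = 1) {
  if (drop_prob < 0 || drop_prob > 1)
    stop("drop_prob must be in [0, 1]", call. = FALSE)
  structure(
    list(K = as.integer(K), d = as.integer(d), drop_prob = drop_prob,
         class_embeddings = matrix(stats::rnorm(K * d, 0, init_sd), K, d),
         null_embedding = stats::rnorm(d, 0, init_sd)),
    class = "conditioning_config")
}

#' Select the conditional or unconditional embedding
#'
#' Implements the classifier-free gate
#' `emb_c = g * E[c] + (1 - g) * emb_null`: with `g = 1` the class
#' embedding row is used, with `g = 0` the null embedding regardless of `c`.
#' During training `g` is drawn per sample from `Bernoulli(p)`; at sampling
#' time callers request both branches explicitly.
#'
#' @param c class label (1-based) or `NA` when `g = 0`.
#' @param g gate bit (0 or 1).
#' @param cfg a [conditioning_config()].
#' @return length-`d` embedding vector.
#' @export
condition_embedding <- function(c, g, cfg) {
  stopifnot(inherits(cfg, "conditioning_config"), g %in% c(0, 1))
  if (g == 1) {
    if (is.na(c) || c < 1 || c > cfg$K)
      stop(sprintf("class label must be in [1, %d]", cfg$K), call. = FALSE)
    cfg$class_embeddings[c, ]
  } else {
    cfg$null_embedding
  }
}

#' Denoiser network configuration
#'
#' Describes the encoder-decoder U-Net over the time axis used as the noise
#' predictor: `levels` resolution levels with channel widths
#' `base_width * channel_mult`, residual blocks with kernelized linear
#' attention, skip connections from each encoder level to the matching
#' decoder level, and conditioning injected per residual block by adding
#' the projected sum of the sinusoidal step embedding and the (linearly
#' projected) class embedding. Defaults follow the reference configuration
#' (4 levels, base width 64); CPU-scale experiments use smaller settings.
#'
#' @param D input/output channel count.
#' @param Ts segment length; must be divisible by `2^(levels-1)`.
#' @param n_classes number of condition classes `K`.
#' @param base_width base channel dimension (default 64).
#' @param levels number of resolution levels (default 4).
#' @param channel_mult per-level width multipliers (default `2^(0:(levels-1))`).
#' @param emb_dim conditioning embedding dimension (even; default 256).
#' @param attention logical, include linear-attention mixing in each block.
#' @param drop_prob classifier-free gate probability `p`.
#' @return object of class `denoiser_config`.
#' @export
denoiser_config <- function(D, Ts, n_classes, base_width = 64L, levels = 4L,
                            channel_mult = NULL, emb_dim = 256L,
                            attention = TRUE, drop_prob = 0.5) {
  channel_mult <- channel_mult %||% 2^(0:(levels - 1L))
  if (length(channel_mult) != levels)
    stop("channel_mult must have one entry per level", call. = FALSE)
  if (Ts %% 2^(levels - 1L) != 0)
    stop("Ts must be divisible by 2^(levels-1)", call. = FALSE)
  if (emb_dim %% 2 != 0) stop("emb_dim must be even", call. = FALSE)
  structure(
    list(D = as.integer(D), Ts = as.integer(Ts),
         n_classes = as.integer(n_classes),
         widths = as.integer(base_width * channel_mult),
         levels = as.integer(levels), emb_dim = as.integer(emb_dim),
         attention = attention, drop_prob = drop_prob),
    class = "denoiser_config")
}

res_prefixes <- function(cfg) {
  L <- cfg$levels
  list(enc = paste0("e", seq_len(L)), dec = paste0("r", seq_len(L)),
       down = paste0("d", seq_len(max(L - 1L, 0L))),
       up = if (L > 1L) paste0("u", 2:L) else character(0))
}

init_res_params <- function(p, prefix, Cin, Cout, emb) {
  p[[paste0(prefix, "_W1")]] <- init_mat(3L * Cin, Cout, sqrt(2 / (3 * Cin)))
  p[[paste0(prefix, "_b1")]] <- numeric(Cout)
  p[[paste0(prefix, "_cW")]] <- init_mat(emb, Cout, sqrt(1 / emb))
  p[[paste0(prefix, "_cb")]] <- numeric(Cout)
  p[[paste0(prefix, "_W2")]] <- zeros_mat(3L * Cout, Cout)
  p[[paste0(prefix, "_b2")]] <- numeric(Cout)
  if (Cin != Cout)
    p[[paste0(prefix, "_Ws")]] <- init_mat(Cin, Cout, sqrt(1 / Cin))
  p
}

init_attn_params <- function(p, prefix, C) {
  p[[paste0(prefix, "_Wq")]] <- init_mat(C, C, sqrt(1 / C))
  p[[paste0(prefix, "_Wk")]] <- init_mat(C, C, sqrt(1 / C))
  p[[paste0(prefix, "_Wv")]] <- init_mat(C, C, sqrt(1 / C))
  p[[paste0(prefix, "_Wo")]] <- zeros_mat(C, C)
  p[[paste0(prefix, "_bo")]] <- numeric(C)
  p
}

#' Initialise a U-Net denoiser model
#'
#' @param cfg a [denoiser_config()].
#' @param seed RNG seed for the parameter draw.
#' @return object of class `denoiser_unet` with elements `params`
#'   (flat named list of matrices/vectors) and `cfg`.
#' @export
init_denoiser <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "denoiser_config"))
  with_seed(seed, {
    W <- cfg$widths; L <- cfg$levels; emb <- cfg$emb_dim
    p <- list()
    # conditioning: step-embedding MLP, class projection, embedding tables
    p$t_W1 <- init_mat(emb, emb, sqrt(1 / emb)); p$t_b1 <- numeric(emb)
    p$t_W2 <- init_mat(emb, emb, sqrt(1 / emb)); p$t_b2 <- numeric(emb)
    p$c_W <- init_mat(emb, emb, sqrt(1 / emb)); p$c_b <- numeric(emb)
    p$E <- matrix(stats::rnorm(cfg$n_classes * emb), cfg$n_classes, emb)
    p$null <- matrix(stats::rnorm(emb), 1L, emb)
    p$in_W <- init_mat(3L * cfg$D, W[1L], sqrt(2 / (3 * cfg$D)))
    p$in_b <- numeric(W[1L])
    pre <- res_prefixes(cfg)
    for (l in seq_len(L)) {
      Cin <- if (l == 1L) W[1L] else W[l - 1L]
      p <- init_res_params(p, pre$enc[l], Cin, W[l], emb)
      if (cfg$attention) p <- init_attn_params(p, paste0("ea", l), W[l])
      if (l < L) {
        p[[paste0("d", l, "_W")]] <- init_mat(3L * W[l], W[l], sqrt(2 / (3 * W[l])))
        p[[paste0("d", l, "_b")]] <- numeric(W[l])
      }
    }
    p <- init_res_params(p, "bm1", W[L], W[L], emb)
    if (cfg$attention) p <- init_attn_params(p, "ba", W[L])
    p <- init_res_params(p, "bm2", W[L], W[L], emb)
    for (l in L:1L) {
      p <- init_res_params(p, pre$dec[l], 2L * W[l], W[l], emb)
      if (cfg$attention) p <- init_attn_params(p, paste0("ra", l), W[l])
      if (l > 1L) {
        p[[paste0("u", l, "_W")]] <- init_mat(3L * W[l], W[l - 1L], sqrt(2 / (3 * W[l])))
        p[[paste0("u", l, "_b")]] <- numeric(W[l - 1L])
      }
    }
    p$o_W <- zeros_mat(3L * W[1L], cfg$D)
    p$o_b <- numeric(cfg$D)
    structure(list(params = p, cfg = cfg), class = "denoiser_unet")
  })
}

#' @export
print.denoiser_unet <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<denoiser_unet> D = %d, Ts = %d, %d levels (widths %s), %s parameters\n",
              x$cfg$D, x$cfg$Ts, x$cfg$levels,
              paste(x$cfg$widths, collapse = "/"), format(np, big.mark = ",")))
  invisible(x)
}

# ---- composite blocks ------------------------------------------------------

res_fwd <- function(p, prefix, X, cond, B, T) {
  nm <- function(s) p[[paste0(prefix, "_", s)]]
  a1 <- silu_fwd(X)
  c1 <- conv3_fwd(a1$Y, nm("W1"), nm("b1"), B, T)
  cd <- dense_fwd(cond, nm("cW"), nm("cb"))
  h <- c1$Y + cd$Y[rep(seq_len(B), each = T), , drop = FALSE]
  a2 <- silu_fwd(h)
  c2 <- conv3_fwd(a2$Y, nm("W2"), nm("b2"), B, T)
  Ws <- nm("Ws")
  skip <- if (is.null(Ws)) X else X %*% Ws
  list(Y = c2$Y + skip, a1 = a1, c1 = c1, cd = cd, a2 = a2, c2 = c2, X = X)
}

res_bwd <- function(p, prefix, dY, cache, genv, B, T) {
  nm <- function(s) paste0(prefix, "_", s)
  g2 <- conv3_bwd(dY, cache$c2, p[[nm("W2")]], B, T)
  acc_grad(genv, nm("W2"), g2$dW); acc_grad(genv, nm("b2"), g2$db)
  dh <- silu_bwd(g2$dX, cache$a2)
  dcv <- rowsum(dh, rep(seq_len(B), each = T))
  gc <- dense_bwd(dcv, cache$cd, p[[nm("cW")]])
  acc_grad(genv, nm("cW"), gc$dW); acc_grad(genv, nm("cb"), gc$db)
  g1 <- conv3_bwd(dh, cache$c1, p[[nm("W1")]], B, T)
  acc_grad(genv, nm("W1"), g1$dW); acc_grad(genv, nm("b1"), g1$db)
  dX <- silu_bwd(g1$dX, cache$a1)
  Ws <- p[[nm("Ws")]]
  if (is.null(Ws)) {
    dX <- dX + dY
  } else {
    dX <- dX + dY %*% t(Ws)
    acc_grad(genv, nm("Ws"), crossprod(cache$X, dY))
  }
  list(dX = dX, dcond = gc$dX)
}

attn_fwd <- function(p, prefix, X, B, T) {
  nm <- function(s) p[[paste0(prefix, "_", s)]]
  Wq <- nm("Wq"); Wk <- nm("Wk"); Wv <- nm("Wv"); Wo <- nm("Wo"); bo <- nm("bo")
  C <- ncol(X)
  O <- matrix(0, nrow(X), C)
  per <- vector("list", B)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * T + 1L):(b * T)
    Xb <- X[rows, , drop = FALSE]
    Q <- Xb %*% Wq; K <- Xb %*% Wk; V <- Xb %*% Wv
    P <- phi_fwd(Q); G <- phi_fwd(K)
    S <- crossprod(G$Y, V)              # C x C
    sk <- colSums(G$Y)
    N <- P$Y %*% S
    den <- drop(P$Y %*% sk)
    Ob <- N / den
    O[rows, ] <- Ob
    per[[b]] <- list(Xb = Xb, P = P, G = G, S = S, sk = sk, N = N,
                     den = den, V = V, Ob = Ob)
  }
  proj <- dense_fwd(O, Wo, bo)
  list(Y = X + proj$Y, O = O, per = per, proj = proj)
}

attn_bwd <- function(p, prefix, dY, cache, genv, B, T) {
  nm <- function(s) paste0(prefix, "_", s)
  Wq <- p[[nm("Wq")]]; Wk <- p[[nm("Wk")]]; Wv <- p[[nm("Wv")]]
  gp <- dense_bwd(dY, cache$proj, p[[nm("Wo")]])
  acc_grad(genv, nm("Wo"), gp$dW); acc_grad(genv, nm("bo"), gp$db)
  dO <- gp$dX
  dX <- dY                                # residual path
  dWq <- 0; dWk <- 0; dWv <- 0
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * T + 1L):(b * T)
    cb <- cache$per[[b]]
    dOb <- dO[rows, , drop = FALSE]
    dN <- dOb / cb$den
    dden <- -rowSums(dOb * cb$N) / cb$den^2
    dP <- dN %*% t(cb$S) + outer(dden, cb$sk)
    dS <- crossprod(cb$P$Y, dN)
    dsk <- drop(crossprod(cb$P$Y, dden))
    dG <- cb$V %*% t(dS) + matrix(dsk, T, length(dsk), byrow = TRUE)
    dV <- cb$G$Y %*% dS
    dQ <- dP * cb$P$d
    dK <- dG * cb$G$d
    dWq <- dWq + crossprod(cb$Xb, dQ)
    dWk <- dWk + crossprod(cb$Xb, dK)
    dWv <- dWv + crossprod(cb$Xb, dV)
    dX[rows, ] <- dX[rows, ] + dQ %*% t(Wq) + dK %*% t(Wk) + dV %*% t(Wv)
  }
  acc_grad(genv, nm("Wq"), dWq)
  acc_grad(genv, nm("Wk"), dWk)
  acc_grad(genv, nm("Wv"), dWv)
  dX
}

cond_fwd <- function(p, cfg, t_vec, labels, B) {
  se <- time_embedding(t_vec, cfg$emb_dim)
  if (is.null(dim(se))) se <- matrix(se, 1L)
  d1 <- dense_fwd(se, p$t_W1, p$t_b1)
  a1 <- silu_fwd(d1$Y)
  d2 <- dense_fwd(a1$Y, p$t_W2, p$t_b2)
  embc <- matrix(0, B, cfg$emb_dim)
  for (i in seq_len(B))
    embc[i, ] <- if (is.na(labels[i])) p$null else p$E[labels[i], ]
  dc <- dense_fwd(embc, p$c_W, p$c_b)
  list(Y = d2$Y + dc$Y, d1 = d1, a1 = a1, d2 = d2, dc = dc,
       labels = labels, embc = embc)
}

cond_bwd <- function(p, cfg, dcond, cache, genv) {
  g2 <- dense_bwd(dcond, cache$d2, p$t_W2)
  acc_grad(genv, "t_W2", g2$dW); acc_grad(genv, "t_b2", g2$db)
  da1 <- silu_bwd(g2$dX, cache$a1)
  g1 <- dense_bwd(da1, cache$d1, p$t_W1)
  acc_grad(genv, "t_W1", g1$dW); acc_grad(genv, "t_b1", g1$db)
  gc <- dense_bwd(dcond, cache$dc, p$c_W)
  acc_grad(genv, "c_W", gc$dW); acc_grad(genv, "c_b", gc$db)
  dE <- matrix(0, nrow(p$E), ncol(p$E))
  dnull <- matrix(0, 1L, ncol(p$E))
  for (i in seq_along(cache$labels)) {
    if (is.na(cache$labels[i])) dnull <- dnull + gc$dX[i, ]
    else dE[cache$labels[i], ] <- dE[cache$labels[i], ] + gc$dX[i, ]
  }
  acc_grad(genv, "E", dE)
  acc_grad(genv, "null", dnull)
  invisible(NULL)
}

denoiser_forward <- function(model, X, t_vec, labels, B) {
  cfg <- model$cfg; p <- model$params
  T0 <- nrow(X) / B
  if (length(t_vec) == 1L) t_vec <- rep(t_vec, B)
  if (length(labels) == 1L) labels <- rep(labels, B)
  cond <- cond_fwd(p, cfg, t_vec, labels, B)
  cache <- list(cond = cond)
  cin <- conv3_fwd(X, p$in_W, p$in_b, B, T0)
  cache$cin <- cin
  x <- cin$Y; Tc <- T0
  L <- cfg$levels
  skips <- vector("list", L)
  enc <- vector("list", L)
  for (l in seq_len(L)) {
    rc <- res_fwd(p, paste0("e", l), x, cond$Y, B, Tc)
    x <- rc$Y
    ac <- NULL
    if (cfg$attention) { ac <- attn_fwd(p, paste0("ea", l), x, B, Tc); x <- ac$Y }
    skips[[l]] <- x
    dcv <- NULL
    if (l < L) {
      dcv <- conv3_fwd(x, p[[paste0("d", l, "_W")]], p[[paste0("d", l, "_b")]], B, Tc)
      x <- down_fwd(dcv$Y, B, Tc)
      Tc <- Tc / 2L
    }
    enc[[l]] <- list(res = rc, attn = ac, down = dcv)
  }
  b1 <- res_fwd(p, "bm1", x, cond$Y, B, Tc); x <- b1$Y
  batt <- NULL
  if (cfg$attention) { batt <- attn_fwd(p, "ba", x, B, Tc); x <- batt$Y }
  b2 <- res_fwd(p, "bm2", x, cond$Y, B, Tc); x <- b2$Y
  cache$enc <- enc; cache$b1 <- b1; cache$batt <- batt; cache$b2 <- b2
  dec <- vector("list", L)
  for (l in L:1L) {
    xc <- cbind(x, skips[[l]])
    rc <- res_fwd(p, paste0("r", l), xc, cond$Y, B, Tc)
    x <- rc$Y
    ac <- NULL
    if (cfg$attention) { ac <- attn_fwd(p, paste0("ra", l), x, B, Tc); x <- ac$Y }
    uc <- NULL
    if (l > 1L) {
      xu <- up_fwd(x, B, Tc)
      Tc <- Tc * 2L
      uc <- conv3_fwd(xu, p[[paste0("u", l, "_W")]], p[[paste0("u", l, "_b")]], B, Tc)
      x <- uc$Y
    }
    dec[[l]] <- list(res = rc, attn = ac, up = uc)
  }
  cache$dec <- dec
  ao <- silu_fwd(x)
  co <- conv3_fwd(ao$Y, p$o_W, p$o_b, B, Tc)
  cache$ao <- ao; cache$co <- co
  cache$B <- B; cache$T0 <- T0
  list(Y = co$Y, cache = cache)
}

denoiser_backward <- function(model, dY, cache) {
  cfg <- model$cfg; p <- model$params
  B <- cache$B; T0 <- cache$T0; L <- cfg$levels
  genv <- new.env(); genv$g <- list()
  dcond <- 0
  go <- conv3_bwd(dY, cache$co, p$o_W, B, T0)
  acc_grad(genv, "o_W", go$dW); acc_grad(genv, "o_b", go$db)
  dx <- silu_bwd(go$dX, cache$ao)
  Tc <- T0
  dskips <- vector("list", L)
  for (l in 1:L) {
    dc <- cache$dec[[l]]
    if (l > 1L) {
      gu <- conv3_bwd(dx, dc$up, p[[paste0("u", l, "_W")]], B, Tc)
      acc_grad(genv, paste0("u", l, "_W"), gu$dW)
      acc_grad(genv, paste0("u", l, "_b"), gu$db)
      Tc <- Tc / 2L
      dx <- up_bwd(gu$dX, B, Tc)
    }
    if (cfg$attention)
      dx <- attn_bwd(p, paste0("ra", l), dx, dc$attn, genv, B, Tc)
    gr <- res_bwd(p, paste0("r", l), dx, dc$res, genv, B, Tc)
    dcond <- dcond + gr$dcond
    W <- cfg$widths[l]
    dx <- gr$dX[, seq_len(W), drop = FALSE]
    dskips[[l]] <- gr$dX[, W + seq_len(W), drop = FALSE]
  }
  # bottleneck (dx is at the coarsest resolution, Tc == T0 / 2^(L-1))
  gb2 <- res_bwd(p, "bm2", dx, cache$b2, genv, B, Tc)
  dcond <- dcond + gb2$dcond
  dx <- gb2$dX
  if (cfg$attention) dx <- attn_bwd(p, "ba", dx, cache$batt, genv, B, Tc)
  gb1 <- res_bwd(p, "bm1", dx, cache$b1, genv, B, Tc)
  dcond <- dcond + gb1$dcond
  dx <- gb1$dX
  for (l in L:1L) {
    ec <- cache$enc[[l]]
    if (l < L) {
      Tc <- Tc * 2L
      dful <- down_bwd(dx, B, Tc)
      gd <- conv3_bwd(dful, ec$down, p[[paste0("d", l, "_W")]], B, Tc)
      acc_grad(genv, paste0("d", l, "_W"), gd$dW)
      acc_grad(genv, paste0("d", l, "_b"), gd$db)
      dx <- gd$dX
    }
    dx <- dx + dskips[[l]]
    if (cfg$attention)
      dx <- attn_bwd(p, paste0("ea", l), dx, ec$attn, genv, B, Tc)
    ge <- res_bwd(p, paste0("e", l), dx, ec$res, genv, B, Tc)
    dcond <- dcond + ge$dcond
    dx <- ge$dX
  }
  gi <- conv3_bwd(dx, cache$cin, p$in_W, B, T0)
  acc_grad(genv, "in_W", gi$dW); acc_grad(genv, "in_b", gi$db)
  cond_bwd(p, cfg, dcond, cache$cond, genv)
  genv$g
}

#' Predict the noise component for a batch of noisy samples
#'
#' Generic denoiser interface shared by the trained U-Net and injectable
#' analytic/stub denoisers (used to test the sampler independently of
#' training).
#'
#' @param model a `denoiser_unet` or `denoiser_fn` object.
#' @param X `(B*Ts) x D` matrix of noisy samples (row `r = (b-1)*Ts + t`).
#' @param t diffusion step (scalar or length-`B`).
#' @param labels length-`B` class labels, or `NA` for the unconditional
#'   branch (scalar recycled).
#' @param B batch size.
#' @return `(B*Ts) x D` matrix of predicted noise.
#' @export
predict_noise <- function(model, X, t, labels, B) UseMethod("predict_noise")

#' @export
predict_noise.denoiser_unet <- function(model, X, t, labels, B) {
  denoiser_forward(model, X, t, labels, B)$Y
}

#' @export
predict_noise.denoiser_fn <- function(model, X, t, labels, B) {
  model$fn(X, t, labels, B)
}

#' Wrap a plain function as a denoiser
#'
#' @param fn `function(X, t, labels, B)` returning a matrix shaped like `X`.
#' @return object of class `denoiser_fn`.
#' @export
denoiser_fn <- function(fn) structure(list(fn = fn), class = "denoiser_fn")

#' One training step of the conditional diffusion model
#'
#' Per sample: draw the step `t` uniformly from `{1, ..., T}`, Gaussian
#' noise `eps`, and the classifier-free gate `g ~ Bernoulli(p)` (draws are
#' consumed in that order from the current RNG stream, or can be injected
#' for testing); form the noisy sample by the closed-form forward marginal;
#' and return the mean-squared error between the injected and predicted
#' noise together with parameter gradients (gradients are `NULL` for
#' non-trainable stub denoisers).
#'
#' @param model denoiser (`denoiser_unet` or stub).
#' @param X0 `(B*Ts) x D` matrix of clean samples in signed-unit space.
#' @param labels length-`B` class labels.
#' @param schedule a [build_schedule()] object.
#' @param B batch size.
#' @param drop_prob gate probability `p` (probability the class condition is
#'   *kept*, per the gate definition in [condition_embedding()]).
#' @param draws optional list `(t, eps, g)` overriding the random draws.
#' @return list with `loss`, `grads`.
#' @export
diffusion_training_step <- function(model, X0, labels, schedule, B,
                                    drop_prob = 0.5, draws = NULL) {
  if (max(abs(X0)) > 1 + 1e-9)
    stop("training batch must be in signed-unit space ([-1, 1])", call. = FALSE)
  Ts <- nrow(X0) / B
  t_vec <- draws$t %||% sample.int(schedule$T, B, replace = TRUE)
  eps <- draws$eps %||% matrix(stats::rnorm(length(X0)), nrow(X0), ncol(X0))
  g <- draws$g %||% stats::rbinom(B, 1L, drop_prob)
  ab <- schedule$alpha_bar[t_vec][rep(seq_len(B), each = Ts)]
  Xt <- sqrt(ab) * X0 + sqrt(1 - ab) * eps
  lab_in <- ifelse(g == 1L, labels, NA_integer_)
  if (inherits(model, "denoiser_unet")) {
    fw <- denoiser_forward(model, Xt, t_vec, lab_in, B)
    resid <- fw$Y - eps
    loss <- mean(resid^2)
    grads <- denoiser_backward(model, 2 * resid / length(resid), fw$cache)
    list(loss = loss, grads = grads)
  } else {
    Yh <- predict_noise(model, Xt, t_vec, lab_in, B)
    list(loss = mean((Yh - eps)^2), grads = NULL)
  }
}

#' Train the conditional diffusion model
#'
#' Adam optimisation of the noise-prediction objective on a set of
#' signed-unit segments. A single seeded generator drives minibatch
#' selection and the per-step `(t, eps, g)` draws, so runs are reproducible.
#'
#' @param segments list of `signed_unit` segments (see
#'   [normalize_segment()]).
#' @param schedule a [build_schedule()] object.
#' @param cfg a [denoiser_config()]; its `D`/`Ts` must match the segments.
#' @param iterations number of optimisation steps.
#' @param batch_size minibatch size (sampled with replacement).
#' @param lr Adam learning rate (reference setting 1e-4; CPU-scale presets
#'   may use a larger rate, see the package vignette).
#' @param seed RNG seed.
#' @param verbose print the running loss every `print_every` steps.
#' @param print_every integer.
#' @return a `denoiser_unet` with an added `history` element (loss per
#'   step).
#' @export
train_diffusion <- function(segments, schedule, cfg, iterations = 1000L,
                            batch_size = 16L, lr = 1e-4, seed = 1L,
                            verbose = FALSE, print_every = 200L) {
  stopifnot(length(segments) > 0L)
  Ts <- nrow(segments[[1L]]$values)
  D <- ncol(segments[[1L]]$values)
  if (Ts != cfg$Ts || D != cfg$D)
    stop("segment shape does not match denoiser config", call. = FALSE)
  stopifnot(all(vapply(segments, function(s) s$space == "signed_unit",
                       logical(1))))
  labels_all <- vapply(segments, function(s) s$class_label, integer(1))
  model <- init_denoiser(cfg, seed = derive_seed(seed, 1L))
  with_seed(derive_seed(seed, 2L), {
    opt <- adam_init(model$params)
    history <- numeric(iterations)
    for (it in seq_len(iterations)) {
      idx <- sample.int(length(segments), batch_size, replace = TRUE)
      X0 <- do.call(rbind, lapply(segments[idx], function(s) s$values))
      st <- diffusion_training_step(model, X0, labels_all[idx], schedule,
                                    batch_size, drop_prob = cfg$drop_prob)
      upd <- adam_step(model$params, st$grads, opt, lr = lr)
      model$params <- upd$params; opt <- upd$state
      history[it] <- st$loss
      if (verbose && it %% print_every == 0L)
        message(sprintf("iter %d: loss %.4f (mean last %d: %.4f)", it,
                        st$loss, print_every,
                        mean(history[(it - print_every + 1L):it])))
    }
    model$history <- history
    model
  })
}
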