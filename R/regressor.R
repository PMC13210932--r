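#' Partition a segment into sensors, moments and weight
#'
#' Splits the frozen column layout `[Ds sensors | hip moment | knee moment |
#' body weight]`: columns `1..Ds` are the multimodal sensor sequence, the
#' next two the joint-moment sequence, and the temporal mean of the last
#' column the body-weight scalar.
#'
#' @param segment physical-space segment.
#' @param Ds expected sensor dimension; defaults to `D - 3`. If given and
#'   `D != Ds + 3` an error is raised.
#' @return list with `sensors` (`Ts x Ds`), `moments` (`Ts x 2`), `weight`
#'   (scalar).
#' @export
split_segment <- function(segment, Ds = NULL) {
  D <- ncol(segment$values)
  Ds <- Ds %||% (D - 3L)
  if (D != Ds + 3L)
    stop(sprintf("segment has D = %d columns; expected Ds + 3 = %d",
                 D, Ds + 3L), call. = FALSE)
  list(sensors = segment$values[, seq_len(Ds), drop = FALSE],
       moments = segment$values[, Ds + 1:2, drop = FALSE],
       weight = mean(segment$values[, D]))
}

#' Crop an aligned sensor/target window
#'
#' Extracts a length-`Tc` sub-window from frame-aligned sensors and
#' targets. In `"random"` mode (training-time augmentation) the 0-based
#' start offset is uniform on `{0, ..., Ts - Tc}`; in `"center"` mode
#' (deterministic evaluation) it is `floor((Ts - Tc)/2)`.
#'
#' @param sensors `Ts x Ds` matrix.
#' @param targets `Ts x 2` matrix.
#' @param Tc crop length (`<= Ts`).
#' @param mode `"random"` or `"center"`.
#' @return list with cropped `sensors`, `targets`, and the 0-based `start`.
#' @export
crop_window <- function(sensors, targets, Tc, mode = c("random", "center")) {
  mode <- match.arg(mode)
  Ts <- nrow(sensors)
  stopifnot(nrow(targets) == Ts)
  if (Tc > Ts) stop("Tc must be <= Ts", call. = FALSE)
  start <- if (mode == "random") sample.int(Ts - Tc + 1L, 1L) - 1L
  else (Ts - Tc) %/% 2L
  rows <- (start + 1L):(start + Tc)
  list(sensors = sensors[rows, , drop = FALSE],
       targets = targets[rows, , drop = FALSE], start = start)
}

#' Transformer regressor configuration
#'
#' A post-norm Transformer encoder mapping a z-scored `Tc x Ds` sensor
#' window to a `Tc x 2` joint-moment sequence: linear projection `Ds -> C`,
#' additive sinusoidal positional encoding over the frame index, `L`
#' encoder layers (multi-head self-attention, residual, layer norm; then
#' feedforward, residual, layer norm — normalization *after* each residual
#' sum), and a per-frame linear head `C -> 2`. Defaults follow the
#' reference setting (`C = 128`, `L = 3`, 4 heads, dropout 0.1).
#'
#' @param Ds sensor input width.
#' @param Tc window length.
#' @param C latent width (divisible by `heads`, even).
#' @param L number of encoder layers.
#' @param heads attention heads.
#' @param ffn_mult hidden width of the feedforward sublayer as a multiple
#'   of `C`.
#' @param dropout dropout rate applied after the attention and feedforward
#'   sublayers (training only).
#' @return object of class `momentformer_config`.
#' @export
momentformer_config <- function(Ds, Tc, C = 128L, L = 3L, heads = 4L,
                                ffn_mult = 4L, dropout = 0.1) {
  if (C %% heads != 0) stop("C must be divisible by heads", call. = FALSE)
  if (C %% 2 != 0) stop("C must be even", call. = FALSE)
  if (L < 1) stop("L must be >= 1", call. = FALSE)
  structure(list(Ds = as.integer(Ds), Tc = as.integer(Tc), C = as.integer(C),
                 L = as.integer(L), heads = as.integer(heads),
                 ffn = as.integer(ffn_mult * C), dropout = dropout),
            class = "momentformer_config")
}

#' Initialise a Transformer regressor
#' @param cfg a [momentformer_config()].
#' @param seed RNG seed.
#' @return object of class `momentformer` with `params` and `cfg`.
#' @export
init_momentformer <- function(cfg, seed = 1L) {
  with_seed(seed, {
    C <- cfg$C; Fw <- cfg$ffn
    p <- list(in_W = init_mat(cfg$Ds, C, sqrt(1 / cfg$Ds)), in_b = numeric(C))
    for (l in seq_len(cfg$L)) {
      pre <- paste0("l", l, "_")
      for (w in c("Wq", "Wk", "Wv", "Wo"))
        p[[paste0(pre, w)]] <- init_mat(C, C, sqrt(1 / C))
      for (b in c("bq", "bk", "bv", "bo"))
        p[[paste0(pre, b)]] <- numeric(C)
      p[[paste0(pre, "ln1_g")]] <- rep(1, C)
      p[[paste0(pre, "ln1_b")]] <- numeric(C)
      p[[paste0(pre, "f_W1")]] <- init_mat(C, Fw, sqrt(2 / C))
      p[[paste0(pre, "f_b1")]] <- numeric(Fw)
      p[[paste0(pre, "f_W2")]] <- init_mat(Fw, C, sqrt(1 / Fw))
      p[[paste0(pre, "f_b2")]] <- numeric(C)
      p[[paste0(pre, "ln2_g")]] <- rep(1, C)
      p[[paste0(pre, "ln2_b")]] <- numeric(C)
    }
    p$head_W <- init_mat(C, 2L, sqrt(1 / C))
    p$head_b <- numeric(2L)
    structure(list(params = p, cfg = cfg), class = "momentformer")
  })
}

#' @export
print.momentformer <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<momentformer> Ds = %d, Tc = %d, C = %d, L = %d, %d heads, %s parameters\n",
              x$cfg$Ds, x$cfg$Tc, x$cfg$C, x$cfg$L, x$cfg$heads,
              format(np, big.mark = ",")))
  invisible(x)
}

mha_fwd <- function(p, pre, Z, B, T, heads) {
  C <- ncol(Z); dh <- C %/% heads
  q <- dense_fwd(Z, p[[paste0(pre, "Wq")]], p[[paste0(pre, "bq")]])
  k <- dense_fwd(Z, p[[paste0(pre, "Wk")]], p[[paste0(pre, "bk")]])
  v <- dense_fwd(Z, p[[paste0(pre, "Wv")]], p[[paste0(pre, "bv")]])
  O <- matrix(0, nrow(Z), C)
  A_all <- vector("list", B)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * T + 1L):(b * T)
    Ab <- vector("list", heads)
    for (h in seq_len(heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      Qh <- q$Y[rows, cols, drop = FALSE]
      Kh <- k$Y[rows, cols, drop = FALSE]
      S <- tcrossprod(Qh, Kh) / sqrt(dh)
      S <- S - apply(S, 1, max)[row(S)]     # row-wise stabilisation
      A <- exp(S); A <- A / rowSums(A)
      O[rows, cols] <- A %*% v$Y[rows, cols, drop = FALSE]
      Ab[[h]] <- A
    }
    A_all[[b]] <- Ab
  }
  o <- dense_fwd(O, p[[paste0(pre, "Wo")]], p[[paste0(pre, "bo")]])
  list(Y = o$Y, q = q, k = k, v = v, O = O, A = A_all, o = o)
}

mha_bwd <- function(p, pre, dY, cache, genv, B, T, heads) {
  C <- ncol(dY); dh <- C %/% heads
  go <- dense_bwd(dY, cache$o, p[[paste0(pre, "Wo")]])
  acc_grad(genv, paste0(pre, "Wo"), go$dW)
  acc_grad(genv, paste0(pre, "bo"), go$db)
  dO <- go$dX
  dQ <- matrix(0, nrow(dY), C); dK <- dQ; dV <- dQ
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * T + 1L):(b * T)
    for (h in seq_len(heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      A <- cache$A[[b]][[h]]
      Vh <- cache$v$Y[rows, cols, drop = FALSE]
      dOh <- dO[rows, cols, drop = FALSE]
      dA <- tcrossprod(dOh, Vh)
      dV[rows, cols] <- crossprod(A, dOh)
      dS <- A * (dA - rowSums(dA * A))
      Qh <- cache$q$Y[rows, cols, drop = FALSE]
      Kh <- cache$k$Y[rows, cols, drop = FALSE]
      dQ[rows, cols] <- dS %*% Kh / sqrt(dh)
      dK[rows, cols] <- crossprod(dS, Qh) / sqrt(dh)
    }
  }
  gq <- dense_bwd(dQ, cache$q, p[[paste0(pre, "Wq")]])
  gk <- dense_bwd(dK, cache$k, p[[paste0(pre, "Wk")]])
  gv <- dense_bwd(dV, cache$v, p[[paste0(pre, "Wv")]])
  acc_grad(genv, paste0(pre, "Wq"), gq$dW); acc_grad(genv, paste0(pre, "bq"), gq$db)
  acc_grad(genv, paste0(pre, "Wk"), gk$dW); acc_grad(genv, paste0(pre, "bk"), gk$db)
  acc_grad(genv, paste0(pre, "Wv"), gv$dW); acc_grad(genv, paste0(pre, "bv"), gv$db)
  gq$dX + gk$dX + gv$dX
}

momentformer_forward <- function(model, Xs, B, train = FALSE) {
  cfg <- model$cfg; p <- model$params
  T <- nrow(Xs) / B
  din <- dense_fwd(Xs, p$in_W, p$in_b)
  pe <- time_embedding(0:(T - 1L), cfg$C)
  Z <- din$Y + pe[rep(seq_len(T), B), , drop = FALSE]
  layers <- vector("list", cfg$L)
  for (l in seq_len(cfg$L)) {
    pre <- paste0("l", l, "_")
    at <- mha_fwd(p, pre, Z, B, T, cfg$heads)
    dr1 <- dropout_fwd(at$Y, cfg$dropout, train)
    ln1 <- layernorm_fwd(Z + dr1$Y, p[[paste0(pre, "ln1_g")]],
                         p[[paste0(pre, "ln1_b")]])
    f1 <- dense_fwd(ln1$Y, p[[paste0(pre, "f_W1")]], p[[paste0(pre, "f_b1")]])
    rl <- gelu_fwd(f1$Y)
    f2 <- dense_fwd(rl$Y, p[[paste0(pre, "f_W2")]], p[[paste0(pre, "f_b2")]])
    dr2 <- dropout_fwd(f2$Y, cfg$dropout, train)
    ln2 <- layernorm_fwd(ln1$Y + dr2$Y, p[[paste0(pre, "ln2_g")]],
                         p[[paste0(pre, "ln2_b")]])
    layers[[l]] <- list(at = at, dr1 = dr1, ln1 = ln1, f1 = f1, rl = rl,
                        f2 = f2, dr2 = dr2, ln2 = ln2)
    Z <- ln2$Y
  }
  hd <- dense_fwd(Z, p$head_W, p$head_b)
  list(Y = hd$Y, cache = list(din = din, layers = layers, hd = hd,
                              B = B, T = T))
}

momentformer_backward <- function(model, dY, cache) {
  cfg <- model$cfg; p <- model$params
  B <- cache$B; T <- cache$T
  genv <- new.env(); genv$g <- list()
  gh <- dense_bwd(dY, cache$hd, p$head_W)
  acc_grad(genv, "head_W", gh$dW); acc_grad(genv, "head_b", gh$db)
  dZ <- gh$dX
  for (l in cfg$L:1L) {
    pre <- paste0("l", l, "_")
    lc <- cache$layers[[l]]
    g2 <- layernorm_bwd(dZ, lc$ln2, p[[paste0(pre, "ln2_g")]])
    acc_grad(genv, paste0(pre, "ln2_g"), g2$dgamma)
    acc_grad(genv, paste0(pre, "ln2_b"), g2$dbeta)
    dres2 <- g2$dX
    dfr <- dropout_bwd(dres2, lc$dr2)
    gf2 <- dense_bwd(dfr, lc$f2, p[[paste0(pre, "f_W2")]])
    acc_grad(genv, paste0(pre, "f_W2"), gf2$dW)
    acc_grad(genv, paste0(pre, "f_b2"), gf2$db)
    drl <- gelu_bwd(gf2$dX, lc$rl)
    gf1 <- dense_bwd(drl, lc$f1, p[[paste0(pre, "f_W1")]])
    acc_grad(genv, paste0(pre, "f_W1"), gf1$dW)
    acc_grad(genv, paste0(pre, "f_b1"), gf1$db)
    dln1 <- dres2 + gf1$dX
    g1 <- layernorm_bwd(dln1, lc$ln1, p[[paste0(pre, "ln1_g")]])
    acc_grad(genv, paste0(pre, "ln1_g"), g1$dgamma)
    acc_grad(genv, paste0(pre, "ln1_b"), g1$dbeta)
    dres1 <- g1$dX
    dat <- dropout_bwd(dres1, lc$dr1)
    dZ <- dres1 + mha_bwd(p, pre, dat, lc$at, genv, B, T, cfg$heads)
  }
  gi <- dense_bwd(dZ, cache$din, p$in_W)
  acc_grad(genv, "in_W", gi$dW); acc_grad(genv, "in_b", gi$db)
  genv$g
}

#' Predict joint moments for z-scored sensor windows
#'
#' @param model a trained `momentformer`.
#' @param sensors `Tc x Ds` matrix (or `(B*Tc) x Ds` stacked batch) of
#'   z-scored sensors.
#' @param B batch size (default 1).
#' @return `Tc x 2` (or `(B*Tc) x 2`) predicted hip/knee moment matrix.
#'   Deterministic (dropout disabled).
#' @export
predict_moments <- function(model, sensors, B = 1L) {
  if (ncol(sensors) != model$cfg$Ds)
    stop(sprintf("input width %d does not match model Ds = %d",
                 ncol(sensors), model$cfg$Ds), call. = FALSE)
  Y <- momentformer_forward(model, sensors, B, train = FALSE)$Y
  colnames(Y) <- moment_channel_names()
  Y
}

#' One training step of the moment regressor
#'
#' Computes the windowed regression loss
#' \eqn{L = \frac{1}{T_c}\sum_{i=1}^{T_c} \lVert m_i - m_i^* \rVert_2^2}
#' averaged over the batch (equal to twice the elementwise mean squared
#' error over a `Tc x 2` block) and its parameter gradients.
#'
#' @param model a `momentformer`.
#' @param sensors `(B*Tc) x Ds` stacked z-scored sensors.
#' @param targets `(B*Tc) x 2` stacked moment targets.
#' @param B batch size.
#' @param train logical; enables dropout.
#' @return list with `loss` and `grads`.
#' @export
regression_training_step <- function(model, sensors, targets, B,
                                     train = TRUE) {
  if (!identical(dim(sensors)[1], dim(targets)[1]))
    stop("sensors and targets must be frame-aligned", call. = FALSE)
  fw <- momentformer_forward(model, sensors, B, train = train)
  resid <- fw$Y - targets
  Tc <- nrow(sensors) / B
  loss <- sum(resid^2) / (B * Tc)
  grads <- momentformer_backward(model, 2 * resid / (B * Tc), fw$cache)
  list(loss = loss, grads = grads)
}

segments_to_samples <- function(segments, stats, Tc, mode) {
  lapply(segments, function(sg) {
    parts <- split_segment(sg)
    s <- zscore_sensors(sg, stats)
    cw <- crop_window(s, parts$moments, Tc, mode)
    list(sensors = cw$sensors, targets = cw$targets,
         class_label = sg$class_label, provenance = sg$provenance)
  })
}

#' Train the Transformer moment regressor
#'
#' Epoch-based Adam training with weight decay, one random crop per segment
#' per epoch, reduce-on-plateau learning-rate decay and early stopping (all
#' monitored on a held-out validation split of the training segments, or on
#' the training loss if `val_fraction = 0`). Synthetic segments pass
#' through the same z-score statistics fitted on real data.
#'
#' @param segments list of physical-space segments (real and/or synthetic).
#' @param stats `norm_stats` with a fitted z-score slot (real data only).
#' @param cfg a [momentformer_config()].
#' @param epochs maximum number of epochs.
#' @param batch_size minibatch size.
#' @param lr initial Adam learning rate.
#' @param weight_decay L2 weight decay coefficient.
#' @param lr_patience,lr_factor reduce-on-plateau schedule.
#' @param early_stop_patience epochs without improvement before stopping.
#' @param val_fraction fraction of segments held out for monitoring.
#' @param seed RNG seed (controls split, crops, batching, dropout).
#' @return a `momentformer` with `history` (per-epoch monitored loss).
#' @export
train_regressor <- function(segments, stats, cfg, epochs = 100L,
                            batch_size = 16L, lr = 1e-4,
                            weight_decay = 1e-5, lr_patience = 10L,
                            lr_factor = 0.9, early_stop_patience = 50L,
                            val_fraction = 0, seed = 1L) {
  stopifnot(length(segments) > 0L)
  model <- init_momentformer(cfg, seed = derive_seed(seed, 1L))
  with_seed(derive_seed(seed, 2L), {
    n <- length(segments)
    n_val <- floor(val_fraction * n)
    vidx <- if (n_val > 0) sample.int(n, n_val) else integer(0)
    tr <- if (n_val > 0) segments[-vidx] else segments
    va <- if (n_val > 0) segments[vidx] else NULL
    opt <- adam_init(model$params)
    best <- Inf; best_params <- model$params
    bad_lr <- 0L; bad_stop <- 0L
    history <- numeric(0)
    for (ep in seq_len(epochs)) {
      samples <- segments_to_samples(tr, stats, cfg$Tc, "random")
      ord <- sample.int(length(samples))
      ep_loss <- 0; nb <- 0L
      for (i0 in seq(1L, length(ord), by = batch_size)) {
        idx <- ord[i0:min(i0 + batch_size - 1L, length(ord))]
        B <- length(idx)
        Xs <- do.call(rbind, lapply(samples[idx], `[[`, "sensors"))
        Yt <- do.call(rbind, lapply(samples[idx], `[[`, "targets"))
        st <- regression_training_step(model, Xs, Yt, B, train = TRUE)
        upd <- adam_step(model$params, st$grads, opt, lr = lr,
                         weight_decay = weight_decay)
        model$params <- upd$params; opt <- upd$state
        ep_loss <- ep_loss + st$loss; nb <- nb + 1L
      }
      mon <- if (!is.null(va)) {
        vs <- segments_to_samples(va, stats, cfg$Tc, "center")
        Xs <- do.call(rbind, lapply(vs, `[[`, "sensors"))
        Yt <- do.call(rbind, lapply(vs, `[[`, "targets"))
        resid <- momentformer_forward(model, Xs, length(vs))$Y - Yt
        sum(resid^2) / (length(vs) * cfg$Tc)
      } else ep_loss / nb
      history <- c(history, mon)
      if (mon < best - 1e-12) {
        best <- mon; best_params <- model$params
        bad_lr <- 0L; bad_stop <- 0L
      } else {
        bad_lr <- bad_lr + 1L; bad_stop <- bad_stop + 1L
        if (bad_lr >= lr_patience) { lr <- lr * lr_factor; bad_lr <- 0L }
        if (bad_stop >= early_stop_patience) break
      }
    }
    model$params <- best_params
    model$history <- history
    model
  })
}

#' Evaluate a regressor on segments with deterministic center crops
#'
#' @param model a `momentformer`.
#' @param segments physical-space evaluation segments.
#' @param stats fitted `norm_stats` (real training data).
#' @return list with pooled `predictions` and `truths` (`n x 2` matrices)
#'   and the per-frame `class` labels.
#' @export
evaluate_regressor <- function(model, segments, stats) {
  samples <- segments_to_samples(segments, stats, model$cfg$Tc, "center")
  Xs <- do.call(rbind, lapply(samples, `[[`, "sensors"))
  pred <- predict_moments(model, Xs, B = length(samples))
  truth <- do.call(rbind, lapply(samples, `[[`, "targets"))
  cls <- rep(vapply(samples, `[[`, integer(1), "class_label"),
             each = model$cfg$Tc)
  list(predictions = pred, truths = truth, class = cls)
}
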