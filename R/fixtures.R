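#' Configuration for the toy multimodal fixture generator
#'
#' Describes a synthetic dataset with the statistical structure the method
#' assumes: `K` activity classes with distinct per-channel offsets/scales,
#' class-specific temporal patterns (cyclic sinusoids, smoothed
#' impedance-like step transitions, low-pass-filtered unstructured random
#' walks), cross-channel coupling (channels share an underlying latent
#' pattern; the joint-moment channels are a fixed, documented linear + lagged
#' function of the two encoder channels), and class imbalance (default
#' largest:smallest sequence ratio 5:1, mirroring the before-augmentation
#' regime of the motivating dataset).
#'
#' The per-frame moment model is
#' \deqn{hip(t)   = b_h + w_{hh}\,hip\_angle(t) + w_{hk}\,knee\_angle(t-lag) + \epsilon}
#' \deqn{knee(t)  = b_k + w_{kk}\,knee\_angle(t) + w_{kh}\,hip\_angle(t-lag) + \epsilon}
#' with \eqn{\epsilon \sim N(0, noise\_sd^2)}, so a regressor has known
#' signal to recover and a known noise floor (`noise_sd` per moment channel).
#'
#' @param K number of classes (>= 2); classes are, in order, cyclic,
#'   impedance-like, unstructured (patterns cycle for K > 3).
#' @param n_sequences_per_class integer vector of length `K`.
#' @param length_range `(min, max)` sequence length in frames.
#' @param Ds number of sensor channels (last one is the insole
#'   vertical-force channel, proportional to body weight).
#' @param noise_sd per-channel additive Gaussian noise sd.
#' @param seed integer RNG seed; generation is deterministic given it.
#' @param weight_range body-weight sampling range (one draw per sequence).
#' @return object of class `fixture_config` (includes the resolved
#'   `class_params` offset/amplitude tables and `moment_params`).
#' @export
fixture_config <- function(K = 3L,
                           n_sequences_per_class = c(15L, 6L, 3L),
                           length_range = c(320L, 448L),
                           Ds = 6L,
                           noise_sd = 0.05,
                           seed = 1L,
                           weight_range = c(55, 90)) {
  if (K < 2) stop("K must be >= 2", call. = FALSE)
  if (length(n_sequences_per_class) != K)
    stop("n_sequences_per_class must have length K", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (Ds < 3) stop("Ds must be >= 3", call. = FALSE)
  patterns <- rep(c("cyclic", "impedance", "unstructured"), length.out = K)
  base_off <- c(2, 4, -1.5, 0.5, -3)[((seq_len(K) - 1L) %% 5L) + 1L]
  base_amp <- c(1.0, 0.8, 1.2, 0.9, 1.1)[((seq_len(K) - 1L) %% 5L) + 1L]
  class_params <- lapply(seq_len(K), function(c) {
    j <- seq_len(Ds)
    list(pattern = patterns[c],
         # distinct, deterministic per-class per-channel offsets and scales
         offset = base_off[c] + 0.8 * sin(j + c),
         amp = base_amp[c] * (0.6 + 0.4 * ((j %% 3L) / 2)),
         freq = 1.5 + 0.5 * c,          # cycles per 100 frames (cyclic)
         dwell = 60L, ramp = 8,         # impedance step geometry
         ar = 0.95,                     # unstructured AR(1) coefficient
         insole_base = 0.7, insole_scale = 0.2)
  })
  structure(
    list(K = as.integer(K),
         n_sequences_per_class = as.integer(n_sequences_per_class),
         length_range = as.integer(length_range), Ds = as.integer(Ds),
         noise_sd = noise_sd, seed = as.integer(seed),
         weight_range = weight_range, class_params = class_params,
         moment_params = list(lag = 5L,
                              hip = c(b = 0.5, w_same = 0.8, w_cross = -0.5),
                              knee = c(b = -0.3, w_same = 0.9, w_cross = -0.4))),
    class = "fixture_config")
}

#' Joint-moment generating function of the fixtures
#'
#' The documented deterministic map from the two encoder channels to the hip
#' and knee moment channels (before additive noise). Exposed so tests and
#' noise-floor calculations can evaluate it independently of the generator.
#'
#' @param hip_angle,knee_angle length-T numeric vectors.
#' @param params the `moment_params` element of a [fixture_config()].
#' @return `T x 2` matrix (hip, knee moments).
#' @export
fixture_moment_function <- function(hip_angle, knee_angle, params) {
  lag <- params$lag
  lagged <- function(x) x[pmax(seq_along(x) - lag, 1L)]
  hip <- params$hip[["b"]] + params$hip[["w_same"]] * hip_angle +
    params$hip[["w_cross"]] * lagged(knee_angle)
  knee <- params$knee[["b"]] + params$knee[["w_same"]] * knee_angle +
    params$knee[["w_cross"]] * lagged(hip_angle)
  cbind(hip_moment = hip, knee_moment = knee)
}

# shared standardized latent pattern per class; mean ~0, sd ~1 by design
fixture_pattern <- function(kind, len, p) {
  t <- seq_len(len)
  switch(kind,
    cyclic = {
      phi <- stats::runif(1, 0, 2 * pi)
      # per-channel phase offsets added later; return base phase + freq
      list(type = "cyclic", phi = phi,
           base = sin(2 * pi * p$freq * t / 100 + phi))
    },
    impedance = {
      n_lev <- max(2L, ceiling(len / p$dwell))
      levels <- stats::rnorm(n_lev)
      centers <- seq(1, len, length.out = n_lev)
      z <- rep(levels[1L], len)
      for (k in 2:n_lev) {     # sigmoid ramps between consecutive levels
        w <- stats::plogis((t - centers[k]) / p$ramp)
        z <- z + (levels[k] - levels[k - 1L]) * w
      }
      list(type = "impedance", base = z)
    },
    unstructured = {
      a <- p$ar
      innov_sd <- sqrt(1 - a^2)        # stationary sd 1
      z <- numeric(len)
      z[1L] <- stats::rnorm(1)
      if (len > 1L)
        for (i in 2:len) z[i] <- a * z[i - 1L] + stats::rnorm(1, 0, innov_sd)
      list(type = "unstructured", base = z)
    },
    stop("unknown pattern kind"))
}

fixture_channels <- function(pat, len, p, Ds, noise_sd) {
  t <- seq_len(len)
  X <- matrix(0, len, Ds)
  for (j in seq_len(Ds)) {
    pj <- switch(pat$type,
      cyclic = sin(2 * pi * p$freq * t / 100 + pat$phi + (j - 1L) * pi / 4) *
        sqrt(2),                               # rescale: sd 1 like the others
      impedance = ((-1)^j) * pat$base,
      unstructured = {
        zj <- numeric(len); zj[1L] <- stats::rnorm(1)
        a <- p$ar
        if (len > 1L)
          for (i in 2:len) zj[i] <- a * zj[i - 1L] + stats::rnorm(1, 0, sqrt(1 - a^2))
        0.8 * pat$base + 0.6 * zj             # coupled + private component
      })
    X[, j] <- p$offset[j] + p$amp[j] * pj +
      if (noise_sd > 0) stats::rnorm(len, 0, noise_sd) else 0
  }
  X
}

#' Generate a toy multimodal motion dataset
#'
#' Draws `sum(n_sequences_per_class)` variable-length sequences with the
#' class-conditional structure described in [fixture_config()]. The insole
#' vertical-force channel is `weight * (insole_base + insole_scale *
#' pattern)` plus noise; the moment channels apply
#' [fixture_moment_function()] to the *realized* (noisy) encoder channels
#' plus independent noise, so at `noise_sd = 0` they equal the documented
#' function exactly. Deterministic given `config$seed`.
#'
#' @param config a [fixture_config()].
#' @return list of [motion_sequence()] objects.
#' @export
generate_toy_dataset <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  with_seed(config$seed, {
    out <- list()
    Ds <- config$Ds
    cn <- c(sensor_channel_names(Ds), moment_channel_names())
    for (c in seq_len(config$K)) {
      p <- config$class_params[[c]]
      for (i in seq_len(config$n_sequences_per_class[c])) {
        len <- sample(config$length_range[1L]:config$length_range[2L], 1L)
        w <- stats::runif(1, config$weight_range[1L], config$weight_range[2L])
        pat <- fixture_pattern(p$pattern, len, p)
        X <- fixture_channels(pat, len, p, Ds, config$noise_sd)
        # insole vertical force is weight-proportional
        fi <- insole_force_index(sensor_channel_names(Ds))
        drv <- (X[, fi] - p$offset[fi]) / p$amp[fi]  # standardized pattern
        X[, fi] <- w * (p$insole_base + p$insole_scale * drv) +
          if (config$noise_sd > 0) stats::rnorm(len, 0, config$noise_sd) else 0
        M <- fixture_moment_function(X[, 1L], X[, 2L], config$moment_params)
        if (config$noise_sd > 0)
          M <- M + matrix(stats::rnorm(2 * len, 0, config$noise_sd), len, 2)
        fr <- cbind(X, M)
        colnames(fr) <- cn
        out[[length(out) + 1L]] <- motion_sequence(
          fr, c, w, subject_id = sprintf("c%d_s%02d", c, i))
      }
    }
    out
  })
}

#' Per-class, per-channel mean and standard deviation
#'
#' Frame-pooled mean and sd for every (class, channel) pair — the statistic
#' used for real-vs-synthetic distribution comparison. The sd uses the
#' population (1/N) convention to match the fitted z-score statistics.
#'
#' @param dataset non-empty list of [motion_sequence()] objects, or a list
#'   of `segment` objects.
#' @return `data.frame` with columns `class`, `channel`, `mean`, `sd`,
#'   `n_frames`.
#' @export
class_summary <- function(dataset) {
  if (length(dataset) == 0L) stop("empty dataset", call. = FALSE)
  get_mat <- function(x) if (inherits(x, "segment")) x$values else x$frames
  labels <- vapply(dataset, function(x) x$class_label, integer(1))
  res <- list()
  for (c in sort(unique(labels))) {
    m <- do.call(rbind, lapply(dataset[labels == c], get_mat))
    mu <- colMeans(m)
    sd_pop <- sqrt(colMeans(sweep(m, 2, mu, "-")^2))
    res[[length(res) + 1L]] <- data.frame(
      class = c, channel = colnames(m) %||% paste0("ch", seq_along(mu)),
      mean = unname(mu), sd = unname(sd_pop), n_frames = nrow(m))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Closed-form expectations of the fixture generator
#'
#' Expected frame-pooled channel means (all classes) and sds (where a closed
#' form exists: cyclic and unstructured sensor channels) implied by a
#' [fixture_config()]. Used to validate the generator against Monte-Carlo
#' estimates.
#'
#' @param config a [fixture_config()].
#' @return `data.frame` with columns `class`, `channel`, `mean`, `sd`
#'   (`NA` where no simple closed form applies).
#' @export
class_summary_targets <- function(config) {
  Ds <- config$Ds
  cn <- c(sensor_channel_names(Ds), moment_channel_names())
  fi <- insole_force_index(sensor_channel_names(Ds))
  ew <- mean(config$weight_range)
  res <- list()
  for (c in seq_len(config$K)) {
    p <- config$class_params[[c]]
    mu <- p$offset
    sdv <- rep(NA_real_, Ds)
    if (p$pattern == "cyclic")
      sdv <- sqrt(p$amp^2 + config$noise_sd^2)   # sin * sqrt(2) has sd 1
    if (p$pattern == "unstructured")
      sdv <- sqrt(p$amp^2 + config$noise_sd^2)
    mu[fi] <- ew * p$insole_base
    sdv[fi] <- NA_real_                           # weight variance dominates
    mp <- config$moment_params
    mh <- mp$hip[["b"]] + mp$hip[["w_same"]] * mu[1L] +
      mp$hip[["w_cross"]] * mu[2L]
    mk <- mp$knee[["b"]] + mp$knee[["w_same"]] * mu[2L] +
      mp$knee[["w_cross"]] * mu[1L]
    res[[length(res) + 1L]] <- data.frame(
      class = c, channel = cn, mean = c(mu, mh, mk),
      sd = c(sdv, NA_real_, NA_real_))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
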