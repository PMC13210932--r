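#' Classifier-free guidance settings
#'
#' @param s guidance scale (>= 0): 0 gives the unconditional prediction, 1
#'   the purely conditional one, larger values amplify the class condition.
#'   Default 3, the reference setting.
#' @param clip_range interval to which the clean-sample estimate is clipped
#'   at every reverse step.
#' @param seed optional RNG seed for sampling.
#' @return object of class `guidance_settings`.
#' @export
guidance_settings <- function(s = 3, clip_range = c(-1, 1), seed = NULL) {
  if (s < 0) stop("guidance scale s must be >= 0", call. = FALSE)
  structure(list(s = s, clip_range = clip_range, seed = seed),
            class = "guidance_settings")
}

#' Combine conditional and unconditional noise predictions
#'
#' The guided noise estimate
#' \eqn{\hat\epsilon_t = \epsilon_u + s(\epsilon_c - \epsilon_u)}: the
#' unconditional prediction plus `s` times the guidance term (the
#' conditional-minus-unconditional difference).
#'
#' @param eps_cond,eps_uncond same-shape noise predictions.
#' @param s guidance scale.
#' @return guided estimate, same shape.
#' @export
guided_noise_estimate <- function(eps_cond, eps_uncond, s) {
  if (!identical(dim(eps_cond), dim(eps_uncond)))
    stop("conditional and unconditional predictions must have the same shape",
         call. = FALSE)
  # short-circuit the limits so the s = 0 / s = 1 identities are bitwise
  if (s == 0) return(eps_uncond)
  if (s == 1) return(eps_cond)
  eps_uncond + s * (eps_cond - eps_uncond)
}

#' Estimate the clean sample from a noisy sample and a noise estimate
#'
#' Inverts the forward marginal:
#' \eqn{\hat x_0 = (x_t - \sqrt{1-\bar\alpha_t}\,\hat\epsilon_t)/\sqrt{\bar\alpha_t}},
#' then clips elementwise to `clip_range` for sampling stability.
#'
#' @param x_t noisy sample at step `t`.
#' @param eps_hat guided noise estimate, same shape.
#' @param t diffusion step.
#' @param schedule a [build_schedule()] object.
#' @param clip_range clipping interval (`NULL` to skip clipping).
#' @return clean-sample estimate, same shape as `x_t`.
#' @export
estimate_clean <- function(x_t, eps_hat, t, schedule, clip_range = c(-1, 1)) {
  t <- check_step(t, schedule)
  ab <- schedule$alpha_bar[t]
  x0 <- (x_t - sqrt(1 - ab) * eps_hat) / sqrt(ab)
  if (!is.null(clip_range)) x0 <- pmin(pmax(x0, clip_range[1]), clip_range[2])
  x0
}

#' Reverse-posterior mean and variance
#'
#' Parameters of \eqn{q(x_{t-1} \mid x_t, \hat x_0)}:
#' \deqn{\mu_t = \frac{\sqrt{\bar\alpha_{t-1}}\beta_t}{1-\bar\alpha_t}\hat x_0
#'   + \frac{\sqrt{\alpha_t}(1-\bar\alpha_{t-1})}{1-\bar\alpha_t} x_t,\qquad
#'   \sigma_t^2 = \frac{1-\bar\alpha_{t-1}}{1-\bar\alpha_t}\beta_t}
#' with the convention \eqn{\bar\alpha_0 = 1}, under which the step
#' \eqn{t = 1} collapses to \eqn{\mu_1 = \hat x_0}, \eqn{\sigma_1^2 = 0}.
#'
#' @param x0_hat clipped clean-sample estimate.
#' @param x_t current noisy sample, same shape.
#' @param t diffusion step.
#' @param schedule a [build_schedule()] object.
#' @return list with `mu` (same shape) and `sigma2` (scalar).
#' @export
posterior_params <- function(x0_hat, x_t, t, schedule) {
  t <- check_step(t, schedule)
  ab <- schedule$alpha_bar[t]
  abp <- alpha_bar_prev(t, schedule)
  beta <- schedule$beta[t]
  alpha <- schedule$alpha[t]
  c0 <- sqrt(abp) * beta / (1 - ab)
  ct <- sqrt(alpha) * (1 - abp) / (1 - ab)
  list(mu = c0 * x0_hat + ct * x_t,
       sigma2 = (1 - abp) / (1 - ab) * beta)
}

#' Ancestral sampling with classifier-free guidance
#'
#' Generates class-conditioned segments by initialising
#' \eqn{x_T \sim N(0, I)} and iterating from `t = T` down to 1. At each
#' step the denoiser is queried twice (class branch and unconditional
#' branch), the guided noise estimate, clipped clean estimate and reverse
#' posterior are formed in order, and
#' \eqn{x_{t-1} = \mu_t + \sigma_t z} with a fresh Gaussian `z` — except at
#' the final step, where `z = 0` and the posterior mean is returned.
#' Intermediate samples are not clipped; only the clean estimate is.
#' Deterministic given the seed.
#'
#' @param model a denoiser ([predict_noise()] interface).
#' @param schedule a [build_schedule()] object.
#' @param class_label class to condition on (1-based).
#' @param settings a [guidance_settings()].
#' @param shape `c(Ts, D)` of each generated segment.
#' @param n number of segments to generate in one batch.
#' @param seed RNG seed (overrides `settings$seed` if given).
#' @param channel_names optional column names for the generated segments.
#' @return list of `n` `segment` objects in `signed_unit` space with
#'   provenance `"synthetic"`.
#' @export
reverse_sample <- function(model, schedule, class_label, settings,
                           shape, n = 1L, seed = NULL, channel_names = NULL) {
  stopifnot(inherits(settings, "guidance_settings"))
  if (inherits(model, "denoiser_unet") &&
      (is.na(class_label) || class_label < 1 ||
       class_label > model$cfg$n_classes))
    stop("invalid class label for this model", call. = FALSE)
  Ts <- shape[1L]; D <- shape[2L]
  seed <- seed %||% settings$seed
  with_seed(seed, {
    X <- matrix(stats::rnorm(n * Ts * D), n * Ts, D)
    for (t in schedule$T:1L) {
      eps_c <- predict_noise(model, X, t, rep(class_label, n), n)
      eps_u <- predict_noise(model, X, t, rep(NA_integer_, n), n)
      eps_hat <- guided_noise_estimate(eps_c, eps_u, settings$s)
      x0h <- estimate_clean(X, eps_hat, t, schedule, settings$clip_range)
      pp <- posterior_params(x0h, X, t, schedule)
      X <- if (t > 1L)
        pp$mu + sqrt(pp$sigma2) * matrix(stats::rnorm(length(X)), nrow(X), D)
      else pp$mu
    }
    if (!is.null(channel_names)) colnames(X) <- channel_names
    lapply(seq_len(n), function(i) {
      new_segment(X[((i - 1L) * Ts + 1L):(i * Ts), , drop = FALSE],
                  class_label, space = "signed_unit",
                  provenance = "synthetic",
                  subject_id = sprintf("synthetic_c%d_%d", class_label, i))
    })
  })
}

#' Bayes-optimal denoiser for Gaussian scalar data
#'
#' For data \eqn{x_0 \sim N(\mu_0, \sigma_0^2)} the posterior-mean clean
#' estimate given \eqn{x_t} is available in closed form, and the optimal
#' noise predictor is
#' \eqn{\epsilon^*(x_t, t) = (x_t - \sqrt{\bar\alpha_t}\,m(x_t))/\sqrt{1-\bar\alpha_t}}
#' with
#' \eqn{m(x_t) = (\sigma_0^2\sqrt{\bar\alpha_t}\,x_t + (1-\bar\alpha_t)\mu_0)/(\bar\alpha_t\sigma_0^2 + 1-\bar\alpha_t)}.
#' Used as an analytic oracle to test the sampler independently of network
#' training: with it, ancestral sampling is exact up to the fixed-variance
#' approximation of the reverse kernel.
#'
#' `mu0`/`sigma0` may be length-`K` vectors (per-class data means); the
#' unconditional branch (label `NA`) uses `mu0_uncond`/`sigma0_uncond`
#' (defaults: moment-matched to the class mixture with equal weights).
#'
#' @param mu0,sigma0 data mean(s) and sd(s).
#' @param schedule a [build_schedule()] object.
#' @param mu0_uncond,sigma0_uncond unconditional-branch moments.
#' @return a `denoiser_fn`.
#' @export
oracle_gaussian_denoiser <- function(mu0, sigma0, schedule,
                                     mu0_uncond = NULL, sigma0_uncond = NULL) {
  K <- length(mu0)
  if (length(sigma0) == 1L) sigma0 <- rep(sigma0, K)
  mu0_uncond <- mu0_uncond %||% mean(mu0)
  sigma0_uncond <- sigma0_uncond %||%
    sqrt(mean(sigma0^2) + mean((mu0 - mean(mu0))^2))
  denoiser_fn(function(X, t, labels, B) {
    Ts <- nrow(X) / B
    if (length(t) == 1L) t <- rep(t, B)
    if (length(labels) == 1L) labels <- rep(labels, B)
    ab <- schedule$alpha_bar[t][rep(seq_len(B), each = Ts)]
    mu <- ifelse(is.na(labels), mu0_uncond, mu0[ifelse(is.na(labels), 1L, labels)])
    sg <- ifelse(is.na(labels), sigma0_uncond, sigma0[ifelse(is.na(labels), 1L, labels)])
    mu <- mu[rep(seq_len(B), each = Ts)]
    v0 <- (sg^2)[rep(seq_len(B), each = Ts)]
    m <- (v0 * sqrt(ab) * X + (1 - ab) * mu) / (ab * v0 + 1 - ab)
    (X - sqrt(ab) * m) / sqrt(1 - ab)
  })
}
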