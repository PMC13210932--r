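#' Build a linear variance (noise) schedule for the diffusion process
#'
#' Constructs the per-step noise variances \eqn{\beta_t} of the forward
#' diffusion chain, linearly spaced between `beta_start` and `beta_end`
#' (inclusive), together with the derived signal-retention coefficients
#' \eqn{\alpha_t = 1 - \beta_t} and their running products
#' \eqn{\bar\alpha_t = \prod_{s \le t} \alpha_s}. The convention
#' \eqn{\bar\alpha_0 = 1} is stored explicitly so that the reverse-posterior
#' coefficients are defined at the final denoising step.
#'
#' The default (`T = 1000`, `beta` from `1e-4` to `0.02`) is the standard
#' linear schedule for denoising diffusion probabilistic models and drives
#' the terminal signal level below 1\% (`alpha_bar[T] < 0.01`), so the
#' terminal state is close to a standard Gaussian. When using a much shorter
#' chain (for CPU-scale experiments), raise `beta_end` so this property is
#' preserved; see [reduced_schedule()].
#'
#' @param T_steps number of diffusion steps (\eqn{T \ge 1}).
#' @param beta_start,beta_end endpoints of the linear beta schedule;
#'   `0 < beta_start <= beta_end < 1`.
#' @return An object of class `diffusion_schedule`: a list with elements
#'   `T`, `beta`, `alpha`, `alpha_bar` (all length `T`, 1-based in `t`) and
#'   `alpha_bar0 = 1`.
#' @examples
#' sch <- build_schedule(10)
#' sch$alpha_bar[10]
#' @export
build_schedule <- function(T_steps = 1000L, beta_start = 1e-4, beta_end = 0.02) {
  if (length(T_steps) != 1L || !is.finite(T_steps) || T_steps < 1 ||
      T_steps != round(T_steps))
    stop("T_steps must be a positive integer", call. = FALSE)
  if (!(beta_start > 0 && beta_start <= beta_end && beta_end < 1))
    stop("require 0 < beta_start <= beta_end < 1", call. = FALSE)
  T_steps <- as.integer(T_steps)
  beta <- if (T_steps == 1L) beta_start else
    seq(beta_start, beta_end, length.out = T_steps)
  alpha <- 1 - beta
  structure(
    list(T = T_steps, beta = beta, alpha = alpha,
         alpha_bar = cumprod(alpha), alpha_bar0 = 1),
    class = "diffusion_schedule"
  )
}

#' @export
print.diffusion_schedule <- function(x, ...) {
  cat(sprintf(
    "<diffusion_schedule> T = %d, beta in [%g, %g], alpha_bar_T = %.4g\n",
    x$T, x$beta[1], x$beta[x$T], x$alpha_bar[x$T]))
  invisible(x)
}

#' Short diffusion schedule with a near-Gaussian terminal state
#'
#' Convenience constructor for CPU-scale chains: chooses `beta_end` so that
#' the cumulative signal coefficient at the last step stays below
#' `target_alpha_bar_T`, matching the terminal behaviour of the full
#' 1000-step schedule with far fewer steps.
#'
#' @param T_steps number of steps.
#' @param target_alpha_bar_T upper bound for `alpha_bar[T]` (default 0.01).
#' @return a `diffusion_schedule`.
#' @export
reduced_schedule <- function(T_steps, target_alpha_bar_T = 0.01) {
  # sum(beta) ~ -log(alpha_bar_T); linear schedule => sum = T*(b0+b1)/2
  b0 <- 1e-4
  b1 <- min(0.999, 2 * (-log(target_alpha_bar_T) * 1.08) / T_steps - b0)
  b1 <- max(b1, b0)
  sch <- build_schedule(T_steps, b0, b1)
  # the log-linear estimate is approximate for large beta; nudge up if needed
  while (sch$alpha_bar[sch$T] >= target_alpha_bar_T && b1 < 0.95) {
    b1 <- min(0.95, b1 * 1.15)
    sch <- build_schedule(T_steps, b0, b1)
  }
  sch
}

check_step <- function(t, schedule) {
  if (any(t < 1 | t > schedule$T | t != round(t)))
    stop(sprintf("diffusion step t must be an integer in [1, %d]", schedule$T),
         call. = FALSE)
  as.integer(t)
}

# alpha_bar_{t-1} with the alpha_bar_0 = 1 convention; vectorised over t.
alpha_bar_prev <- function(t, schedule) {
  ifelse(t == 1L, schedule$alpha_bar0, schedule$alpha_bar[pmax(t - 1L, 1L)])
}

#' Forward diffusion: construct the noisy sample at step t
#'
#' Applies the closed-form forward marginal
#' \eqn{x_t = \sqrt{\bar\alpha_t}\,x_0 + \sqrt{1-\bar\alpha_t}\,\epsilon}
#' to a clean sample in the signed-unit space. No clipping is applied.
#'
#' @param x0 numeric vector/matrix/array, the clean sample (values expected
#'   in \[-1, 1\] for model training, though the formula itself is exact for
#'   any input).
#' @param t diffusion step, either a scalar or (for batched arrays whose
#'   first dimension indexes samples) a vector of length `dim(x0)[1]`.
#' @param eps Gaussian noise draw with the same shape as `x0`.
#' @param schedule a [build_schedule()] object.
#' @return noisy sample of the same shape as `x0`.
#' @export
forward_noise <- function(x0, t, eps, schedule) {
  t <- check_step(t, schedule)
  if (!identical(dim(x0) %||% length(x0), dim(eps) %||% length(eps)))
    stop("x0 and eps must have identical shape", call. = FALSE)
  ab <- schedule$alpha_bar[t]
  if (length(t) == 1L) {
    sqrt(ab) * x0 + sqrt(1 - ab) * eps
  } else {
    # per-row steps: x0 is a matrix with one sample per row
    if (is.null(dim(x0)) || nrow(x0) != length(t))
      stop("vector t requires one row of x0 per step", call. = FALSE)
    sqrt(ab) * x0 + sqrt(1 - ab) * eps
  }
}

#' Sinusoidal embedding of a diffusion step (or frame position)
#'
#' One-dimensional sinusoidal positional encoding:
#' entry \eqn{2k} is \eqn{\sin(t w_k)} and entry \eqn{2k+1} is
#' \eqn{\cos(t w_k)} (0-based entries) with
#' \eqn{w_k = 1/10000^{2k/d}}.
#'
#' @param t non-negative scalar or vector of steps/positions.
#' @param d even embedding dimension.
#' @return if `t` is scalar, a length-`d` vector; otherwise a
#'   `length(t) x d` matrix.
#' @examples
#' time_embedding(0, 4)   # c(0, 1, 0, 1)
#' @export
time_embedding <- function(t, d) {
  if (length(d) != 1L || d < 2 || d %% 2 != 0)
    stop("embedding dimension d must be a positive even integer", call. = FALSE)
  k <- 0:(d / 2 - 1)
  w <- 1 / 10000^(2 * k / d)
  ang <- outer(t, w)                       # |t| x d/2
  out <- matrix(0, length(t), d)
  out[, 2 * k + 1] <- sin(ang)
  out[, 2 * k + 2] <- cos(ang)
  if (length(t) == 1L) drop(out) else out
}
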