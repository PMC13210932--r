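#' Plan the per-class synthetic sample allocation
#'
#' The augmentation ratio `rho` is the ratio of *total* synthetic samples to
#' *total* real samples. The synthetic budget `round(rho * sum(real))` is
#' split equally across classes (floor, with the remainder going to the
#' largest classes first), so every class gains the same increment and the
#' imbalance ratio (largest-to-smallest class count) strictly decreases
#' whenever `rho > 0` and the real counts are unequal. A `per_class` mode
#' instead generates `round(rho * n_c)` per class (proportional, preserving
#' imbalance) for comparison.
#'
#' @param real_counts_per_class non-negative integer vector (at least one
#'   positive).
#' @param rho augmentation ratio (>= 0; default 2).
#' @param mode `"equal"` (default) or `"per_class"`.
#' @return object of class `augmentation_plan` with `rho`, `real_counts`,
#'   `synthetic_counts`, `after_counts`, `percent_before`, `percent_after`,
#'   `imbalance_before`, `imbalance_after`.
#' @examples
#' plan_allocation(c(1729000, 420000, 344000), rho = 2)
#' @export
plan_allocation <- function(real_counts_per_class, rho = 2,
                            mode = c("equal", "per_class")) {
  mode <- match.arg(mode)
  n <- real_counts_per_class
  if (any(n < 0) || all(n == 0))
    stop("real counts must be non-negative with at least one positive",
         call. = FALSE)
  if (rho < 0) stop("rho must be >= 0", call. = FALSE)
  K <- length(n)
  if (mode == "equal") {
    total_syn <- round(rho * sum(n))
    base <- total_syn %/% K
    rem <- total_syn %% K
    syn <- rep(base, K)
    if (rem > 0) {
      take <- order(n, decreasing = TRUE)[seq_len(rem)]
      syn[take] <- syn[take] + 1
    }
  } else {
    syn <- round(rho * n)
  }
  after <- n + syn
  imb <- function(x) {
    pos <- x[x > 0]
    if (length(pos) == 0L) NA_real_ else max(pos) / min(pos)
  }
  structure(
    list(rho = rho, mode = mode, real_counts = n, synthetic_counts = syn,
         after_counts = after,
         percent_before = 100 * n / sum(n),
         percent_after = 100 * after / sum(after),
         imbalance_before = imb(n), imbalance_after = imb(after)),
    class = "augmentation_plan")
}

#' @export
print.augmentation_plan <- function(x, ...) {
  cat(sprintf("<augmentation_plan> rho = %g (%s split)\n", x$rho, x$mode))
  tab <- rbind(before = x$real_counts, synthetic = x$synthetic_counts,
               after = x$after_counts)
  colnames(tab) <- paste0("class", seq_along(x$real_counts))
  print(tab)
  cat(sprintf("imbalance ratio: %.2f:1 -> %.2f:1\n",
              x$imbalance_before, x$imbalance_after))
  invisible(x)
}

#' Build the augmented training set
#'
#' Generates the planned per-class synthetic counts with guided ancestral
#' sampling, maps each synthetic segment back to physical units with its
#' own class's min-max statistics, replaces the (slightly time-varying)
#' generated weight column by its temporal mean, tags provenance, and
#' concatenates with the real segments. Z-score statistics for the
#' regressor must still be fitted on the real segments only.
#'
#' @param real_segments list of physical-space real segments.
#' @param model a trained (or stub) denoiser.
#' @param schedule a [build_schedule()] object.
#' @param plan an [plan_allocation()] object (length-`K` counts).
#' @param stats fitted [fit_minmax_stats()] on the real training set.
#' @param settings a [guidance_settings()].
#' @param seed RNG seed (one derived sub-seed per class/batch).
#' @param batch_size generation batch size.
#' @return list of physical-space segments, real first then synthetic, each
#'   provenance-tagged.
#' @export
build_augmented_dataset <- function(real_segments, model, schedule, plan,
                                    stats, settings, seed = 1L,
                                    batch_size = 64L) {
  stopifnot(inherits(plan, "augmentation_plan"),
            inherits(stats, "norm_stats"))
  K <- length(plan$synthetic_counts)
  if (K > nrow(stats$min))
    stop("plan has more classes than fitted statistics", call. = FALSE)
  Ts <- nrow(real_segments[[1L]]$values)
  D <- ncol(real_segments[[1L]]$values)
  out <- real_segments
  for (c in seq_len(K)) {
    need <- plan$synthetic_counts[c]
    batch_i <- 0L
    while (need > 0L) {
      nb <- min(need, batch_size)
      batch_i <- batch_i + 1L
      segs <- reverse_sample(model, schedule, c, settings, c(Ts, D), n = nb,
                             seed = derive_seed(seed, c * 1000L + batch_i),
                             channel_names = stats$channel_names)
      for (sg in segs) {
        ph <- denormalize_segment(sg, stats)
        ph$values[, D] <- mean(ph$values[, D])   # constant weight column
        out[[length(out) + 1L]] <- ph
      }
      need <- need - nb
    }
  }
  out
}
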