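#' CPU-scale study of diffusion augmentation on toy fixtures
#'
#' Runs the full pipeline at a size suited to a single CPU: seeded toy
#' fixtures (3 classes with ~5:1 imbalance, 6 sensor channels, 64-frame
#' segments), a short-chain conditional diffusion model, guided generation
#' of a rho = 2 augmented set, a distribution-matching comparison of real
#' vs synthetic per-class channel means (for each class, the channels with
#' the largest-magnitude real means — "dominant channels" — are compared by
#' relative error), and a ratio sweep training the Transformer regressor at
#' each `rho` for several seeds with held-out evaluation. See the package
#' vignette for the rationale behind every size choice.
#'
#' @param seed master seed; all sub-seeds derive from it.
#' @param Ts segment length (frames).
#' @param Tc regressor crop length.
#' @param rho_values augmentation ratios for the sweep (must include 0).
#' @param reg_seeds regressor training seeds.
#' @param diffusion_iterations diffusion Adam steps.
#' @param diffusion_batch,diffusion_lr diffusion minibatch size and Adam
#'   learning rate (CPU-scale preset; see the vignette).
#' @param T_steps diffusion chain length (short chain with matched terminal
#'   noise level).
#' @param epochs regressor training epochs per run.
#' @param n_dominant dominant channels per class in the distribution check.
#' @param verbose print progress.
#' @return list with `dominant` (per-class dominant-channel real/synthetic
#'   means and relative errors), `summary_real`/`summary_synthetic`
#'   (full [class_summary()] tables), `sweep` (ratio-sweep metric rows),
#'   `minority_class`, `minority_rmse` (per rho x seed, hip/knee average
#'   for the minority class), and `diffusion_loss` (first/last training
#'   loss).
#' @export
toy_experiment <- function(seed = 1L, Ts = 64L, Tc = 48L,
                           rho_values = c(0, 2), reg_seeds = 1:5,
                           diffusion_iterations = 5000L, T_steps = 80L,
                           diffusion_batch = 32L, diffusion_lr = 1.5e-3,
                           epochs = 30L, n_dominant = 2L, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  fix_train <- fixture_config(seed = derive_seed(seed, 11L))
  fix_test <- fixture_config(n_sequences_per_class = c(4L, 4L, 4L),
                             seed = derive_seed(seed, 12L))
  train_segs <- segment_sequences(generate_toy_dataset(fix_train), Ts = Ts)
  test_segs <- segment_sequences(generate_toy_dataset(fix_test), Ts = Ts)
  stats <- fit_minmax_stats(train_segs)
  stats <- fit_zscore_stats(train_segs, stats)
  norm <- lapply(train_segs, normalize_segment, stats = stats)
  D <- ncol(train_segs[[1L]]$values)
  counts <- tabulate(vapply(train_segs, function(s) s$class_label,
                            integer(1)), nbins = fix_train$K)
  say("training diffusion on %d segments (counts %s)",
      length(train_segs), paste(counts, collapse = "/"))
  schedule <- reduced_schedule(T_steps)
  dcfg <- denoiser_config(D, Ts, n_classes = fix_train$K, base_width = 16L,
                          levels = 2L, channel_mult = c(1, 2), emb_dim = 32L,
                          attention = FALSE)
  dmodel <- train_diffusion(norm, schedule, dcfg,
                            iterations = diffusion_iterations,
                            batch_size = diffusion_batch, lr = diffusion_lr,
                            seed = derive_seed(seed, 13L), verbose = verbose)
  say("diffusion loss: %.3f -> %.3f", mean(dmodel$history[1:20]),
      mean(utils::tail(dmodel$history, 20)))
  settings <- guidance_settings()
  rho_aug <- max(rho_values)
  plan <- plan_allocation(counts, rho_aug)
  augmented <- build_augmented_dataset(train_segs, dmodel, schedule, plan,
                                       stats, settings,
                                       seed = derive_seed(seed, 14L))
  synthetic <- augmented[vapply(augmented, function(s) s$provenance,
                                character(1)) == "synthetic"]
  sum_real <- class_summary(train_segs)
  sum_syn <- class_summary(synthetic)
  # dominant channels: largest |real mean| sensor/moment channels per class
  dom <- list()
  for (c in seq_len(fix_train$K)) {
    r <- sum_real[sum_real$class == c & sum_real$channel != "body_weight", ]
    s <- sum_syn[sum_syn$class == c, ]
    r <- r[order(-abs(r$mean)), ][seq_len(n_dominant), ]
    sm <- s$mean[match(r$channel, s$channel)]
    dom[[c]] <- data.frame(class = c, channel = r$channel, real_mean = r$mean,
                           synthetic_mean = sm,
                           rel_err = abs(sm - r$mean) / abs(r$mean))
  }
  dominant <- do.call(rbind, dom)
  rownames(dominant) <- NULL
  say("dominant-channel relative errors: %s",
      paste(sprintf("%.3f", dominant$rel_err), collapse = ", "))
  rcfg <- momentformer_config(Ds = D - 3L, Tc = Tc, C = 32L, L = 2L,
                              heads = 4L, ffn_mult = 2L, dropout = 0.1)
  cache <- stats::setNames(list(augmented), as.character(rho_aug))
  sweep <- ratio_sweep(train_segs, test_segs, dmodel, schedule, stats,
                       rho_values = rho_values, seeds = reg_seeds,
                       reg_cfg = rcfg, settings = settings, epochs = epochs,
                       augmented_cache = cache)
  minority <- which.min(counts)
  mino <- sweep[sweep$class == as.character(minority), ]
  minority_rmse <- stats::aggregate(rmse ~ rho + seed, data = mino, FUN = mean)
  list(dominant = dominant, summary_real = sum_real,
       summary_synthetic = sum_syn, sweep = sweep,
       minority_class = minority, minority_rmse = minority_rmse,
       real_counts = counts, plan = plan,
       diffusion_loss = c(first = mean(dmodel$history[1:20]),
                          last = mean(utils::tail(dmodel$history, 20))))
}
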