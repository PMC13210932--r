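#' Joint-moment estimation metrics
#'
#' Computes, per joint over the pooled evaluation frames:
#' \itemize{
#'   \item RMSE \eqn{= \sqrt{\mathrm{mean}((m - m^*)^2)}};
#'   \item \eqn{R^2 = 1 - SS_{res}/SS_{tot}} (total sum of squares about
#'     the ground-truth mean);
#'   \item nMAE \eqn{= 100\,\mathrm{mean}|m - m^*| / (\max m^* - \min m^*)},
#'     the mean absolute error as a percentage of the ground-truth
#'     peak-to-peak range (a convention of this package; see the vignette).
#' }
#'
#' @param predictions `n x 2` matrix (hip, knee), frame-aligned to truths.
#' @param truths `n x 2` matrix of ground-truth moments.
#' @return `data.frame` with columns `joint`, `rmse`, `r2`, `nmae`,
#'   `n_frames`.
#' @export
compute_metrics <- function(predictions, truths) {
  predictions <- as.matrix(predictions); truths <- as.matrix(truths)
  if (!identical(dim(predictions), dim(truths)))
    stop("predictions and truths must have identical shape", call. = FALSE)
  if (nrow(truths) < 2L) stop("need at least 2 frames", call. = FALSE)
  joints <- colnames(truths) %||% c("hip", "knee")
  res <- lapply(seq_len(ncol(truths)), function(j) {
    m <- predictions[, j]; ms <- truths[, j]
    if (max(ms) == min(ms))
      stop(sprintf("R-squared undefined: constant ground truth in joint '%s'",
                   joints[j]), call. = FALSE)
    err <- m - ms
    data.frame(joint = joints[j],
               rmse = sqrt(mean(err^2)),
               r2 = 1 - sum(err^2) / sum((ms - mean(ms))^2),
               nmae = 100 * mean(abs(err)) / (max(ms) - min(ms)),
               n_frames = length(ms))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Aggregate metrics across seeds within activity categories
#'
#' Takes a long table of per-run metrics (one row per class x seed x joint)
#' and reports the mean and population standard deviation of each metric
#' across seeds within each (class, joint) cell.
#'
#' @param runs `data.frame` with columns `class`, `seed`, `joint` and one
#'   or more metric columns (e.g. `rmse`, `r2`, `nmae`).
#' @param metrics character vector of metric column names to aggregate.
#' @return long `data.frame` with columns `class`, `joint`, `metric`,
#'   `mean`, `sd`, `n_seeds`.
#' @export
per_category_report <- function(runs, metrics = intersect(c("rmse", "r2", "nmae"),
                                                          names(runs))) {
  stopifnot(all(c("class", "seed", "joint") %in% names(runs)),
            length(metrics) > 0L)
  cells <- unique(runs[, c("class", "joint")])
  out <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- runs$class == cells$class[i] & runs$joint == cells$joint[i]
    for (m in metrics) {
      v <- runs[[m]][sel]
      out[[length(out) + 1L]] <- data.frame(
        class = cells$class[i], joint = cells$joint[i], metric = m,
        mean = mean(v), sd = sqrt(mean((v - mean(v))^2)),
        n_seeds = length(v))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

eval_rows <- function(model, test_segments, stats, extra = list()) {
  ev <- evaluate_regressor(model, test_segments, stats)
  rows <- list()
  add <- function(class_tag, sel) {
    mt <- compute_metrics(ev$predictions[sel, , drop = FALSE],
                          ev$truths[sel, , drop = FALSE])
    mt$class <- class_tag
    rows[[length(rows) + 1L]] <<- mt
  }
  add("all", rep(TRUE, length(ev$class)))
  for (c in sort(unique(ev$class))) add(as.character(c), ev$class == c)
  out <- do.call(rbind, rows)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

#' Sweep over synthetic-to-real augmentation ratios
#'
#' For each ratio `rho`, builds the augmented training set (equal-split
#' allocation; `rho = 0` reduces bit-for-bit to the no-augmentation
#' baseline), trains the regressor once per seed, and evaluates on held-out
#' segments, overall and per activity class. Reproducible given the seeds.
#'
#' @param real_segments physical-space real training segments.
#' @param test_segments held-out evaluation segments.
#' @param diffusion_model trained denoiser (required when any `rho > 0`).
#' @param schedule the denoiser's diffusion schedule.
#' @param stats `norm_stats` with min-max and z-score slots fitted on the
#'   real training segments.
#' @param rho_values numeric vector of ratios.
#' @param seeds integer vector of training seeds.
#' @param reg_cfg a [momentformer_config()].
#' @param settings a [guidance_settings()].
#' @param epochs,batch_size,lr training settings passed to
#'   [train_regressor()].
#' @return long `data.frame`: one row per (rho, seed, class, joint) with
#'   the three metrics.
#' @export
ratio_sweep <- function(real_segments, test_segments, diffusion_model,
                        schedule, stats, rho_values = c(0, 1, 2),
                        seeds = 1:5, reg_cfg, settings = guidance_settings(),
                        epochs = 30L, batch_size = 16L, lr = 1e-3,
                        augmented_cache = list()) {
  if (any(rho_values > 0) && is.null(diffusion_model) &&
      !all(as.character(rho_values[rho_values > 0]) %in% names(augmented_cache)))
    stop("a diffusion model checkpoint is required for rho > 0", call. = FALSE)
  counts <- tabulate(vapply(real_segments, function(s) s$class_label,
                            integer(1)), nbins = nrow(stats$min))
  out <- list()
  for (rho in rho_values) {
    train_set <- if (rho == 0) real_segments
    else augmented_cache[[as.character(rho)]] %||%
      build_augmented_dataset(real_segments, diffusion_model, schedule,
                              plan_allocation(counts, rho), stats, settings,
                              seed = derive_seed(1000L, round(1000 * rho)))
    for (sd_i in seeds) {
      model <- train_regressor(train_set, stats, reg_cfg, epochs = epochs,
                               batch_size = batch_size, lr = lr, seed = sd_i)
      out[[length(out) + 1L]] <- eval_rows(model, test_segments, stats,
                                           extra = list(rho = rho, seed = sd_i))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Sensor-modality ablation
#'
#' Trains and evaluates the regressor on subsets of the sensor modalities
#' (`insole`, `encoder`, `imu`), dropping the unused channels and
#' re-fitting z-score statistics on the kept columns. The full subset
#' reduces to the standard pipeline.
#'
#' @param real_segments training segments (physical space).
#' @param test_segments evaluation segments.
#' @param subsets named list of modality character vectors; default the 7
#'   non-empty combinations.
#' @param seeds integer vector of training seeds.
#' @param reg_cfg a [momentformer_config()] for the *full* sensor width;
#'   widths are reduced per subset.
#' @param epochs,batch_size,lr training settings.
#' @return long `data.frame`: one row per (subset, seed, class, joint).
#' @export
sensor_ablation <- function(real_segments, test_segments,
                            subsets = NULL, seeds = 1L, reg_cfg,
                            epochs = 30L, batch_size = 16L, lr = 1e-3) {
  subsets <- subsets %||% list(
    a = "insole", b = "encoder", c = "imu",
    d = c("insole", "encoder"), e = c("insole", "imu"),
    f = c("encoder", "imu"), g = c("insole", "encoder", "imu"))
  D <- ncol(real_segments[[1L]]$values)
  cn <- colnames(real_segments[[1L]]$values)
  mods <- channel_modalities(cn[seq_len(D - 3L)])
  restrict <- function(segments, keep_cols) {
    lapply(segments, function(sg) {
      v <- sg$values[, c(keep_cols, D - 2L, D - 1L, D), drop = FALSE]
      new_segment(v, sg$class_label, sg$space, sg$provenance, sg$subject_id)
    })
  }
  out <- list()
  for (nm in names(subsets)) {
    keep <- which(mods %in% subsets[[nm]])
    if (length(keep) == 0L)
      stop(sprintf("subset '%s' selects no channels", nm), call. = FALSE)
    tr <- restrict(real_segments, keep)
    te <- restrict(test_segments, keep)
    st <- fit_zscore_stats(tr)
    cfg <- reg_cfg
    cfg$Ds <- length(keep)
    for (sd_i in seeds) {
      model <- train_regressor(tr, st, cfg, epochs = epochs,
                               batch_size = batch_size, lr = lr, seed = sd_i)
      out[[length(out) + 1L]] <- eval_rows(model, te, st,
                                           extra = list(subset = nm,
                                                        seed = sd_i))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
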