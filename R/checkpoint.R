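#' Save a diffusion or regressor checkpoint
#'
#' Bundles model parameters and configuration with the diffusion schedule
#' and the normalization statistics they were fitted with, so sampling and
#' inference are reproducible from a single archive.
#'
#' @param model a `denoiser_unet` or `momentformer`.
#' @param path output file path (RDS).
#' @param schedule optional [build_schedule()] object.
#' @param stats optional `norm_stats`.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path, schedule = NULL, stats = NULL) {
  saveRDS(list(model = model, schedule = schedule, stats = stats,
               package_version = as.character(utils::packageVersion("momentdiff"))),
          path)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#' @param path checkpoint path.
#' @return list with `model`, `schedule`, `stats`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path))
    stop(sprintf("checkpoint not found: %s", path), call. = FALSE)
  readRDS(path)
}
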