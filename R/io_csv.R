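#' Write motion sequences to the canonical CSV layout
#'
#' One row per frame with header
#' `trial_id,subject_id,class_label,weight,<sensor names>,hip_moment,knee_moment`;
#' frames of one trial are contiguous and distinguished by `trial_id`.
#'
#' @param sequences list of [motion_sequence()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_motion_dataset <- function(sequences, path) {
  stopifnot(length(sequences) > 0L)
  rows <- lapply(seq_along(sequences), function(i) {
    sq <- sequences[[i]]
    data.frame(trial_id = i, subject_id = sq$subject_id,
               class_label = sq$class_label, weight = sq$body_weight,
               sq$frames, check.names = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Load motion sequences from the canonical CSV layout
#'
#' Validates the header against the documented channel contract, checks all
#' values are finite (a parse error names the offending row and column), and
#' reads class label and body weight once per trial.
#'
#' @param path CSV file written in the layout of [write_motion_dataset()].
#' @return list of [motion_sequence()] objects, one per trial.
#' @export
load_motion_dataset <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- c("trial_id", "subject_id", "class_label", "weight")
  missing_meta <- setdiff(meta, names(df))
  if (length(missing_meta))
    stop(sprintf("missing required column(s): %s",
                 paste(missing_meta, collapse = ", ")), call. = FALSE)
  mom <- moment_channel_names()
  if (!all(mom %in% names(df)))
    stop("missing joint-moment column(s) hip_moment/knee_moment", call. = FALSE)
  chan <- setdiff(names(df), c(meta, "provenance"))
  if (!identical(utils::tail(chan, 2L), mom))
    stop("channel columns must end with hip_moment, knee_moment", call. = FALSE)
  num <- df[, chan, drop = FALSE]
  for (cl in chan) {
    v <- suppressWarnings(as.numeric(num[[cl]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("non-finite value at row %d, column '%s'", bad[1L], cl),
           call. = FALSE)
    num[[cl]] <- v
  }
  lab <- suppressWarnings(as.integer(df$class_label))
  if (any(!is.finite(lab) | lab < 1L))
    stop("class_label must be a positive integer for every frame", call. = FALSE)
  ids <- unique(df$trial_id)
  lapply(ids, function(id) {
    sel <- df$trial_id == id
    fr <- as.matrix(num[sel, , drop = FALSE])
    rownames(fr) <- NULL
    w <- unique(df$weight[sel]); lb <- unique(lab[sel])
    if (length(w) != 1L)
      stop(sprintf("trial %s has a non-constant weight column", id),
           call. = FALSE)
    if (length(lb) != 1L)
      stop(sprintf("trial %s has a non-constant class label", id),
           call. = FALSE)
    motion_sequence(fr, lb, w, subject_id = as.character(df$subject_id[sel][1L]))
  })
}

#' Write segments to CSV (with provenance column)
#'
#' Same columnar layout as [write_motion_dataset()] plus a `provenance`
#' column; each segment becomes one trial of `Ts` rows. Segments must be in
#' physical space (the weight column is folded back into the `weight`
#' metadata column).
#'
#' @param segments list of physical-space `segment` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  stopifnot(length(segments) > 0L)
  rows <- lapply(seq_along(segments), function(i) {
    sg <- segments[[i]]
    stopifnot(sg$space == "physical")
    D <- ncol(sg$values)
    data.frame(trial_id = i, subject_id = sg$subject_id,
               class_label = sg$class_label,
               weight = mean(sg$values[, D]),
               provenance = sg$provenance,
               sg$values[, -D, drop = FALSE], check.names = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Load segments written by [write_segments()]
#' @param path CSV path.
#' @return list of `segment` objects in physical space.
#' @export
load_segments <- function(path) {
  seqs <- load_motion_dataset(path)
  df <- utils::read.csv(path, check.names = FALSE)
  prov <- if ("provenance" %in% names(df))
    vapply(unique(df$trial_id),
           function(id) as.character(df$provenance[df$trial_id == id][1L]),
           character(1))
  else rep("real", length(seqs))
  lapply(seq_along(seqs), function(i) {
    sq <- seqs[[i]]
    vals <- cbind(sq$frames, body_weight = sq$body_weight)
    new_segment(vals, sq$class_label, space = "physical",
                provenance = prov[i], subject_id = sq$subject_id)
  })
}
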