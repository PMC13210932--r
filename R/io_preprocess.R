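#' Construct a raw multimodal motion sequence
#'
#' A `motion_sequence` is one variable-length recording: a frames-by-channels
#' matrix holding the sensor channels followed by the two ground-truth
#' joint-moment channels, plus a class label, the subject's body weight and a
#' subject identifier. Body weight uses the same unit convention as the
#' divisor applied to the insole vertical-force channel before z-scoring.
#'
#' @param frames numeric matrix, `length x (Ds + 2)`; the last two columns
#'   are hip and knee moment. Column names default to the frozen contract.
#' @param class_label positive integer activity class (1-based).
#' @param body_weight positive scalar.
#' @param subject_id opaque identifier.
#' @return object of class `motion_sequence`.
#' @export
motion_sequence <- function(frames, class_label, body_weight,
                            subject_id = "s1") {
  assert_finite_matrix(frames, "frames")
  if (ncol(frames) < 3L)
    stop("frames needs at least one sensor channel plus two moment channels",
         call. = FALSE)
  if (nrow(frames) < 1L) stop("sequence length must be >= 1", call. = FALSE)
  if (length(class_label) != 1L || class_label < 1 ||
      class_label != round(class_label))
    stop("class_label must be a positive integer", call. = FALSE)
  if (length(body_weight) != 1L || !is.finite(body_weight) || body_weight <= 0)
    stop("body_weight must be a positive scalar", call. = FALSE)
  if (is.null(colnames(frames))) {
    Ds <- ncol(frames) - 2L
    colnames(frames) <- c(sensor_channel_names(Ds), moment_channel_names())
  }
  structure(
    list(frames = frames, class_label = as.integer(class_label),
         body_weight = as.numeric(body_weight),
         subject_id = as.character(subject_id)),
    class = "motion_sequence")
}

#' @export
print.motion_sequence <- function(x, ...) {
  cat(sprintf("<motion_sequence> %d frames x %d channels, class %d, subject %s, weight %.1f\n",
              nrow(x$frames), ncol(x$frames), x$class_label, x$subject_id,
              x$body_weight))
  invisible(x)
}

#' Construct a fixed-length segment
#'
#' A `segment` is a `Ts x D` window where the columns are ordered
#' `[sensor dims | hip moment | knee moment | body weight]`. The `space`
#' tag records which value space the segment currently lives in:
#' `"physical"` (raw units) or `"signed_unit"` (per-class min-max mapped to
#' \[-1, 1\], the diffusion model's training space). The `provenance` tag
#' (`"real"` or `"synthetic"`) gates which segments may be used when fitting
#' z-score statistics.
#'
#' @param values numeric `Ts x D` matrix.
#' @param class_label positive integer.
#' @param space `"physical"` or `"signed_unit"`.
#' @param provenance `"real"` or `"synthetic"`.
#' @param subject_id opaque identifier.
#' @return object of class `segment`.
#' @export
new_segment <- function(values, class_label, space = "physical",
                        provenance = "real", subject_id = "s1") {
  assert_finite_matrix(values, "segment values")
  space <- match.arg(space, c("physical", "signed_unit"))
  provenance <- match.arg(provenance, c("real", "synthetic"))
  if (space == "signed_unit" && (min(values) < -1 - 1e-9 || max(values) > 1 + 1e-9))
    stop("signed_unit segments must have values in [-1, 1]", call. = FALSE)
  structure(
    list(values = values, class_label = as.integer(class_label),
         space = space, provenance = provenance,
         subject_id = as.character(subject_id)),
    class = "segment")
}

#' @export
print.segment <- function(x, ...) {
  cat(sprintf("<segment> %d x %d, class %d, %s space, %s\n",
              nrow(x$values), ncol(x$values), x$class_label, x$space,
              x$provenance))
  invisible(x)
}

#' Segment variable-length sequences into fixed windows
#'
#' Each sequence is cut sequentially into windows of length `Ts` starting at
#' frames `1, 1+stride, 1+2*stride, ...`; a trailing remainder shorter than
#' `Ts` is dropped. The subject's body weight is repeated over all time steps
#' and appended as the last column, and the class label is inherited, so each
#' segment jointly carries sensors, moments and weight (`D = Ds + 3`).
#'
#' @param sequences list of [motion_sequence()] objects.
#' @param Ts window length (frames).
#' @param stride hop between window starts; defaults to `Ts`
#'   (non-overlapping).
#' @return list of `segment` objects in physical space, provenance `"real"`.
#' @export
segment_sequences <- function(sequences, Ts, stride = Ts) {
  if (Ts < 1 || stride < 1) stop("Ts and stride must be >= 1", call. = FALSE)
  Ts <- as.integer(Ts); stride <- as.integer(stride)
  out <- list()
  for (sq in sequences) {
    stopifnot(inherits(sq, "motion_sequence"))
    len <- nrow(sq$frames)
    if (len < Ts) next
    starts <- seq.int(1L, len - Ts + 1L, by = stride)
    for (s in starts) {
      vals <- cbind(sq$frames[s:(s + Ts - 1L), , drop = FALSE],
                    body_weight = sq$body_weight)
      out[[length(out) + 1L]] <- new_segment(
        vals, sq$class_label, space = "physical", provenance = "real",
        subject_id = sq$subject_id)
    }
  }
  out
}

seg_matrix <- function(segments) {
  # stack all frames of all segments: (n*Ts) x D
  do.call(rbind, lapply(segments, function(s) s$values))
}

#' Fit per-class, per-dimension min-max statistics
#'
#' For each activity class `c` and feature dimension `d`, computes the
#' minimum and maximum over all frames of all class-`c` training segments.
#' Dimensions with `max - min = 0` (e.g., the constant body-weight column)
#' are flagged in `degenerate`.
#'
#' @param segments non-empty list of physical-space segments.
#' @param n_classes total number of classes `K`; defaults to the largest
#'   label present.
#' @return object of class `norm_stats` with elements `min`, `max`
#'   (`K x D` matrices, `NA` rows for absent classes), `degenerate`
#'   (`K x D` logical), `channel_names`, and an empty `zscore` slot.
#' @export
fit_minmax_stats <- function(segments, n_classes = NULL) {
  if (length(segments) == 0L) stop("no segments provided", call. = FALSE)
  stopifnot(all(vapply(segments, function(s) s$space == "physical", logical(1))))
  D <- ncol(segments[[1L]]$values)
  labels <- vapply(segments, function(s) s$class_label, integer(1))
  K <- as.integer(n_classes %||% max(labels))
  if (max(labels) > K) stop("segment label exceeds n_classes", call. = FALSE)
  mn <- matrix(NA_real_, K, D); mx <- matrix(NA_real_, K, D)
  for (c in sort(unique(labels))) {
    m <- seg_matrix(segments[labels == c])
    mn[c, ] <- apply(m, 2, min)
    mx[c, ] <- apply(m, 2, max)
  }
  cn <- colnames(segments[[1L]]$values)
  colnames(mn) <- cn; colnames(mx) <- cn
  structure(
    list(min = mn, max = mx, degenerate = (mx - mn) == 0,
         channel_names = cn, zscore = NULL),
    class = "norm_stats")
}

#' @export
print.norm_stats <- function(x, ...) {
  cat(sprintf("<norm_stats> K = %d classes x D = %d dims; z-score %s\n",
              nrow(x$min), ncol(x$min),
              if (is.null(x$zscore)) "not fitted" else "fitted"))
  invisible(x)
}

check_class_in_stats <- function(class_label, stats) {
  if (class_label < 1 || class_label > nrow(stats$min) ||
      anyNA(stats$min[class_label, ]))
    stop(sprintf("class %d has no fitted min-max statistics", class_label),
         call. = FALSE)
}

#' Map a physical segment into the diffusion model's signed-unit space
#'
#' Applies dimension-wise min-max normalization with the statistics of the
#' segment's own class, mapping each dimension to \[0, 1\] via
#' `(x - min) / (max - min)` and then linearly rescaling to \[-1, 1\] via
#' `u -> 2u - 1`. Degenerate dimensions (fitted `min == max`) map to the
#' constant 0. Values outside the fitted range are *not* clipped here (only
#' the sampler clips); segments from the fitting set itself land in
#' \[-1, 1\] exactly.
#'
#' @param segment a physical-space `segment`.
#' @param stats fitted [fit_minmax_stats()] object.
#' @return the segment in `signed_unit` space.
#' @export
normalize_segment <- function(segment, stats) {
  stopifnot(inherits(segment, "segment"), inherits(stats, "norm_stats"))
  if (segment$space != "physical")
    stop("segment is not in physical space", call. = FALSE)
  c <- segment$class_label
  check_class_in_stats(c, stats)
  mn <- stats$min[c, ]; mx <- stats$max[c, ]; deg <- stats$degenerate[c, ]
  rng <- ifelse(deg, 1, mx - mn)
  u <- sweep(sweep(segment$values, 2, mn, "-"), 2, rng, "/")
  y <- 2 * u - 1
  y[, deg] <- 0
  out <- segment
  out$values <- y
  out$space <- "signed_unit"
  out
}

#' Map a signed-unit segment back to physical units
#'
#' Exact algebraic inverse of [normalize_segment()] for the segment's class:
#' `x = min + (y + 1)/2 * (max - min)`; degenerate dimensions are restored
#' to their stored constant.
#'
#' @param segment a `signed_unit` segment.
#' @param stats fitted [fit_minmax_stats()] object.
#' @return the segment in `physical` space.
#' @export
denormalize_segment <- function(segment, stats) {
  stopifnot(inherits(segment, "segment"), inherits(stats, "norm_stats"))
  if (segment$space != "signed_unit")
    stop("segment is not in signed_unit space", call. = FALSE)
  c <- segment$class_label
  check_class_in_stats(c, stats)
  mn <- stats$min[c, ]; mx <- stats$max[c, ]; deg <- stats$degenerate[c, ]
  u <- (segment$values + 1) / 2
  x <- sweep(sweep(u, 2, mx - mn, "*"), 2, mn, "+")
  x[, deg] <- matrix(mn[deg], nrow(x), sum(deg), byrow = TRUE)
  out <- segment
  out$values <- x
  out$space <- "physical"
  out
}

#' Fit per-dimension z-score statistics from real training segments
#'
#' Computes the per-dimension mean and population (1/N) standard deviation
#' across all frames of all *real* training segments; synthetic segments are
#' rejected. The insole vertical-force channel is first divided frame-wise
#' by the segment's body-weight column. These statistics normalize the
#' regressor's inputs; the same statistics are applied to evaluation data.
#'
#' @param real_segments list of physical-space segments with provenance
#'   `"real"`.
#' @param stats optional existing `norm_stats` to attach the z-score slot to.
#' @return a `norm_stats` object with `zscore = list(mean, sd)` (length-D
#'   vectors). Weight-column variance may be zero (it is never z-scored);
#'   zero variance in any sensor or moment dimension is an error naming the
#'   dimension.
#' @export
fit_zscore_stats <- function(real_segments, stats = NULL) {
  if (length(real_segments) == 0L) stop("no segments provided", call. = FALSE)
  if (any(vapply(real_segments, function(s) s$provenance, character(1)) !=
          "real"))
    stop("z-score statistics must be fitted on real segments only",
         call. = FALSE)
  stopifnot(all(vapply(real_segments, function(s) s$space == "physical",
                       logical(1))))
  m <- seg_matrix(real_segments)
  cn <- colnames(real_segments[[1L]]$values)
  D <- ncol(m)
  fi <- insole_force_index(cn)
  if (!is.na(fi)) m[, fi] <- m[, fi] / m[, D]   # weight division first
  mu <- colMeans(m)
  sd_pop <- sqrt(colMeans(sweep(m, 2, mu, "-")^2))
  bad <- which(sd_pop == 0)
  bad <- setdiff(bad, D)                        # constant weight column is fine
  if (length(bad))
    stop(sprintf("zero variance in dimension(s): %s",
                 paste(cn[bad], collapse = ", ")), call. = FALSE)
  out <- stats %||% structure(
    list(min = matrix(NA_real_, 1, D), max = matrix(NA_real_, 1, D),
         degenerate = matrix(FALSE, 1, D), channel_names = cn, zscore = NULL),
    class = "norm_stats")
  out$zscore <- list(mean = mu, sd = sd_pop)
  out
}

#' Z-score a sensor matrix with fitted statistics
#'
#' Applies weight division to the insole vertical-force channel and then the
#' fitted real-data z-score to the sensor columns of a physical segment,
#' returning the normalized `Ts x Ds` sensor matrix.
#'
#' @param segment physical-space segment (`D = Ds + 3` layout).
#' @param stats `norm_stats` with a fitted `zscore` slot.
#' @return `Ts x Ds` matrix of z-scored sensors.
#' @export
zscore_sensors <- function(segment, stats) {
  if (is.null(stats$zscore)) stop("z-score statistics not fitted", call. = FALSE)
  D <- ncol(segment$values)
  Ds <- D - 3L
  s <- segment$values[, seq_len(Ds), drop = FALSE]
  fi <- insole_force_index(colnames(segment$values)[seq_len(Ds)])
  if (!is.na(fi)) s[, fi] <- s[, fi] / segment$values[, D]
  mu <- stats$zscore$mean[seq_len(Ds)]
  sd <- stats$zscore$sd[seq_len(Ds)]
  sweep(sweep(s, 2, mu, "-"), 2, sd, "/")
}

#' Serialize fitted normalization statistics to a JSON sidecar
#' @param stats a `norm_stats` object.
#' @param path output file path.
#' @export
save_norm_stats <- function(stats, path) {
  obj <- list(channel_names = stats$channel_names,
              min = stats$min, max = stats$max,
              degenerate = stats$degenerate,
              zscore = stats$zscore)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load normalization statistics from a JSON sidecar
#' @param path file written by [save_norm_stats()].
#' @return a `norm_stats` object.
#' @export
load_norm_stats <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tomat <- function(m) {
    m <- as.matrix(m); colnames(m) <- obj$channel_names; m
  }
  zs <- NULL
  if (!is.null(obj$zscore))
    zs <- list(mean = as.numeric(obj$zscore$mean),
               sd = as.numeric(obj$zscore$sd))
  structure(
    list(min = tomat(obj$min), max = tomat(obj$max),
         degenerate = tomat(obj$degenerate) > 0,
         channel_names = obj$channel_names, zscore = zs),
    class = "norm_stats")
}
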