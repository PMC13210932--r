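#' Frozen sensor-channel naming contract
#'
#' Channel order is frozen so that dimension indices in fitted normalization
#' statistics stay stable across runs and serialized sidecars. Sensor columns
#' come first (encoders, then IMUs, then insole), followed by the two
#' joint-moment columns and, in segments, the broadcast body-weight column.
#'
#' Two layouts are provided: the compact 6-channel layout used by the toy
#' fixtures, and the full 25-channel layout of a thigh/shank/foot IMU triplet
#' (tri-axial accelerometer + gyroscope each), hip/knee encoder angles and a
#' 5-channel plantar-pressure insole block whose vertical-force channel is
#' named `insole_force_v`.
#'
#' @param Ds number of sensor dimensions; 6 and 25 have canonical names,
#'   other values get generic `sensor_<i>` names.
#' @return character vector of `Ds` sensor channel names.
#' @export
sensor_channel_names <- function(Ds) {
  if (Ds == 6L) {
    c("hip_angle", "knee_angle", "thigh_gyro", "shank_gyro", "foot_accel",
      "insole_force_v")
  } else if (Ds == 25L) {
    imu <- as.vector(outer(
      c("accel_x", "accel_y", "accel_z", "gyro_x", "gyro_y", "gyro_z"),
      c("thigh_imu", "shank_imu", "foot_imu"),
      function(a, s) paste(s, a, sep = "_")))
    c("hip_angle", "knee_angle", imu,
      "insole_force_v", "insole_force_ap", "insole_force_ml",
      "insole_cop_x", "insole_cop_y")
  } else {
    extra <- if (Ds > 3L) paste0("sensor_", seq_len(Ds - 3L)) else character(0)
    c("hip_angle", "knee_angle", extra, "insole_force_v")[seq_len(Ds)]
  }
}

#' @rdname sensor_channel_names
#' @export
moment_channel_names <- function() c("hip_moment", "knee_moment")

#' Map sensor channels to their modality
#'
#' Assigns each sensor channel to one of the three wearable modalities used
#' in the sensor-ablation study: `encoder` (joint-angle encoders), `imu`
#' (inertial measurement units) and `insole` (plantar pressure).
#'
#' @param channel_names character vector of sensor channel names.
#' @return character vector of modalities, same length.
#' @export
channel_modalities <- function(channel_names) {
  out <- rep("imu", length(channel_names))
  out[grepl("^(hip|knee)_angle$", channel_names)] <- "encoder"
  out[grepl("^insole", channel_names)] <- "insole"
  out
}

# index of the weight-normalized insole vertical-force channel (NA if absent)
insole_force_index <- function(channel_names) {
  i <- match("insole_force_v", channel_names)
  if (is.na(i)) NA_integer_ else i
}
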