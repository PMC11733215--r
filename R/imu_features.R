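# IMU feature pipeline: moving-average smoothing, per-series mean
# centering (which removes the constant gravity offset on accelerometer
# channels), and pooled z-scoring of accelerations and angular
# velocities separately, giving the 300 x 36 matrix. Channels stay at
# 60 Hz; temporal harmonization with the other modalities happens only
# in early fusion.

imu_channel_names <- function() {
  as.vector(vapply(seq_len(6L), function(s) {
    paste0(IMU_CHANNEL_ORDER, "_s", s)
  }, character(6L)))
}

# columns of the sensor-major 300 x 36 layout holding accelerations
imu_acc_cols <- function() which(rep(c(TRUE, TRUE, TRUE, FALSE, FALSE,
                                       FALSE), 6L))
imu_gyr_cols <- function() which(rep(c(FALSE, FALSE, FALSE, TRUE, TRUE,
                                       TRUE), 6L))

# Fold-independent part: smoothed, mean-centered 300 x 36 matrix.
imu_series <- function(snippet) {
  stopifnot(inherits(snippet, "imu_snippet"))
  mat <- imu_to_matrix(snippet$values)
  mat <- apply(mat, 2L, smooth_series, window = 5L,
               kind = "moving_average")
  sweep(mat, 2L, colMeans(mat))
}

#' Build the 300 x 36 IMU feature matrix
#'
#' Each of the 36 channel series is smoothed with a moving-average
#' filter (window 5) and mean-centered per series; acceleration channels
#' are then z-scored with the pooled training-set `acceleration`
#' statistics and gyro channels with the `angular_velocity` statistics.
#' Columns are sensor-major: `(ax, ay, az, gx, gy, gz)` for sensor 1
#' (L-shoulder) through sensor 6 (R-foot).
#'
#' @param snippet An [imu_snippet()].
#' @param stats A [fit_norm_stats()] result with groups `acceleration`
#'   and `angular_velocity`.
#' @return A [feature_matrix()] of modality `"IMU"` (300 x 36).
#' @export
build_imu_features <- function(snippet, stats) {
  mat <- imu_series(snippet)
  acc <- imu_acc_cols()
  gyr <- imu_gyr_cols()
  mat[, acc] <- apply_norm(mat[, acc], "acceleration", stats)
  mat[, gyr] <- apply_norm(mat[, gyr], "angular_velocity", stats)
  feature_matrix(mat, "IMU", imu_channel_names(), snippet$meta)
}
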