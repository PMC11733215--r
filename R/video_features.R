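# Video (pose key-point) feature pipeline: outlier removal and
# smoothing, skeleton centering / rotation / scaling, per-series mean
# centering, finite-difference velocities, and pooled z-scoring, giving
# the 250 x 60 position + velocity feature matrix.

HIP_IDX <- c(10L, 11L)       # l_hip, r_hip
SHOULDER_IDX <- c(4L, 5L)    # l_shoulder, r_shoulder

#' Remove key-point outliers and smooth trajectories
#'
#' Passes each of the 30 coordinate series through a median filter
#' (window 5) and then a moving-average filter (window 5). Isolated
#' pose-estimation spikes are absorbed by the median stage; no separate
#' outlier-detection pass is used.
#'
#' @param snippet A [keypoint_snippet()].
#' @return A [keypoint_snippet()] of the same shape.
#' @export
clean_trajectories <- function(snippet) {
  stopifnot(inherits(snippet, "keypoint_snippet"))
  vals <- snippet$values
  for (k in seq_len(15L)) {
    for (a in 1:2) {
      s <- smooth_series(vals[, k, a], 5L, "median")
      vals[, k, a] <- smooth_series(s, 5L, "moving_average")
    }
  }
  keypoint_snippet(vals, snippet$meta)
}

hip_center <- function(vals) {
  c(mean(vals[, HIP_IDX, 1L]), mean(vals[, HIP_IDX, 2L]))
}

shoulder_center <- function(vals) {
  c(mean(vals[, SHOULDER_IDX, 1L]), mean(vals[, SHOULDER_IDX, 2L]))
}

#' Center the skeleton on the average hip midpoint
#'
#' Computes the across-frames average center point between the two hip
#' key points and subtracts it from every key point in every frame.
#'
#' @param snippet A (cleaned) [keypoint_snippet()].
#' @return A centered [keypoint_snippet()].
#' @export
center_skeleton <- function(snippet) {
  stopifnot(inherits(snippet, "keypoint_snippet"))
  vals <- snippet$values
  hc <- hip_center(vals)
  vals[, , 1L] <- vals[, , 1L] - hc[1L]
  vals[, , 2L] <- vals[, , 2L] - hc[2L]
  keypoint_snippet(vals, snippet$meta)
}

#' Rotate the skeleton so the trunk midline lies on the +Y axis
#'
#' Computes the across-frames average shoulder midpoint and rotates
#' every frame by the signed angle that takes it to the positive Y axis.
#' The signed angle `atan2(x, y)` is used so that skeletons tilted to
#' either side are aligned onto +Y (an unsigned `acos` would flip
#' left-tilted skeletons onto -Y).
#'
#' @param snippet A centered [keypoint_snippet()].
#' @return A rotated [keypoint_snippet()].
#' @export
rotate_skeleton <- function(snippet) {
  stopifnot(inherits(snippet, "keypoint_snippet"))
  vals <- snippet$values
  sc <- shoulder_center(vals)
  r <- sqrt(sum(sc^2))
  if (r < 1e-12) stop("degenerate geometry: shoulder center at origin")
  phi <- atan2(sc[1L], sc[2L])
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2L, 2L)
  xy <- cbind(as.vector(vals[, , 1L]), as.vector(vals[, , 2L])) %*% t(R)
  vals[, , 1L] <- xy[, 1L]
  vals[, , 2L] <- xy[, 2L]
  keypoint_snippet(vals, snippet$meta)
}

#' Scale the skeleton to a fixed trunk length
#'
#' Divides all coordinates by three times the vertical distance between
#' the average hip and shoulder center points, so that the trunk length
#' becomes exactly 1/3.
#'
#' @param snippet A centered and rotated [keypoint_snippet()].
#' @return A scaled [keypoint_snippet()].
#' @export
scale_skeleton <- function(snippet) {
  stopifnot(inherits(snippet, "keypoint_snippet"))
  vals <- snippet$values
  hc <- hip_center(vals)
  sc <- shoulder_center(vals)
  denom <- 3 * abs(hc[2L] - sc[2L])
  if (denom < 1e-12) {
    stop("degenerate geometry: zero hip-shoulder distance")
  }
  keypoint_snippet(vals / denom, snippet$meta)
}

#' Full skeleton preprocessing chain
#'
#' clean -> center -> rotate -> scale, in the narrative order of the
#' video pipeline.
#'
#' @param snippet A raw [keypoint_snippet()].
#' @return A preprocessed [keypoint_snippet()].
#' @export
process_keypoints <- function(snippet) {
  scale_skeleton(rotate_skeleton(center_skeleton(
    clean_trajectories(snippet))))
}

central_diff <- function(x) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / 2
  d[1L] <- x[2L] - x[1L]
  d[n] <- x[n] - x[n - 1L]
  d
}

vid_channel_names <- function(prefix) {
  as.vector(t(outer(seq_len(15L), c("x", "y"), function(k, a) {
    paste0(a, k, "_", prefix)
  })))
}

# Per-snippet mean-centered position series (250 x 30, x1,y1,...) and
# their finite-difference velocities / accelerations. Fold-independent:
# only the final z-scoring needs training-set statistics.
pose_series <- function(snippet) {
  vals <- snippet$values
  pos <- matrix(0, nrow(vals), 30L)
  pos[, seq(1L, 29L, 2L)] <- vals[, , 1L]
  pos[, seq(2L, 30L, 2L)] <- vals[, , 2L]
  pos <- sweep(pos, 2L, colMeans(pos))
  vel <- apply(pos, 2L, central_diff)
  acc <- apply(vel, 2L, central_diff)
  list(pos = pos, vel = vel, acc = acc)
}

#' Build the 250 x 60 video feature matrix
#'
#' Mean-centers each key-point coordinate series within the snippet,
#' computes central-difference velocities (forward/backward differences
#' at the edge frames), and z-scores positions and velocities separately
#' with pooled training-set statistics. Columns are ordered
#' `x1_p, y1_p, ..., x15_p, y15_p, x1_v, y1_v, ..., x15_v, y15_v`.
#' With `include_acceleration = TRUE`, 30 acceleration columns
#' (z-scored with `stats$acceleration`) are appended.
#'
#' @param snippet A preprocessed [keypoint_snippet()] (see
#'   [process_keypoints()]).
#' @param stats A [fit_norm_stats()] result with groups `position` and
#'   `velocity` (and `acceleration` if requested).
#' @param include_acceleration Append acceleration columns (ablation
#'   flag; default `FALSE`).
#' @return A [feature_matrix()] of modality `"VID"` (250 x 60, or
#'   250 x 90 with accelerations).
#' @export
build_video_features <- function(snippet, stats,
                                 include_acceleration = FALSE) {
  ser <- pose_series(snippet)
  out <- cbind(apply_norm(ser$pos, "position", stats),
               apply_norm(ser$vel, "velocity", stats))
  names_out <- c(vid_channel_names("p"), vid_channel_names("v"))
  if (include_acceleration) {
    out <- cbind(out, apply_norm(ser$acc, "acceleration", stats))
    names_out <- c(names_out, vid_channel_names("a"))
  }
  feature_matrix(out, "VID", names_out, snippet$meta)
}
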