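# Shared containers and signal utilities: snippet types, the dataset
# collection, synchronization filtering, smoothing, and pooled z-scoring.

KEYPOINT_NAMES <- c(
  "nose", "l_eye", "r_eye", "l_shoulder", "r_shoulder",
  "l_elbow", "r_elbow", "l_wrist", "r_wrist", "l_hip", "r_hip",
  "l_knee", "r_knee", "l_ankle", "r_ankle"
)

IMU_SENSOR_ORDER <- c("l_shoulder", "r_shoulder", "l_hip", "r_hip",
                      "l_foot", "r_foot")
IMU_CHANNEL_ORDER <- c("ax", "ay", "az", "gx", "gy", "gz")

SESSIONS <- paste0("T", 1:7)

VID_RATE <- 50L
MAT_RATE <- 100L
IMU_RATE <- 60L
SNIPPET_SECONDS <- 5L

#' Snippet metadata
#'
#' Metadata shared by all modalities of one 5-second recording unit: a
#' unique snippet id, the infant it was recorded from, the recording
#' session (T1..T7, biweekly from 4 weeks post-term), and the human
#' fidgety-movement label.
#'
#' @param snippet_id Unique snippet identifier (string).
#' @param infant_id Infant identifier (string).
#' @param session One of `"T1"`..`"T7"`.
#' @param label `1` for FM+ (fidgety movements present), `0` for FM-
#'   (absent), or `NA` for a not-assessable snippet (excluded before
#'   classification).
#' @return An object of class `snippet_meta`.
#' @export
snippet_meta <- function(snippet_id, infant_id, session = "T5", label = NA) {
  stopifnot(is.character(snippet_id), length(snippet_id) == 1L,
            is.character(infant_id), length(infant_id) == 1L)
  if (!session %in% SESSIONS) {
    stop("session must be one of ", paste(SESSIONS, collapse = ", "))
  }
  if (!(is.na(label) || label %in% c(0, 1))) {
    stop("label must be 0 (FM-), 1 (FM+) or NA (not assessable)")
  }
  structure(
    list(snippet_id = snippet_id, infant_id = infant_id,
         session = session,
         label = if (is.na(label)) NA_integer_ else as.integer(label),
         duration_s = SNIPPET_SECONDS),
    class = "snippet_meta")
}

#' Key-point snippet (video modality)
#'
#' A 5-second series of 15 skeleton key points at 50 Hz: an array of
#' 250 frames x 15 key points x 2 coordinates, in pixel units. Key-point
#' order is fixed (nose, eyes, shoulders, elbows, wrists, hips, knees,
#' ankles; left before right). Ear key points are never part of the
#' container: the head is located by the nose and two eyes alone.
#'
#' @param values Numeric array `c(250, 15, 2)`.
#' @param meta A [snippet_meta()].
#' @return An object of class `keypoint_snippet`.
#' @export
keypoint_snippet <- function(values, meta) {
  check_array(values, c(VID_RATE * SNIPPET_SECONDS, 15L, 2L),
              "keypoints", meta$snippet_id)
  structure(list(values = values, frame_rate = VID_RATE,
                 keypoint_names = KEYPOINT_NAMES, meta = meta),
            class = "keypoint_snippet")
}

#' Pressure-mat snippet
#'
#' A 5-second series of 32x32 pressure images at 100 Hz (500 frames),
#' non-negative sensor units.
#'
#' @param values Numeric array `c(500, 32, 32)`, all entries `>= 0`.
#' @param meta A [snippet_meta()].
#' @return An object of class `pressure_snippet`.
#' @export
pressure_snippet <- function(values, meta) {
  check_array(values, c(MAT_RATE * SNIPPET_SECONDS, 32L, 32L),
              "pressure", meta$snippet_id)
  if (any(values < 0)) {
    stop("pressure snippet ", meta$snippet_id, ": negative sensor values")
  }
  structure(list(values = values, frame_rate = MAT_RATE, meta = meta),
            class = "pressure_snippet")
}

#' IMU snippet
#'
#' A 5-second series from six inertial measurement units at 60 Hz:
#' 300 frames x 6 sensors x 6 channels. Sensors are ordered L-shoulder,
#' R-shoulder, L-hip, R-hip, L-foot, R-foot; channels are the
#' acceleration triplet (ax, ay, az) followed by the angular-velocity
#' triplet (gx, gy, gz).
#'
#' @param values Numeric array `c(300, 6, 6)`.
#' @param meta A [snippet_meta()].
#' @return An object of class `imu_snippet`.
#' @export
imu_snippet <- function(values, meta) {
  check_array(values, c(IMU_RATE * SNIPPET_SECONDS, 6L, 6L),
              "imu", meta$snippet_id)
  structure(list(values = values, frame_rate = IMU_RATE,
                 sensor_order = IMU_SENSOR_ORDER,
                 channel_order = IMU_CHANNEL_ORDER, meta = meta),
            class = "imu_snippet")
}

check_array <- function(values, dims, modality, snippet_id) {
  if (!is.numeric(values) || !identical(dim(values), as.integer(dims))) {
    stop("snippet ", snippet_id, ", modality ", modality,
         ": expected array of shape ", paste(dims, collapse = "x"),
         ", got ",
         if (is.null(dim(values))) "non-array"
         else paste(dim(values), collapse = "x"))
  }
  if (any(!is.finite(values))) {
    stop("snippet ", snippet_id, ", modality ", modality,
         ": non-finite values")
  }
  invisible(TRUE)
}

#' One synchronized tri-modal observation
#'
#' Bundles the (possibly absent) per-modality snippets of one 5-second
#' recording unit under shared metadata. A triple is "synchronized" when
#' all three modalities are present.
#'
#' @param meta A [snippet_meta()].
#' @param keypoints A [keypoint_snippet()] or `NULL`.
#' @param pressure A [pressure_snippet()] or `NULL`.
#' @param imu An [imu_snippet()] or `NULL`.
#' @return An object of class `snippet_triple`.
#' @export
snippet_triple <- function(meta, keypoints = NULL, pressure = NULL,
                           imu = NULL) {
  for (part in list(keypoints, pressure, imu)) {
    if (!is.null(part) &&
        !identical(part$meta$snippet_id, meta$snippet_id)) {
      stop("sub-snippet metadata does not match triple metadata for ",
           meta$snippet_id)
    }
  }
  structure(list(meta = meta, keypoints = keypoints, pressure = pressure,
                 imu = imu),
            class = "snippet_triple")
}

#' Dataset of snippet triples
#'
#' @param triples List of [snippet_triple()] objects with unique snippet
#'   ids.
#' @return An object of class `fm_dataset` with elements `triples` and
#'   the derived unique `infant_ids`.
#' @export
fm_dataset <- function(triples = list()) {
  ids <- vapply(triples, function(t) t$meta$snippet_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate snippet ids in dataset")
  infants <- unique(vapply(triples, function(t) t$meta$infant_id,
                           character(1)))
  structure(list(triples = triples, infant_ids = infants),
            class = "fm_dataset")
}

#' @export
length.fm_dataset <- function(x) length(x$triples)

#' @export
print.fm_dataset <- function(x, ...) {
  labs <- dataset_labels(x)
  cat(sprintf(
    "<fm_dataset> %d snippets from %d infants (FM+ %d, FM- %d, NA %d)\n",
    length(x$triples), length(x$infant_ids),
    sum(labs == 1L, na.rm = TRUE), sum(labs == 0L, na.rm = TRUE),
    sum(is.na(labs))))
  invisible(x)
}

dataset_labels <- function(dataset) {
  vapply(dataset$triples, function(t) t$meta$label, integer(1))
}

dataset_infants <- function(dataset) {
  vapply(dataset$triples, function(t) t$meta$infant_id, character(1))
}

has_modality <- function(triple, modality) {
  part <- switch(modality,
                 VID = triple$keypoints,
                 MAT = triple$pressure,
                 IMU = triple$imu,
                 stop("unknown modality: ", modality))
  !is.null(part)
}

#' Keep only labeled snippets with all required modalities present
#'
#' Drops triples missing any of the required modalities (e.g. snippets
#' with no synchronized IMU or pressure-mat recording) and triples whose
#' label is `NA` (not assessable). Order is preserved and the operation
#' is idempotent.
#'
#' @param dataset An [fm_dataset()].
#' @param required Character subset of `c("VID", "MAT", "IMU")`.
#' @return The filtered [fm_dataset()].
#' @export
filter_synchronized <- function(dataset,
                                required = c("VID", "MAT", "IMU")) {
  required <- match.arg(required, c("VID", "MAT", "IMU"),
                        several.ok = TRUE)
  keep <- vapply(dataset$triples, function(t) {
    !is.na(t$meta$label) &&
      all(vapply(required, function(m) has_modality(t, m), logical(1)))
  }, logical(1))
  fm_dataset(dataset$triples[keep])
}

#' Smooth a series with a centered sliding window
#'
#' Median or moving-average filter with a centered window. At the series
#' boundaries the window is truncated to the part that fits inside the
#' series, so the output has the same length as the input and no data is
#' invented at the edges.
#'
#' @param series Numeric vector.
#' @param window Odd positive window size in frames (default 5, the
#'   window used throughout the feature extraction).
#' @param kind `"median"` or `"moving_average"`.
#' @return Numeric vector of the same length.
#' @export
smooth_series <- function(series, window = 5L,
                          kind = c("median", "moving_average")) {
  kind <- match.arg(kind)
  n <- length(series)
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L) {
    stop("window must be an odd positive integer")
  }
  if (window > n) stop("window exceeds series length")
  if (window == 1L || n == 0L) return(series)
  half <- (window - 1L) %/% 2L
  if (kind == "moving_average") {
    # truncated centered mean via cumulative sums
    cs <- c(0, cumsum(series))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    return((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
  }
  out <- series
  if (n >= window) {
    out[(half + 1L):(n - half)] <- stats::runmed(series, window,
                                                 endrule = "keep")[
      (half + 1L):(n - half)]
  }
  for (i in c(seq_len(half), (n - half + 1L):n)) {
    out[i] <- stats::median(series[max(1L, i - half):min(n, i + half)])
  }
  out
}

#' Fit pooled normalization statistics on training data
#'
#' Computes one (mean, sd) pair per channel group by pooling every sample
#' of every series in that group across all training snippets, key
#' points/sensors, and coordinate axes. The sd is the population standard
#' deviation (divide by N), so z-scoring the training pool with its own
#' statistics gives exactly mean 0, sd 1.
#'
#' @param groups Named list mapping a group label (e.g. `"position"`,
#'   `"velocity"`, `"acceleration"`, `"angular_velocity"`) to a list (or
#'   single vector/matrix) of numeric series to pool.
#' @param fitted_on Free-text identifier of the training set.
#' @return An object of class `norm_stats`: named list of
#'   `list(mean, sd)` per group.
#' @export
fit_norm_stats <- function(groups, fitted_on = "training") {
  stopifnot(is.list(groups), !is.null(names(groups)),
            all(nzchar(names(groups))))
  stats_list <- lapply(names(groups), function(g) {
    series <- groups[[g]]
    if (!is.list(series)) series <- list(series)
    if (length(series) == 0L) stop("group ", g, " has no series")
    pool <- unlist(lapply(series, as.numeric), use.names = FALSE)
    m <- mean(pool)
    s <- sqrt(mean((pool - m)^2))
    if (!is.finite(s) || s <= 0) {
      stop("degenerate data: zero pooled variance in group ", g)
    }
    list(mean = m, sd = s)
  })
  names(stats_list) <- names(groups)
  structure(list(groups = stats_list, fitted_on = fitted_on),
            class = "norm_stats")
}

#' Apply training-set z-score normalization
#'
#' @param values Numeric vector/matrix/array.
#' @param group Group label present in `stats`.
#' @param stats A [fit_norm_stats()] result.
#' @return `(values - mean) / sd` with the group's training-set
#'   statistics; shape preserved.
#' @export
apply_norm <- function(values, group, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  g <- stats$groups[[group]]
  if (is.null(g)) stop("unknown normalization group: ", group)
  (values - g$mean) / g$sd
}
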