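# Sensor fusion: probability averaging across per-modality networks
# (late fusion) and feature concatenation on a common 250-frame grid
# (early fusion).

#' Late fusion by probability averaging
#'
#' Averages the FM+ probabilities of one to three per-modality networks
#' and thresholds the mean at 0.5 (ties, `p = 0.5` exactly, classify as
#' FM+).
#'
#' @param probs Numeric vector of 1-3 probabilities in `[0, 1]`,
#'   optionally named by modality.
#' @return An object of class `fusion_decision`: list with
#'   `probabilities`, `fused_probability`, `label` (0/1) and
#'   `threshold`.
#' @export
late_fuse <- function(probs) {
  if (length(probs) < 1L || length(probs) > 3L) {
    stop("late_fuse expects 1-3 probabilities")
  }
  if (any(!is.finite(probs)) || any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  p_bar <- mean(probs)
  structure(list(probabilities = probs, fused_probability = p_bar,
                 label = as.integer(p_bar >= 0.5), threshold = 0.5),
            class = "fusion_decision")
}

#' Resample a feature matrix to a target frame count
#'
#' Linearly interpolates every column onto `target_frames` uniformly
#' spaced points spanning the original time extent; the first and last
#' rows are preserved exactly. Used to down-sample the 500-frame mat
#' and 300-frame IMU features to the 250-frame video grid before early
#' fusion.
#'
#' @param fm A [feature_matrix()] (or plain matrix) with at least 2
#'   rows.
#' @param target_frames Target number of rows (default 250).
#' @return A [feature_matrix()] with `target_frames` rows and unchanged
#'   channel names.
#' @export
resample_features <- function(fm, target_frames = 250L) {
  n <- nrow(fm)
  target_frames <- as.integer(target_frames)
  if (is.na(n) || n < 2L || target_frames < 2L) {
    stop("resampling needs at least 2 source and target frames")
  }
  x_old <- seq(0, 1, length.out = n)
  x_new <- seq(0, 1, length.out = target_frames)
  vals <- apply(unclass(fm), 2L, function(col) {
    stats::approx(x_old, col, xout = x_new)$y
  })
  if (inherits(fm, "feature_matrix")) {
    feature_matrix(vals, attr(fm, "modality"), colnames(fm),
                   attr(fm, "meta"))
  } else {
    vals
  }
}

#' Early fusion by feature concatenation
#'
#' Concatenates per-modality feature matrices column-wise in the fixed
#' order MAT (6), IMU (36), VID (60); with all three at the default
#' 250-frame grid the result is 250 x 102. All inputs must share one
#' frame count (resample first; see [resample_features()]).
#'
#' @param mats Named list of [feature_matrix()] objects (names from
#'   `MAT`, `IMU`, `VID`; any subset of size >= 1).
#' @return A [feature_matrix()] of modality `"FUSED"`.
#' @export
early_fuse <- function(mats) {
  stopifnot(is.list(mats), length(mats) >= 1L)
  order_wanted <- c("MAT", "IMU", "VID")
  mods <- vapply(mats, function(m) attr(m, "modality"), character(1))
  names(mats) <- mods
  mats <- mats[intersect(order_wanted, mods)]
  frames <- vapply(mats, nrow, integer(1))
  if (length(unique(frames)) != 1L) {
    bad <- names(frames)[frames != stats::median(frames)]
    stop("frame-count mismatch in early fusion: ",
         paste(names(frames), frames, sep = "=", collapse = ", "),
         " (offending: ", paste(bad, collapse = ", "), ")")
  }
  vals <- do.call(cbind, lapply(mats, unclass))
  chan <- unlist(lapply(names(mats), function(m) {
    paste0(m, ".", colnames(mats[[m]]))
  }), use.names = FALSE)
  feature_matrix(vals, "FUSED", chan, attr(mats[[1L]], "meta"))
}
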