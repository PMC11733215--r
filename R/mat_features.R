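# Pressure-mat feature pipeline: crop to the active 29 x 26 area, split
# into a shoulder/head (top, 12 x 26) and hip (bottom, 17 x 26) region,
# per-frame center of pressure and mean pressure per region, smoothing,
# and per-snippet [0, 1] normalization, giving the 500 x 6 matrix
# (x_t, y_t, p_t, x_b, y_b, p_b).

MAT_CROP_ROWS <- 1:29
MAT_CROP_COLS <- 4:29
MAT_TOP_ROWS <- 1:12    # within the crop
MAT_BOTTOM_ROWS <- 13:29

#' Crop the active mat area and split into top and bottom regions
#'
#' Keeps rows 1-29 and columns 4-29 (1-based, inclusive) of each 32x32
#' frame - the 29 x 26 = 754 sensors that are active under the infant -
#' and splits the crop into the top 12 rows (shoulders/head) and the
#' bottom 17 rows (hips).
#'
#' @param snippet A [pressure_snippet()].
#' @return List with `top` (frames x 12 x 26) and `bottom`
#'   (frames x 17 x 26) arrays.
#' @export
crop_and_split <- function(snippet) {
  stopifnot(inherits(snippet, "pressure_snippet"))
  crop <- snippet$values[, MAT_CROP_ROWS, MAT_CROP_COLS, drop = FALSE]
  list(top = crop[, MAT_TOP_ROWS, , drop = FALSE],
       bottom = crop[, MAT_BOTTOM_ROWS, , drop = FALSE])
}

#' Per-frame center of pressure and mean pressure of a region
#'
#' For each frame, `x` is the pressure-weighted mean column index, `y`
#' the pressure-weighted mean row index (both 1-based), and `p` the
#' total pressure divided by the fixed region size `m * n`. Frames with
#' zero total pressure carry the CoP forward from the last valid frame
#' (or use the region centroid if none exists); such events are counted
#' in the `n_zero_frames` attribute and logged when
#' `options(fmfusion.verbose = TRUE)`.
#'
#' @param region_frames Numeric array frames x m x n with non-negative
#'   values.
#' @return List of numeric series `x`, `y`, `p` (one value per frame),
#'   with attribute `n_zero_frames`.
#' @export
compute_cop <- function(region_frames) {
  d <- dim(region_frames)
  stopifnot(length(d) == 3L)
  if (any(region_frames < 0)) {
    stop("negative pressure values in region")
  }
  m <- d[2L]
  n <- d[3L]
  flat <- matrix(region_frames, d[1L], m * n)
  total <- rowSums(flat)
  wi <- rep(seq_len(m), times = n)
  wj <- rep(seq_len(n), each = m)
  x <- as.vector(flat %*% wj)
  y <- as.vector(flat %*% wi)
  zero <- total == 0
  x[!zero] <- x[!zero] / total[!zero]
  y[!zero] <- y[!zero] / total[!zero]
  if (any(zero)) {
    cx <- (n + 1) / 2
    cy <- (m + 1) / 2
    last_x <- cx
    last_y <- cy
    for (f in seq_len(d[1L])) {
      if (zero[f]) {
        x[f] <- last_x
        y[f] <- last_y
      } else {
        last_x <- x[f]
        last_y <- y[f]
      }
    }
    fm_log("zero-total-pressure frames: ", sum(zero),
           " (CoP carried forward)")
  }
  out <- list(x = x, y = y, p = total / (m * n))
  attr(out, "n_zero_frames") <- sum(zero)
  out
}

fm_log <- function(...) {
  if (isTRUE(getOption("fmfusion.verbose", FALSE))) message(...)
}

#' Normalize CoP coordinate series to [0, 1] with a shared range
#'
#' `gamma` is the largest of the four per-series ranges; each series is
#' mapped to `(s - min(s)) / gamma`, so all outputs lie in [0, 1] and at
#' least one spans the full unit interval. The shared denominator
#' preserves the relative movement amplitudes across series.
#'
#' @param xt,yt,xb,yb Smoothed CoP coordinate series.
#' @return List of the four normalized series plus `gamma`.
#' @export
normalize_cop <- function(xt, yt, xb, yb) {
  series <- list(xt = xt, yt = yt, xb = xb, yb = yb)
  ranges <- vapply(series, function(s) diff(range(s)), numeric(1))
  gamma <- max(ranges)
  if (gamma <= 0) {
    stop("degenerate input: no CoP movement in any series (gamma = 0)")
  }
  out <- lapply(series, function(s) (s - min(s)) / gamma)
  out$gamma <- gamma
  out
}

#' Normalize mean-pressure series to [0, 1] with a shared range
#'
#' `beta` is the larger of the two per-series ranges; each series is
#' mapped to `(s - min(s)) / beta`.
#'
#' @param pt,pb Smoothed mean-pressure series (top, bottom).
#' @return List of the two normalized series plus `beta`.
#' @export
normalize_pressure <- function(pt, pb) {
  beta <- max(diff(range(pt)), diff(range(pb)))
  if (beta <= 0) {
    stop("degenerate input: constant pressure in both regions",
         " (beta = 0)")
  }
  list(pt = (pt - min(pt)) / beta, pb = (pb - min(pb)) / beta,
       beta = beta)
}

#' Build the 500 x 6 pressure-mat feature matrix
#'
#' Full chain: crop and split, per-region CoP and mean pressure,
#' moving-average smoothing (window 5) of each of the six series, then
#' shared-range [0, 1] normalization of positions and pressures.
#' Columns are ordered `(x_t, y_t, p_t, x_b, y_b, p_b)`. With
#' `include_derivatives = TRUE` the six first-derivative series are
#' appended (ablation flag), doubling the width.
#'
#' @param snippet A [pressure_snippet()].
#' @param include_derivatives Append first-derivative columns (default
#'   `FALSE`).
#' @return A [feature_matrix()] of modality `"MAT"` (500 x 6, or
#'   500 x 12 with derivatives).
#' @export
build_mat_features <- function(snippet, include_derivatives = FALSE) {
  regions <- crop_and_split(snippet)
  top <- compute_cop(regions$top)
  bottom <- compute_cop(regions$bottom)
  sm <- function(s) smooth_series(s, 5L, "moving_average")
  pos <- normalize_cop(sm(top$x), sm(top$y), sm(bottom$x), sm(bottom$y))
  prs <- normalize_pressure(sm(top$p), sm(bottom$p))
  out <- cbind(pos$xt, pos$yt, prs$pt, pos$xb, pos$yb, prs$pb)
  names_out <- c("x_t", "y_t", "p_t", "x_b", "y_b", "p_b")
  if (include_derivatives) {
    out <- cbind(out, apply(out, 2L, central_diff))
    names_out <- c(names_out, paste0("d", names_out))
  }
  feature_matrix(out, "MAT", names_out, snippet$meta)
}
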