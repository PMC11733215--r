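# Seeded synthetic tri-modal movement simulator.
#
# Each snippet is driven by latent limb/trunk displacement trajectories
# built as sums of random-phase sinusoids: a slow large-amplitude
# baseline component (both classes) plus, for FM+ snippets only, a
# small-amplitude moderate-frequency "fidgety" component. The latents
# are rendered to (a) pose key points on a canonical supine skeleton,
# (b) two Gaussian pressure blobs (shoulders/head and hips) on a 32x32
# mat, and (c) per-sensor IMU accelerations (second finite differences,
# plus a constant gravity offset) and angular velocities (first
# differences of segment angles).

#' Simulator configuration
#'
#' Defines a synthetic cohort: its size, class balance, movement
#' amplitudes and bands, noise levels, per-infant random effects, and
#' missing-modality rate. Defaults mirror the recorded-study geometry
#' (36 cross-validation infants, FM+ prevalence 0.56 as in the 943/1683
#' annotated snippets) with amplitudes in pixel units of a 1080p supine
#' view.
#'
#' @param n_infants Number of infants.
#' @param snippets_per_infant Snippets recorded per infant.
#' @param p_fm_plus Probability that a snippet is FM+.
#' @param baseline_amp Baseline movement amplitude (pixels).
#' @param baseline_band Baseline frequency band (Hz), both classes.
#' @param fidgety_amp Amplitude (pixels) of the extra FM+ component;
#'   `0` makes the two classes identically distributed.
#' @param fidgety_band Fidgety frequency band (Hz).
#' @param keypoint_noise_sd Gaussian key-point jitter (pixels).
#' @param outlier_rate Per-frame per-key-point probability of a
#'   pose-estimation outlier spike.
#' @param outlier_magnitude Typical outlier spike size (pixels).
#' @param pressure_noise_sd Pressure sensor noise (sensor units).
#' @param imu_noise_sd IMU channel noise (channel units).
#' @param infant_effect_sd SD of the log-normal per-infant amplitude
#'   multiplier.
#' @param missing_modality_rate Probability that each modality of a
#'   snippet is independently missing (exercises the synchronization
#'   filter).
#' @param split_signal If `TRUE`, three mutually independent fidgety
#'   components are drawn and each is expressed in exactly one modality,
#'   so every modality alone carries a weak independent class signal.
#' @param seed Master seed; per-snippet substreams are derived from it
#'   so any subset regenerates identically.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_infants = 36L, snippets_per_infant = 20L,
                       p_fm_plus = 0.56,
                       baseline_amp = 40, baseline_band = c(0.1, 0.5),
                       fidgety_amp = 18, fidgety_band = c(1.0, 3.0),
                       keypoint_noise_sd = 2, outlier_rate = 0.002,
                       outlier_magnitude = 150,
                       pressure_noise_sd = 1, imu_noise_sd = 0.3,
                       infant_effect_sd = 0.15,
                       missing_modality_rate = 0,
                       split_signal = FALSE, seed = 1L) {
  cfg <- list(n_infants = as.integer(n_infants),
              snippets_per_infant = as.integer(snippets_per_infant),
              p_fm_plus = p_fm_plus, baseline_amp = baseline_amp,
              baseline_band = baseline_band, fidgety_amp = fidgety_amp,
              fidgety_band = fidgety_band,
              keypoint_noise_sd = keypoint_noise_sd,
              outlier_rate = outlier_rate,
              outlier_magnitude = outlier_magnitude,
              pressure_noise_sd = pressure_noise_sd,
              imu_noise_sd = imu_noise_sd,
              infant_effect_sd = infant_effect_sd,
              missing_modality_rate = missing_modality_rate,
              split_signal = isTRUE(split_signal),
              seed = as.integer(seed))
  rates <- c(cfg$p_fm_plus, cfg$outlier_rate, cfg$missing_modality_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  amps <- c(cfg$baseline_amp, cfg$fidgety_amp, cfg$keypoint_noise_sd,
            cfg$outlier_magnitude, cfg$pressure_noise_sd,
            cfg$imu_noise_sd, cfg$infant_effect_sd)
  if (any(amps < 0)) stop("amplitudes and noise SDs must be >= 0")
  for (band in list(cfg$baseline_band, cfg$fidgety_band)) {
    if (length(band) != 2L || band[1] <= 0 || band[2] < band[1] ||
        band[2] >= VID_RATE / 2) {
      stop("frequency bands must lie within (0, Nyquist of the slowest",
           " modality)")
    }
  }
  if (cfg$n_infants < 1L || cfg$snippets_per_infant < 1L) {
    stop("n_infants and snippets_per_infant must be positive")
  }
  structure(cfg, class = "sim_config")
}

# Canonical supine skeleton in pixels, mathematical y-up convention
# (head toward larger y). Order matches KEYPOINT_NAMES.
BASE_SKELETON <- matrix(c(
  960, 700,   # nose
  940, 715,   # l_eye
  980, 715,   # r_eye
  900, 640,   # l_shoulder
  1020, 640,  # r_shoulder
  860, 570,   # l_elbow
  1060, 570,  # r_elbow
  840, 500,   # l_wrist
  1080, 500,  # r_wrist
  920, 440,   # l_hip
  1000, 440,  # r_hip
  900, 360,   # l_knee
  1020, 360,  # r_knee
  880, 280,   # l_ankle
  1040, 280   # r_ankle
), ncol = 2L, byrow = TRUE)

# A latent displacement channel: sum of random-phase sinusoids per axis.
draw_sinusoids <- function(n, band, amp) {
  list(amp = amp * runif(n, 0.5, 1),
       freq = runif(n, band[1], band[2]),
       phase = runif(n, 0, 2 * pi))
}

eval_sinusoids <- function(par, t) {
  out <- numeric(length(t))
  for (i in seq_along(par$amp)) {
    out <- out + par$amp[i] * sin(2 * pi * par$freq[i] * t +
                                    par$phase[i])
  }
  out
}

# Latent channels for one snippet. Baseline components move everything;
# the fidgety component is added to the distal limb channels (wrists,
# ankles; half amplitude on elbows and knees) when label == FM+.
# `which_fid` selects which modality's independent fidgety draw is
# active ("all" shares one draw across modalities).
draw_latents <- function(config, infant_effect, label) {
  chans <- c("trunk", "head", "l_elbow", "r_elbow", "l_wrist", "r_wrist",
             "l_knee", "r_knee", "l_ankle", "r_ankle")
  scales <- c(trunk = 0.25, head = 0.3, l_elbow = 0.6, r_elbow = 0.6,
              l_wrist = 1, r_wrist = 1, l_knee = 0.6, r_knee = 0.6,
              l_ankle = 1, r_ankle = 1)
  fid_scales <- c(trunk = 0.3, head = 0, l_elbow = 0.5, r_elbow = 0.5,
                  l_wrist = 1, r_wrist = 1, l_knee = 0.5, r_knee = 0.5,
                  l_ankle = 1, r_ankle = 1)
  base <- lapply(chans, function(ch) {
    list(x = draw_sinusoids(3L, config$baseline_band,
                            config$baseline_amp * scales[[ch]] *
                              infant_effect),
         y = draw_sinusoids(3L, config$baseline_band,
                            config$baseline_amp * scales[[ch]] *
                              infant_effect))
  })
  names(base) <- chans
  n_fid_sets <- if (config$split_signal) 3L else 1L
  # in split mode the IMU-expressed component is attenuated: finite
  # differencing amplifies the fidgety band by (2*pi*f)^2, so without
  # attenuation the IMU signal would dominate instead of being
  # comparably weak to the other modalities
  split_scale <- c(1, 1, 0.12)
  fid <- lapply(seq_len(n_fid_sets), function(s) {
    f <- lapply(chans, function(ch) {
      amp <- if (label == 1L) {
        config$fidgety_amp * fid_scales[[ch]] * infant_effect *
          (if (config$split_signal) split_scale[s] else 1)
      } else 0
      list(x = draw_sinusoids(2L, config$fidgety_band, amp),
           y = draw_sinusoids(2L, config$fidgety_band, amp))
    })
    names(f) <- chans
    f
  })
  list(base = base, fid = fid)
}

# Displacement of one channel at times t, for the modality-specific
# fidgety set (1 = VID, 2 = MAT, 3 = IMU when split_signal, else 1).
latent_disp <- function(latents, chan, t, fid_set = 1L) {
  fid_set <- min(fid_set, length(latents$fid))
  cbind(eval_sinusoids(latents$base[[chan]]$x, t) +
          eval_sinusoids(latents$fid[[fid_set]][[chan]]$x, t),
        eval_sinusoids(latents$base[[chan]]$y, t) +
          eval_sinusoids(latents$fid[[fid_set]][[chan]]$y, t))
}

# Map key points to the latent channel driving them (trunk moves all).
KP_CHANNEL <- c(nose = "head", l_eye = "head", r_eye = "head",
                l_shoulder = NA, r_shoulder = NA,
                l_elbow = "l_elbow", r_elbow = "r_elbow",
                l_wrist = "l_wrist", r_wrist = "r_wrist",
                l_hip = NA, r_hip = NA,
                l_knee = "l_knee", r_knee = "r_knee",
                l_ankle = "l_ankle", r_ankle = "r_ankle")

render_keypoints <- function(config, latents, t, fid_set) {
  n <- length(t)
  vals <- array(0, dim = c(n, 15L, 2L))
  trunk <- latent_disp(latents, "trunk", t, fid_set)
  for (k in seq_len(15L)) {
    disp <- trunk
    ch <- KP_CHANNEL[[KEYPOINT_NAMES[k]]]
    if (!is.na(ch)) disp <- disp + latent_disp(latents, ch, t, fid_set)
    vals[, k, 1L] <- BASE_SKELETON[k, 1L] + disp[, 1L]
    vals[, k, 2L] <- BASE_SKELETON[k, 2L] + disp[, 2L]
  }
  vals <- vals + array(rnorm(n * 30L, 0, config$keypoint_noise_sd),
                       dim = dim(vals))
  n_out <- stats::rbinom(1L, n * 15L, config$outlier_rate)
  if (n_out > 0L) {
    frames <- sample.int(n, n_out, replace = TRUE)
    kps <- sample.int(15L, n_out, replace = TRUE)
    for (i in seq_len(n_out)) {
      vals[frames[i], kps[i], ] <- vals[frames[i], kps[i], ] +
        rnorm(2L, 0, config$outlier_magnitude)
    }
  }
  vals
}

GRID_PER_PX <- 0.08  # pressure-grid cells per pixel of latent motion

render_pressure <- function(config, latents, t, fid_set) {
  n <- length(t)
  trunk <- latent_disp(latents, "trunk", t, fid_set)
  ank <- (latent_disp(latents, "l_ankle", t, fid_set) +
            latent_disp(latents, "r_ankle", t, fid_set)) / 2
  # blob centers in grid coordinates; row 1 is the head end
  top_i <- 8 - GRID_PER_PX * trunk[, 2L]
  top_j <- 16.5 + GRID_PER_PX * trunk[, 1L]
  bot_i <- 21 - GRID_PER_PX * (0.7 * trunk[, 2L] + 0.5 * ank[, 2L])
  bot_j <- 16.5 + GRID_PER_PX * (0.7 * trunk[, 1L] + 0.5 * ank[, 1L])
  amp_top <- 60 + 0.1 * trunk[, 2L]
  amp_bot <- 80 + 0.1 * ank[, 2L]
  sigma2 <- 2.5^2
  blob <- function(ci, cj, amp) {
    ei <- exp(-outer(ci, 1:32, "-")^2 / (2 * sigma2)) * amp   # n x 32
    ej <- exp(-outer(cj, 1:32, "-")^2 / (2 * sigma2))         # n x 32
    ei[, rep(1:32, times = 32)] * ej[, rep(1:32, each = 32)]  # n x 1024
  }
  flat <- blob(top_i, top_j, amp_top) + blob(bot_i, bot_j, amp_bot) +
    matrix(rnorm(n * 1024L, 0, config$pressure_noise_sd), n, 1024L)
  pmax(array(flat, dim = c(n, 32L, 32L)), 0)
}

M_PER_PX <- 0.0015  # meters per pixel at crib distance
GRAVITY <- 9.81

# sensor -> (attachment channel, segment endpoints for the gyro angle)
IMU_ATTACH <- list(
  l_shoulder = list(point = "trunk", seg = c("trunk", "l_elbow")),
  r_shoulder = list(point = "trunk", seg = c("trunk", "r_elbow")),
  l_hip = list(point = "trunk", seg = c("trunk", "l_knee")),
  r_hip = list(point = "trunk", seg = c("trunk", "r_knee")),
  l_foot = list(point = "l_ankle", seg = c("l_knee", "l_ankle")),
  r_foot = list(point = "r_ankle", seg = c("r_knee", "r_ankle"))
)

second_diff <- function(x) {
  n <- length(x)
  dd <- numeric(n)
  dd[2:(n - 1L)] <- x[3:n] - 2 * x[2:(n - 1L)] + x[1:(n - 2L)]
  dd[1L] <- dd[2L]
  dd[n] <- dd[n - 1L]
  dd
}

first_diff <- function(x) {
  n <- length(x)
  c(x[2L] - x[1L], x[2:n] - x[1:(n - 1L)])
}

render_imu <- function(config, latents, t, fid_set) {
  n <- length(t)
  rate <- IMU_RATE
  vals <- array(0, dim = c(n, 6L, 6L))
  for (s in seq_along(IMU_SENSOR_ORDER)) {
    att <- IMU_ATTACH[[IMU_SENSOR_ORDER[s]]]
    pos <- latent_disp(latents, att$point, t, fid_set) * M_PER_PX
    # z motion: reuse the attachment channel with a fixed mixing so the
    # vertical axis carries correlated (and, for limbs, fidgety) motion
    posz <- 0.5 * pos[, 1L] + 0.3 * pos[, 2L]
    acc <- cbind(second_diff(pos[, 1L]), second_diff(pos[, 2L]),
                 second_diff(posz)) * rate^2
    g_dir <- rnorm(3L)
    g_dir <- g_dir / sqrt(sum(g_dir^2))
    acc <- acc + matrix(GRAVITY * g_dir, n, 3L, byrow = TRUE)
    acc <- acc + matrix(rnorm(n * 3L, 0, config$imu_noise_sd), n, 3L)
    seg <- latent_disp(latents, att$seg[2L], t, fid_set) -
      if (att$seg[1L] == "trunk") latent_disp(latents, "trunk", t,
                                              fid_set) * 0
      else latent_disp(latents, att$seg[1L], t, fid_set)
    base_vec <- BASE_SKELETON[match(sub("trunk", "l_hip", att$seg[2L]),
                                    KEYPOINT_NAMES), ] -
      BASE_SKELETON[match(sub("trunk", "l_hip", att$seg[1L]),
                          KEYPOINT_NAMES), ]
    ang <- atan2(base_vec[2L] + seg[, 2L], base_vec[1L] + seg[, 1L])
    omega <- first_diff(ang) * rate
    axis <- rnorm(3L)
    axis <- axis / sqrt(sum(axis^2))
    gyr <- outer(omega, axis) +
      matrix(rnorm(n * 3L, 0, config$imu_noise_sd), n, 3L)
    vals[, s, 1:3] <- acc
    vals[, s, 4:6] <- gyr
  }
  vals
}

#' Simulate one synchronized tri-modal snippet
#'
#' Draws latent movement trajectories for the given class label and
#' renders all three modalities. Uses the current R RNG state; callers
#' wanting per-snippet reproducibility should seed beforehand (as
#' [generate_dataset()] does with derived substreams).
#'
#' @param config A [sim_config()].
#' @param label `1` (FM+) or `0` (FM-).
#' @param infant_effect Multiplicative per-infant amplitude effect.
#' @param meta A [snippet_meta()]; defaults to a generic one.
#' @return A [snippet_triple()] with all three modalities present.
#' @export
simulate_snippet <- function(config, label, infant_effect = 1,
                             meta = snippet_meta("s1", "i1",
                                                 label = label)) {
  stopifnot(inherits(config, "sim_config"), label %in% c(0L, 1L))
  latents <- draw_latents(config, infant_effect, as.integer(label))
  t_vid <- seq(0, by = 1 / VID_RATE, length.out = VID_RATE * 5L)
  t_mat <- seq(0, by = 1 / MAT_RATE, length.out = MAT_RATE * 5L)
  t_imu <- seq(0, by = 1 / IMU_RATE, length.out = IMU_RATE * 5L)
  kp <- keypoint_snippet(render_keypoints(config, latents, t_vid, 1L),
                         meta)
  pr <- pressure_snippet(render_pressure(config, latents, t_mat, 2L),
                         meta)
  im <- imu_snippet(render_imu(config, latents, t_imu, 3L), meta)
  snippet_triple(meta, keypoints = kp, pressure = pr, imu = im)
}

snippet_seed <- function(master, counter) {
  as.integer((as.double(master) * 1009 + counter * 2003) %% 2147483629)
}

#' Generate a full synthetic cohort
#'
#' `n_infants * snippets_per_infant` triples; labels i.i.d.
#' Bernoulli(`p_fm_plus`); each infant carries a multiplicative
#' LogNormal(0, `infant_effect_sd`) amplitude effect; each modality of
#' each snippet is independently deleted with `missing_modality_rate`.
#' Fully reproducible from `config$seed`, including any subset (each
#' snippet uses a substream derived from the master seed and its index).
#'
#' @param config A [sim_config()].
#' @return An [fm_dataset()].
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_total <- config$n_infants * config$snippets_per_infant
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  effects <- stats::rlnorm(config$n_infants, 0, config$infant_effect_sd)
  labels <- stats::rbinom(n_total, 1L, config$p_fm_plus)
  missing <- matrix(stats::runif(n_total * 3L) <
                      config$missing_modality_rate, n_total, 3L)
  triples <- vector("list", n_total)
  idx <- 0L
  for (i in seq_len(config$n_infants)) {
    infant_id <- sprintf("infant%02d", i)
    for (s in seq_len(config$snippets_per_infant)) {
      idx <- idx + 1L
      meta <- snippet_meta(sprintf("%s_s%03d", infant_id, s), infant_id,
                           session = sample(c("T5", "T6", "T7"), 1L),
                           label = labels[idx])
      set.seed(snippet_seed(config$seed, idx))
      tr <- simulate_snippet(config, labels[idx], effects[i], meta)
      if (missing[idx, 1L]) tr$keypoints <- NULL
      if (missing[idx, 2L]) tr$pressure <- NULL
      if (missing[idx, 3L]) tr$imu <- NULL
      triples[[idx]] <- tr
    }
  }
  fm_dataset(triples)
}
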