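test_that("serialization round-trip is bit-exact, including absent modalities", {
  ds <- dataset_fix(n_infants = 2L, snippets_per_infant = 2L, seed = 3L)
  ds$triples[[2L]]$pressure <- NULL        # declared-missing modality
  ds <- fm_dataset(ds$triples)
  dir <- withr::local_tempdir()
  manifest <- write_dataset(ds, dir)
  ds2 <- read_dataset(manifest)
  expect_equal(length(ds2), length(ds))
  for (i in seq_along(ds$triples)) {
    a <- ds$triples[[i]]
    b <- ds2$triples[[i]]
    expect_identical(a$meta$snippet_id, b$meta$snippet_id)
    expect_identical(a$meta$label, b$meta$label)
    expect_identical(is.null(a$pressure), is.null(b$pressure))
    if (!is.null(a$keypoints)) {
      expect_identical(a$keypoints$values, b$keypoints$values)
    }
    if (!is.null(a$pressure)) {
      expect_identical(a$pressure$values, b$pressure$values)
    }
    if (!is.null(a$imu)) {
      expect_identical(a$imu$values, b$imu$values)
    }
  }
  # empty dataset round-trips too
  dir2 <- withr::local_tempdir()
  m2 <- write_dataset(fm_dataset(), dir2)
  expect_equal(length(read_dataset(m2)), 0L)
})

test_that("read_dataset rejects malformed inputs with named errors", {
  ds <- dataset_fix(n_infants = 1L, snippets_per_infant = 1L, seed = 4L)
  dir <- withr::local_tempdir()
  manifest <- write_dataset(ds, dir)
  # truncate the key-point file to 240 frames
  kp_file <- file.path(dir, paste0(ds$triples[[1L]]$meta$snippet_id,
                                   "_keypoints.tsv"))
  writeLines(head(readLines(kp_file), 240L), kp_file)
  expect_error(read_dataset(manifest), "keypoints")
  # missing file
  file.remove(kp_file)
  expect_error(read_dataset(manifest), "missing array file")
  expect_error(read_dataset(file.path(dir, "nope.json")), "not found")
})

test_that("unknown label strings are rejected and FM labels map 0/1", {
  expect_identical(fmfusion:::string_to_label("FM+"), 1L)
  expect_identical(fmfusion:::string_to_label("FM-"), 0L)
  expect_true(is.na(fmfusion:::string_to_label("NA")))
  expect_error(fmfusion:::string_to_label("maybe"), "unknown label")
})

test_that("filter_synchronized drops incomplete and unlabeled triples, keeps order, is idempotent", {
  triples <- lapply(1:10, function(i) {
    tr <- sim_triple_fix(label = i %% 2L, seed = 100L + i)
    tr$meta$snippet_id <- sprintf("s%02d", i)
    tr$keypoints$meta <- tr$meta
    tr$pressure$meta <- tr$meta
    tr$imu$meta <- tr$meta
    tr
  })
  triples[[2L]]$imu <- NULL
  triples[[7L]]$imu <- NULL
  ds <- fm_dataset(triples)
  all3 <- filter_synchronized(ds, c("VID", "MAT", "IMU"))
  expect_equal(length(all3), 8L)
  expect_equal(length(filter_synchronized(ds, "VID")), 10L)
  # order preserved
  ids <- vapply(all3$triples, function(t) t$meta$snippet_id,
                character(1))
  expect_identical(ids, sort(ids))
  # idempotent, never increases
  expect_equal(length(filter_synchronized(all3, c("VID", "MAT", "IMU"))),
               8L)
  # NA labels dropped
  ds$triples[[1L]]$meta$label <- NA_integer_
  expect_equal(length(filter_synchronized(ds, c("VID", "MAT", "IMU"))),
               7L)
})

test_that("smooth_series handles medians, averages, edges and degenerate windows", {
  expect_equal(smooth_series(rep(3, 20), 5, "median"), rep(3, 20))
  expect_equal(smooth_series(rep(3, 20), 5, "moving_average"),
               rep(3, 20))
  # impulse removed by the median at the center
  expect_equal(smooth_series(c(0, 0, 10, 0, 0), 5, "median")[3L], 0)
  # window 1 is the identity
  x <- rnorm(10)
  expect_identical(smooth_series(x, 1, "median"), x)
  expect_identical(smooth_series(x, 1, "moving_average"), x)
  # truncated centered windows at the edges
  x <- c(5, 1, 2, 3, 4, 0)
  ma <- smooth_series(x, 5, "moving_average")
  expect_equal(ma[1L], mean(x[1:3]))
  expect_equal(ma[2L], mean(x[1:4]))
  expect_equal(ma[6L], mean(x[4:6]))
  md <- smooth_series(x, 5, "median")
  expect_equal(md[1L], median(x[1:3]))
  expect_equal(md[3L], median(x[1:5]))
  expect_error(smooth_series(x, 4), "odd")
  expect_error(smooth_series(x, -1), "odd")
  expect_error(smooth_series(x, 7), "exceeds")
})

test_that("smoothing commutes with constants; moving average preserves ramps in the interior", {
  set.seed(1)
  for (i in 1:5) {
    x <- rnorm(50)
    c0 <- runif(1, -10, 10)
    for (kind in c("median", "moving_average")) {
      expect_equal(smooth_series(x + c0, 5, kind),
                   smooth_series(x, 5, kind) + c0, tolerance = 1e-12)
    }
  }
  ramp <- seq(0, 1, length.out = 40)
  sm <- smooth_series(ramp, 5, "moving_average")
  expect_equal(sm[3:38], ramp[3:38], tolerance = 1e-12)
})

test_that("pooled z-score statistics use the population sd and fail on degenerate groups", {
  # [1,1] and [3,3] pooled: mean 2, population sd 1
  st <- fit_norm_stats(list(g = list(c(1, 1), c(3, 3))))
  expect_equal(st$groups$g$mean, 2)
  expect_equal(st$groups$g$sd, 1)
  expect_error(fit_norm_stats(list(g = list(c(2, 2, 2)))),
               "zero pooled variance")
  # groups are fitted independently
  st2 <- fit_norm_stats(list(g = list(c(1, 1), c(3, 3)),
                             h = list(c(-50, 50))))
  expect_equal(st2$groups$g, st$groups$g)
})

test_that("apply_norm is the z-score identity on the training pool", {
  set.seed(2)
  series <- lapply(1:4, function(i) rnorm(100, mean = 3, sd = 2))
  st <- fit_norm_stats(list(position = series))
  pool <- unlist(lapply(series, apply_norm, group = "position",
                        stats = st))
  expect_equal(mean(pool), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean((pool - mean(pool))^2)), 1, tolerance = 1e-9)
  # identity stats
  st$groups$position$mean <- 0
  st$groups$position$sd <- 1
  expect_identical(apply_norm(series[[1L]], "position", st),
                   series[[1L]])
  expect_error(apply_norm(1:3, "nope", st), "unknown normalization")
  # test values under training stats differ from their own z-score
  test_vals <- rnorm(50, mean = 10, sd = 5)
  st3 <- fit_norm_stats(list(position = series))
  normed <- apply_norm(test_vals, "position", st3)
  expect_gt(abs(mean(normed)), 0.5)
})

test_that("snippet containers enforce shapes and metadata consistency", {
  expect_error(keypoint_snippet(array(0, c(240, 15, 2)), meta_fix()),
               "250x15x2")
  expect_error(pressure_snippet(array(-1, c(500, 32, 32)), meta_fix()),
               "negative")
  expect_error(imu_snippet(array(NA_real_, c(300, 6, 6)), meta_fix()),
               "non-finite")
  expect_error(snippet_meta("a", "b", session = "T9"), "session")
  expect_error(snippet_meta("a", "b", label = 2), "label")
  other <- kp_fix(meta = meta_fix(id = "other"))
  expect_error(snippet_triple(meta_fix(), keypoints = other),
               "does not match")
  expect_error(fm_dataset(list(sim_triple_fix(), sim_triple_fix())),
               "duplicate")
})
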