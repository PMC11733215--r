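# small separable fixture: class 1 carries a 3 Hz sinusoid in channel 1
toy_cohort <- function(n = 120L, frames = 100L, channels = 4L,
                       seed = 2L, signal = 2) {
  set.seed(seed)
  arr <- array(rnorm(frames * channels * n), c(frames, channels, n))
  y <- rbinom(n, 1L, 0.5)
  t <- seq(0, 2, length.out = frames)
  for (i in which(y == 1L)) {
    arr[, 1L, i] <- arr[, 1L, i] +
      signal * sin(2 * pi * 3 * t + runif(1, 0, 2 * pi))
  }
  list(arr = arr, y = y)
}

tiny_cnn <- cnn_config(conv_layers = list(c(4L, 3L)), fc_units = 8L)

test_that("model building validates configuration against the input shape", {
  m <- build_model(cnn_config_small(), c(250L, 60L))
  expect_s3_class(m, "fm_cnn")
  expect_error(build_model(cnn_config(conv_layers = list(c(4L, 99L))),
                           c(50L, 4L)), "kernel size exceeds")
  expect_error(cnn_config(dropout_rate = 1), "dropout")
  # parameter count is a deterministic function of the config
  expect_identical(count_params(m), count_params(m))
  expect_gt(count_params(build_model(cnn_config(), c(250L, 60L))),
            count_params(m))
})

test_that("an untrained forward pass yields one finite logit per snippet", {
  m <- build_model(cnn_config(conv_layers = list(c(32L, 5L), c(32L, 5L),
                                                 c(32L, 5L)),
                              fc_units = 64L), c(250L, 60L))
  w <- init_weights(m, seed = 3L)
  arr <- array(rnorm(250 * 60 * 2), c(250L, 60L, 2L))
  clf <- structure(list(config = m$config, input_shape = m$input_shape,
                        weights = w),
                   class = "trained_classifier")
  p <- predict_proba(clf, arr)
  expect_length(p, 2L)
  expect_true(all(is.finite(p) & p > 0 & p < 1))
  # identical inputs give identical outputs
  expect_identical(p, predict_proba(clf, arr))
  expect_error(predict_proba(clf, array(0, c(100L, 60L, 1L))),
               "does not match")
})

test_that("the forward pass matches a hand-computed Conv/FC oracle", {
  # 1 conv layer (1 kernel of size 3), fc 2, no BN, no dropout,
  # input 5 frames x 1 channel
  cfg <- cnn_config(conv_layers = list(c(1L, 3L)), fc_units = 2L,
                    dropout_rate = 0, batch_norm = FALSE)
  m <- build_model(cfg, c(5L, 1L))
  w <- init_weights(m, seed = 1L)
  w$conv[[1L]]$W <- matrix(c(0.5, -1, 2), ncol = 1L)  # taps d=-1,0,+1
  w$conv[[1L]]$b <- 0.1
  w$fc$W <- matrix(seq(-0.5, 0.6, length.out = 10L), nrow = 5L)
  w$fc$b <- c(0.2, -0.3)
  w$out$W <- matrix(c(1.5, -0.7), ncol = 1L)
  w$out$b <- 0.25
  x <- c(1, -2, 3, 0.5, -1)
  xpad <- c(0, x, 0)
  conv <- vapply(1:5, function(t) {
    sum(c(0.5, -1, 2) * xpad[t:(t + 2L)]) + 0.1
  }, numeric(1))
  relu1 <- pmax(conv, 0)
  fc <- pmax(as.vector(relu1 %*% w$fc$W) + w$fc$b, 0)
  logit <- sum(fc * w$out$W) + 0.25
  clf <- structure(list(config = cfg, input_shape = c(5L, 1L),
                        weights = w),
                   class = "trained_classifier")
  got <- predict_proba(clf, array(x, c(5L, 1L, 1L)))
  expect_equal(got, plogis(logit), tolerance = 1e-12)
})

test_that("training is reproducible bit-wise from the seed", {
  toy <- toy_cohort(n = 60L, seed = 5L)
  m <- build_model(tiny_cnn, c(100L, 4L))
  tc <- train_config(n_restarts = 1L, max_epochs = 8L, seed = 11L)
  f1 <- train_model(m, toy$arr, toy$y, tc)
  f2 <- train_model(m, toy$arr, toy$y, tc)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$training_log, f2$training_log)
  # a different seed gives different weights
  tc2 <- tc
  tc2$seed <- 12L
  f3 <- train_model(m, toy$arr, toy$y, tc2)
  expect_false(identical(f1$weights, f3$weights))
})

test_that("a separable cohort is learned to high training accuracy", {
  toy <- toy_cohort(n = 120L, seed = 2L, signal = 2)
  m <- build_model(tiny_cnn, c(100L, 4L))
  tc <- train_config(n_restarts = 1L, max_epochs = 30L, seed = 5L)
  clf <- train_model(m, toy$arr, toy$y, tc)
  pred <- as.integer(predict_proba(clf, toy$arr) >= 0.5)
  ba <- (mean(pred[toy$y == 1L] == 1L) +
           mean(pred[toy$y == 0L] == 0L)) / 2
  expect_gte(ba, 0.95)
})

test_that("shuffled labels keep the validation loss near chance level", {
  toy <- toy_cohort(n = 120L, seed = 7L, signal = 2)
  set.seed(8)
  y_perm <- sample(toy$y)
  m <- build_model(tiny_cnn, c(100L, 4L))
  tc <- train_config(n_restarts = 1L, max_epochs = 20L, seed = 9L)
  clf <- train_model(m, toy$arr, y_perm, tc)
  # no-signal control: best val loss cannot drop materially below ln 2
  expect_gt(clf$best_val_loss, 0.5)
})

test_that("training rejects degenerate label sets", {
  toy <- toy_cohort(n = 20L, seed = 3L)
  m <- build_model(tiny_cnn, c(100L, 4L))
  tc <- train_config(n_restarts = 1L, max_epochs = 2L, seed = 1L)
  expect_error(train_model(m, toy$arr, rep(1L, 20L), tc),
               "per class")
  expect_error(train_model(m, toy$arr, toy$y[1:5], tc),
               "labels length")
})

test_that("restart selection returns the minimum validation loss, ties to the earliest", {
  toy <- toy_cohort(n = 60L, seed = 4L)
  m <- build_model(tiny_cnn, c(100L, 4L))
  tc1 <- train_config(n_restarts = 1L, max_epochs = 6L, seed = 21L)
  single <- train_model(m, toy$arr, toy$y, tc1)
  multi1 <- train_with_restarts(m, toy$arr, toy$y, tc1)
  expect_identical(single$weights, multi1$weights)
  tc3 <- train_config(n_restarts = 3L, max_epochs = 6L, seed = 21L)
  multi <- train_with_restarts(m, toy$arr, toy$y, tc3)
  per_restart <- vapply(1:3, function(r) {
    tcr <- tc1
    tcr$seed <- fmfusion:::restart_seed(21L, r)
    train_model(m, toy$arr, toy$y, tcr)$best_val_loss
  }, numeric(1))
  expect_equal(multi$best_val_loss, min(per_restart))
  expect_identical(attr(multi, "restart"),
                   which.min(per_restart)[[1L]])
  # same master seed selects the same restart
  multi2 <- train_with_restarts(m, toy$arr, toy$y, tc3)
  expect_identical(attr(multi, "restart"), attr(multi2, "restart"))
})

test_that("grid search ranks configurations by validation loss", {
  toy <- toy_cohort(n = 80L, seed = 6L, signal = 3)
  crippled <- cnn_config(conv_layers = list(c(1L, 1L)), fc_units = 1L)
  tc <- train_config(n_restarts = 1L, max_epochs = 12L, seed = 2L)
  one <- grid_search_light(toy$arr, toy$y, list(tiny_cnn), tc)
  expect_length(one, 1L)
  ranked <- grid_search_light(toy$arr, toy$y, list(crippled, tiny_cnn),
                              tc)
  losses <- vapply(ranked, `[[`, numeric(1), "val_loss")
  expect_true(!is.unsorted(losses))
  expect_identical(ranked[[1L]]$config$fc_units, tiny_cnn$fc_units)
})

test_that("classifier checkpoints round-trip through JSON", {
  toy <- toy_cohort(n = 40L, seed = 12L)
  m <- build_model(tiny_cnn, c(100L, 4L))
  tc <- train_config(n_restarts = 1L, max_epochs = 4L, seed = 3L)
  clf <- train_model(m, toy$arr, toy$y, tc,
                     norm_stats = fit_norm_stats(
                       list(position = list(c(1, 2, 3)))))
  path <- withr::local_tempfile(fileext = ".json")
  save_classifier(clf, path)
  clf2 <- load_classifier(path)
  expect_equal(predict_proba(clf2, toy$arr),
               predict_proba(clf, toy$arr), tolerance = 1e-12)
  expect_equal(clf2$best_val_loss, clf$best_val_loss)
  expect_equal(clf2$norm_stats$groups$position$mean, 2)
})
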