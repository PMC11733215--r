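# independent enumeration oracle: loop over every sign assignment
wilcoxon_oracle <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  Ws <- as.vector(signs %*% r)
  min(1, 2 * min(mean(Ws <= W + 1e-9), mean(Ws >= W - 1e-9)))
}

test_that("subject-disjoint folds partition the infants exactly", {
  infants <- sprintf("i%02d", 1:36)
  folds <- make_folds(infants, k = 9L, infants_per_fold = 4L, seed = 3L)
  expect_length(folds, 9L)
  test_sets <- lapply(folds, `[[`, "test_infants")
  expect_true(all(lengths(test_sets) == 4L))
  expect_setequal(unlist(test_sets), infants)
  expect_equal(anyDuplicated(unlist(test_sets)), 0L)
  for (f in folds) {
    expect_length(intersect(f$train_infants, f$test_infants), 0L)
    expect_setequal(c(f$train_infants, f$test_infants), infants)
  }
  # seeded determinism
  expect_identical(folds, make_folds(infants, seed = 3L))
  expect_false(identical(folds, make_folds(infants, seed = 4L)))
  expect_error(make_folds(infants[1:35]), "configuration error")
})

test_that("confusion metrics follow the TPR/TNR/BA definitions", {
  m <- classification_metrics(confusion_counts(TP = 9, FN = 1, TN = 8,
                                               FP = 2))
  expect_equal(m$TPR, 0.9)
  expect_equal(m$TNR, 0.8)
  expect_equal(m$BA, 0.85)
  perfect <- classification_metrics(confusion_counts(10, 10, 0, 0))
  expect_equal(perfect$BA, 1)
  # the always-FM+ predictor scores BA 0.5 on a mixed set
  naive <- classification_metrics(confusion_counts(TP = 7, TN = 0,
                                                   FP = 5, FN = 0))
  expect_equal(naive$TPR, 1)
  expect_equal(naive$TNR, 0)
  expect_equal(naive$BA, 0.5)
  expect_error(classification_metrics(confusion_counts(0, 5, 3, 0)),
               "undefined")
  expect_error(confusion_counts(-1, 2, 3, 4), "non-negative")
  # BA invariant to swapping the class labeling (TPR/TNR swap)
  sw <- classification_metrics(confusion_counts(TP = 8, TN = 9, FP = 1,
                                                FN = 2))
  expect_equal(sw$BA, m$BA)
})

test_that("the t-based confidence interval matches the textbook formula", {
  x <- c(0.91, 0.84, 0.88, 0.95, 0.79, 0.90, 0.86, 0.93, 0.87)
  ci <- mean_ci95(x)
  half <- qt(0.975, 8) * sd(x) / 3
  expect_equal(ci$mean, mean(x))
  expect_equal(ci$lower, mean(x) - half)
  expect_equal(ci$upper, mean(x) + half)
  expect_true(ci$lower <= ci$mean && ci$mean <= ci$upper)
  # identical values give a zero-width interval
  same <- mean_ci95(rep(0.8, 5))
  expect_equal(same$lower, 0.8)
  expect_equal(same$upper, 0.8)
  expect_error(mean_ci95(0.5), "at least 2")
})

test_that("the exact Wilcoxon test reproduces the forced n = 9 extremes", {
  # nine differences of one sign with distinct magnitudes
  a <- c(0.95, 0.92, 0.96, 0.93, 0.91, 0.97, 0.94, 0.90, 0.98)
  b <- a - c(0.05, 0.04, 0.06, 0.03, 0.02, 0.07, 0.045, 0.015, 0.08)
  res <- wilcoxon_exact(a, b)
  expect_equal(res$statistic, 45)
  expect_equal(res$p_value, 2 / 512)        # 0.00390625
  # eight one way, the opposite difference the smallest in magnitude
  b2 <- b
  b2[8L] <- a[8L] + 0.001
  res2 <- wilcoxon_exact(a, b2)
  expect_equal(res2$p_value, 4 / 512)       # 0.0078125
  expect_error(wilcoxon_exact(c(1, 2), c(1, 2)), "all differences")
})

test_that("wilcoxon_exact equals the brute-force enumeration oracle (and wilcox.test without ties)", {
  set.seed(10)
  for (trial in 1:60) {
    n <- sample(3:12, 1L)
    a <- round(rnorm(n), 2)
    b <- round(rnorm(n), 2)
    if (all(a == b)) next
    got <- wilcoxon_exact(a, b)
    expect_equal(got$p_value, wilcoxon_oracle(a, b), tolerance = 1e-12)
    d <- a - b
    d <- d[d != 0]
    # wilcox.test is only exact without zeros and without ties
    if (length(d) == n && anyDuplicated(abs(d)) == 0L) {
      ref <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                                 exact = TRUE))
      expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
    }
  }
})

test_that("n = 9 tie-free p-values live on the 2k/512 lattice", {
  set.seed(11)
  for (trial in 1:25) {
    a <- rnorm(9)
    b <- rnorm(9)
    p <- wilcoxon_exact(a, b)$p_value
    expect_equal((p * 512) %% 2, 0, tolerance = 1e-9)
  }
})

test_that("large-sample Wilcoxon falls back to the tie-corrected normal approximation", {
  set.seed(12)
  a <- rnorm(25, 0.3)
  b <- rnorm(25)
  got <- wilcoxon_exact(a, b)
  expect_identical(got$method,
                   "normal approximation with tie correction")
  ref <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                             exact = FALSE,
                                             correct = TRUE))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-6)
})

test_that("Cohen's kappa matches hand computations", {
  expect_equal(cohen_kappa(c(1, 0, 1, 1), c(1, 0, 1, 1)), 1)
  # 2x2 table (45, 5, 5, 45): p_o = 0.9, p_e = 0.5, kappa = 0.8
  a <- rep(c(1, 1, 0, 0), c(45, 5, 5, 45))
  b <- rep(c(1, 0, 1, 0), c(45, 5, 5, 45))
  expect_equal(cohen_kappa(a, b), 0.8)
  # one rater constant, the other mixed: defined (p_e < 1), kappa <= 0
  expect_lte(cohen_kappa(rep(1, 10), rep(c(1, 0), 5)), 0)
  expect_error(cohen_kappa(rep(1, 5), rep(1, 5)), "2 observed")
  expect_error(cohen_kappa(1:3, 1:2), "equal-length")
})

test_that("cross-validation plumbing: leakage-free folds, self-consistent reports", {
  ds <- dataset_fix(n_infants = 6L, snippets_per_infant = 4L,
                    seed = 33L, fidgety_amp = 40)
  specs <- list(VID = model_spec("VID"),
                ALL3 = model_spec(c("MAT", "IMU", "VID"),
                                  fusion = "late"))
  tc <- train_config(n_restarts = 1L, max_epochs = 3L, seed = 2L)
  rep <- run_crossval(ds, specs, tc, k = 3L, infants_per_fold = 2L,
                      seed = 7L)
  # metrics recompute exactly from the stored confusion counts
  for (nm in names(rep$models)) {
    for (fr in rep$models[[nm]]) {
      if (!is.finite(fr$BA)) next
      m <- classification_metrics(fr$counts)
      expect_equal(fr$TPR, m$TPR)
      expect_equal(fr$TNR, m$TNR)
      expect_equal(fr$BA, m$BA)
    }
  }
  # every test infant is disjoint from its fold's training infants
  infants <- fmfusion:::dataset_infants(ds)
  for (f in rep$folds) {
    expect_length(intersect(f$train_infants, f$test_infants), 0L)
  }
  # prediction rows cover each model x snippet exactly once
  expect_equal(nrow(rep$predictions),
               length(specs) * rep$n_snippets)
  # p-value matrix symmetric with empty diagonal
  expect_true(is.na(rep$wilcoxon_p["VID", "VID"]))
  expect_equal(rep$wilcoxon_p["VID", "ALL3"],
               rep$wilcoxon_p["ALL3", "VID"])
  # reproducible end to end
  rep2 <- run_crossval(ds, specs, tc, k = 3L, infants_per_fold = 2L,
                       seed = 7L)
  expect_identical(rep$summary, rep2$summary)
  # report export writes the three artifacts
  dir <- withr::local_tempdir()
  write_cv_report(rep, dir)
  expect_true(all(file.exists(file.path(dir, c("cv_report.json",
                                               "cv_summary.csv",
                                               "cv_wilcoxon.csv")))))
})
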