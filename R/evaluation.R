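# Subject-disjoint 9-fold cross-validation, classification metrics,
# t-based confidence intervals, the exact two-sided Wilcoxon
# signed-rank test, and Cohen's kappa.

#' Partition infants into subject-disjoint CV folds
#'
#' Randomly (seeded) partitions the infants into `k` disjoint subsets
#' of `infants_per_fold` each; fold `f` tests on subset `f` and trains
#' on the rest, so no infant ever contributes snippets to both sides.
#'
#' @param dataset An [fm_dataset()] (or a character vector of infant
#'   ids).
#' @param k Number of folds (default 9).
#' @param infants_per_fold Test infants per fold (default 4).
#' @param seed Seed for the partition.
#' @return List of `k` folds: `list(fold_index, train_infants,
#'   test_infants)`.
#' @export
make_folds <- function(dataset, k = 9L, infants_per_fold = 4L,
                       seed = 1L) {
  infants <- if (is.character(dataset)) dataset else dataset$infant_ids
  n <- length(infants)
  if (n != k * infants_per_fold) {
    stop("configuration error: ", n, " infants cannot form ", k,
         " folds of ", infants_per_fold)
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  shuffled <- sample(infants)
  lapply(seq_len(k), function(f) {
    test <- shuffled[((f - 1L) * infants_per_fold + 1L):
                       (f * infants_per_fold)]
    list(fold_index = f, train_infants = setdiff(shuffled, test),
         test_infants = test)
  })
}

#' Confusion counts
#'
#' @param TP,TN,FP,FN Non-negative integer counts.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  structure(as.list(counts), class = "confusion_counts")
}

#' Sensitivity, specificity and balanced accuracy
#'
#' `TPR = TP / (TP + FN)`, `TNR = TN / (TN + FP)`,
#' `BA = (TPR + TNR) / 2`.
#'
#' @param counts A [confusion_counts()].
#' @return Named list `TPR`, `TNR`, `BA`.
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$TP + counts$FN == 0 || counts$TN + counts$FP == 0) {
    stop("metric undefined: a class is absent from the test set")
  }
  tpr <- counts$TP / (counts$TP + counts$FN)
  tnr <- counts$TN / (counts$TN + counts$FP)
  list(TPR = tpr, TNR = tnr, BA = (tpr + tnr) / 2)
}

#' Mean with Student-t 95% confidence interval
#'
#' `mean +/- t(0.975, n-1) * sd / sqrt(n)`; the t rather than normal
#' quantile because fold counts are small (n = 9 in the standard
#' protocol).
#'
#' @param values Numeric vector, `n >= 2`.
#' @return Named list `mean`, `lower`, `upper`.
#' @export
mean_ci95 <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L) stop("need at least 2 values for a confidence interval")
  m <- mean(values)
  half <- stats::qt(0.975, n - 1L) * stats::sd(values) / sqrt(n)
  list(mean = m, lower = m - half, upper = m + half)
}

#' Exact two-sided Wilcoxon signed-rank test
#'
#' Paired test on `a - b`. Zero differences are dropped; absolute
#' differences are ranked with mid-ranks for ties; `W` is the sum of
#' ranks of positive differences. For `m <= 15` retained pairs the
#' p-value is computed by exact enumeration of all `2^m` sign
#' assignments (valid with ties); above that, a normal approximation
#' with tie correction and continuity correction is used. Two-sided
#' p-value: `min(1, 2 * min(P(W <= w), P(W >= w)))`.
#'
#' @param a,b Equal-length numeric vectors of paired observations.
#' @return List `statistic` (W), `p_value`, `n_effective` (pairs after
#'   dropping zeros), `method`.
#' @export
wilcoxon_exact <- function(a, b) {
  if (length(a) != length(b) || length(a) < 1L) {
    stop("a and b must be equal-length, non-empty")
  }
  d <- a - b
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L) stop("test undefined: all differences are zero")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (m <= 15L) {
    sums <- 0
    for (ri in r) sums <- c(sums, sums + ri)
    p_le <- mean(sums <= W + 1e-9)
    p_ge <- mean(sums >= W - 1e-9)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact enumeration"
  } else {
    mu <- m * (m + 1) / 4
    ties <- table(r)
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation with tie correction"
  }
  list(statistic = W, p_value = p, n_effective = m, method = method)
}

#' Cohen's kappa for interrater agreement
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and
#' chance agreement `p_e` from the marginal products.
#'
#' @param labels_a,labels_b Equal-length categorical sequences.
#' @return Kappa (scalar).
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b) || length(labels_a) < 1L) {
    stop("label sequences must be equal-length and non-empty")
  }
  cats <- sort(unique(c(labels_a, labels_b)))
  if (length(cats) < 2L) {
    stop("need at least 2 observed categories overall")
  }
  fa <- factor(labels_a, levels = cats)
  fb <- factor(labels_b, levels = cats)
  tab <- table(fa, fb)
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (p_e >= 1) stop("kappa undefined: chance agreement is 1")
  (p_o - p_e) / (1 - p_e)
}

# ----------------------------------------------------------------------
# cross-validation driver

fold_model_seed <- function(seed, fold, net_index) {
  as.integer((as.double(seed) + 100003 * fold + 7919 * net_index) %%
               2147483647)
}

config_key <- function(modality, cnn) {
  paste(modality, paste(cnn$conv_kernels, collapse = ","),
        paste(cnn$conv_sizes, collapse = ","), cnn$fc_units,
        cnn$dropout, cnn$batch_norm, sep = "|")
}

#' Specify one model for cross-validation
#'
#' @param modalities Character subset of `c("MAT", "IMU", "VID")`.
#' @param fusion `"none"` (single modality), `"late"` (average the
#'   per-modality network probabilities) or `"early"` (one network on
#'   concatenated features).
#' @param cnn A [cnn_config()] (default [cnn_config_small()]).
#' @return A `model_spec` list.
#' @export
model_spec <- function(modalities, fusion = c("none", "late", "early"),
                       cnn = cnn_config_small()) {
  fusion <- match.arg(fusion)
  modalities <- match.arg(modalities, c("MAT", "IMU", "VID"),
                          several.ok = TRUE)
  if (fusion == "none" && length(modalities) != 1L) {
    stop("fusion 'none' requires exactly one modality")
  }
  if (fusion != "none" && length(modalities) < 2L) {
    stop("fusion requires at least two modalities")
  }
  structure(list(modalities = modalities, fusion = fusion, cnn = cnn),
            class = "model_spec")
}

# Fold-independent per-snippet raw features for the needed modalities.
# Only the series needed downstream are kept (accelerations are an
# ablation-only feature and are recomputed on demand).
precompute_raw <- function(dataset, modalities) {
  out <- list()
  if ("VID" %in% modalities) {
    out$vid <- lapply(dataset$triples, function(tr) {
      ser <- pose_series(process_keypoints(tr$keypoints))
      ser["acc"] <- NULL
      ser
    })
  }
  if ("MAT" %in% modalities) {
    out$mat <- lapply(dataset$triples, function(tr) {
      unclass(build_mat_features(tr$pressure))
    })
  }
  if ("IMU" %in% modalities) {
    out$imu <- lapply(dataset$triples, function(tr) {
      imu_series(tr$imu)
    })
  }
  out
}

# Pooled training-set normalization statistics for one fold.
fold_norm_stats <- function(raw, train_idx, modalities) {
  groups <- list()
  if ("VID" %in% modalities) {
    groups$position <- lapply(raw$vid[train_idx], `[[`, "pos")
    groups$velocity <- lapply(raw$vid[train_idx], `[[`, "vel")
  }
  if ("IMU" %in% modalities) {
    acc_cols <- imu_acc_cols()
    gyr_cols <- imu_gyr_cols()
    groups$acceleration <- lapply(raw$imu[train_idx],
                                  function(m) m[, acc_cols])
    groups$angular_velocity <- lapply(raw$imu[train_idx],
                                      function(m) m[, gyr_cols])
  }
  if (length(groups) == 0L) {
    # MAT-only models: mat features are normalized per snippet and
    # need no pooled statistics
    return(structure(list(groups = list(),
                          fitted_on = "fold training set"),
                     class = "norm_stats"))
  }
  fit_norm_stats(groups, fitted_on = "fold training set")
}

# Final per-snippet feature arrays for one fold (z-scored with the
# fold's training statistics).
fold_feature_arrays <- function(raw, stats, modalities, n,
                                need_fused = FALSE) {
  arrays <- list()
  if ("VID" %in% modalities) {
    arr <- array(0, dim = c(250L, 60L, n))
    for (i in seq_len(n)) {
      arr[, , i] <- cbind(
        apply_norm(raw$vid[[i]]$pos, "position", stats),
        apply_norm(raw$vid[[i]]$vel, "velocity", stats))
    }
    arrays$VID <- arr
  }
  if ("MAT" %in% modalities) {
    arr <- array(0, dim = c(500L, 6L, n))
    for (i in seq_len(n)) arr[, , i] <- raw$mat[[i]]
    arrays$MAT <- arr
  }
  if ("IMU" %in% modalities) {
    acc_cols <- imu_acc_cols()
    gyr_cols <- imu_gyr_cols()
    arr <- array(0, dim = c(300L, 36L, n))
    for (i in seq_len(n)) {
      m <- raw$imu[[i]]
      m[, acc_cols] <- apply_norm(m[, acc_cols], "acceleration", stats)
      m[, gyr_cols] <- apply_norm(m[, gyr_cols], "angular_velocity",
                                  stats)
      arr[, , i] <- m
    }
    arrays$IMU <- arr
  }
  if (need_fused) {
    stopifnot(all(c("MAT", "IMU", "VID") %in% names(arrays)))
    arr <- array(0, dim = c(250L, 102L, n))
    for (i in seq_len(n)) {
      arr[, , i] <- cbind(
        resample_features(arrays$MAT[, , i], 250L),
        resample_features(arrays$IMU[, , i], 250L),
        arrays$VID[, , i])
    }
    arrays$FUSED <- arr
  }
  arrays
}

#' Subject-disjoint cross-validation of one or more models
#'
#' For each fold: fits normalization statistics on the training
#' snippets only, builds the per-modality feature arrays, trains each
#' required network with random restarts (networks shared between
#' models that use the same modality and architecture within a fold),
#' predicts the held-out infants' snippets, applies the requested
#' fusion, and accumulates confusion counts. Reports per-fold metrics,
#' means with 95% CIs, and the pairwise Wilcoxon signed-rank matrix on
#' per-fold balanced accuracy.
#'
#' @param dataset An [fm_dataset()]; it is filtered with
#'   [filter_synchronized()] for the union of required modalities.
#' @param model_specs Named list of [model_spec()] objects.
#' @param tc A [train_config()].
#' @param k,infants_per_fold Fold geometry (defaults 9 and 4).
#' @param seed Seed for the fold partition and derived training seeds.
#' @return An object of class `cv_report`.
#' @export
run_crossval <- function(dataset, model_specs, tc, k = 9L,
                         infants_per_fold = 4L, seed = 1L) {
  stopifnot(is.list(model_specs), length(model_specs) >= 1L,
            !is.null(names(model_specs)))
  modalities <- unique(unlist(lapply(model_specs, `[[`, "modalities")))
  need_fused <- any(vapply(model_specs, function(s) s$fusion == "early",
                           logical(1)))
  ds <- filter_synchronized(dataset, modalities)
  rm(dataset)   # large cohorts: let the caller's expression be freed
  n <- length(ds)
  if (n == 0L) stop("no synchronized labeled snippets left")
  labels <- dataset_labels(ds)
  infants <- dataset_infants(ds)
  snippet_ids <- vapply(ds$triples, function(t) t$meta$snippet_id,
                        character(1))
  raw <- precompute_raw(ds, modalities)
  folds <- make_folds(ds, k = k, infants_per_fold = infants_per_fold,
                      seed = seed)
  # raw sensor arrays are no longer needed once features exist; keep
  # only the metadata so multi-gigabyte cohorts do not stay resident
  ds$triples <- lapply(ds$triples, function(t) list(meta = t$meta))
  gc(verbose = FALSE)

  fold_results <- lapply(names(model_specs), function(nm) vector("list", k))
  names(fold_results) <- names(model_specs)
  predictions <- list()

  for (f in seq_len(k)) {
    fold <- folds[[f]]
    tr_idx <- which(infants %in% fold$train_infants)
    te_idx <- which(infants %in% fold$test_infants)
    stopifnot(length(intersect(tr_idx, te_idx)) == 0L)
    stats <- fold_norm_stats(raw, tr_idx, modalities)
    arrays <- fold_feature_arrays(raw, stats, modalities, n,
                                  need_fused = need_fused)
    net_cache <- new.env(parent = emptyenv())
    net_counter <- 0L
    get_net <- function(mod_name, cnn) {
      key <- config_key(mod_name, cnn)
      if (!is.null(net_cache[[key]])) return(net_cache[[key]])
      net_counter <<- net_counter + 1L
      arr <- arrays[[mod_name]]
      model <- build_model(cnn, dim(arr)[1:2])
      tc_f <- tc
      tc_f$seed <- fold_model_seed(seed, f, net_counter)
      clf <- train_with_restarts(model,
                                 arr[, , tr_idx, drop = FALSE],
                                 labels[tr_idx], tc_f,
                                 norm_stats = stats)
      probs <- predict_proba(clf, arr[, , te_idx, drop = FALSE])
      res <- list(clf = clf, test_probs = probs)
      net_cache[[key]] <- res
      res
    }
    for (nm in names(model_specs)) {
      spec <- model_specs[[nm]]
      if (spec$fusion == "early") {
        probs <- get_net("FUSED", spec$cnn)$test_probs
      } else {
        per_mod <- vapply(spec$modalities, function(m) {
          get_net(m, spec$cnn)$test_probs
        }, numeric(length(te_idx)))
        per_mod <- matrix(per_mod, nrow = length(te_idx))
        probs <- rowMeans(per_mod)
      }
      pred <- as.integer(probs >= 0.5)
      truth <- labels[te_idx]
      counts <- confusion_counts(
        TP = sum(pred == 1L & truth == 1L),
        TN = sum(pred == 0L & truth == 0L),
        FP = sum(pred == 1L & truth == 0L),
        FN = sum(pred == 0L & truth == 1L))
      metrics <- tryCatch(classification_metrics(counts),
                          error = function(e) {
                            list(TPR = NA_real_, TNR = NA_real_,
                                 BA = NA_real_)
                          })
      fold_results[[nm]][[f]] <- list(
        fold_index = f, test_infants = fold$test_infants,
        counts = counts, TPR = metrics$TPR, TNR = metrics$TNR,
        BA = metrics$BA)
      predictions[[length(predictions) + 1L]] <- data.frame(
        model = nm, fold = f, snippet_id = snippet_ids[te_idx],
        prob = probs, pred = pred, truth = truth,
        stringsAsFactors = FALSE)
    }
    rm(arrays, net_cache)
    gc(verbose = FALSE)
  }

  metric_of <- function(nm, what) {
    vapply(fold_results[[nm]], `[[`, numeric(1), what)
  }
  summary <- do.call(rbind, lapply(names(model_specs), function(nm) {
    row <- data.frame(model = nm, stringsAsFactors = FALSE)
    for (what in c("TPR", "TNR", "BA")) {
      ci <- mean_ci95(metric_of(nm, what))
      row[[paste0(what, "_mean")]] <- ci$mean
      row[[paste0(what, "_lo")]] <- ci$lower
      row[[paste0(what, "_hi")]] <- ci$upper
    }
    row
  }))

  nm_all <- names(model_specs)
  pmat <- matrix(NA_real_, length(nm_all), length(nm_all),
                 dimnames = list(nm_all, nm_all))
  if (length(nm_all) >= 2L) {
    for (i in seq_along(nm_all)) {
      for (j in seq_along(nm_all)) {
        if (i < j) {
          ba_i <- metric_of(nm_all[i], "BA")
          ba_j <- metric_of(nm_all[j], "BA")
          ok <- is.finite(ba_i) & is.finite(ba_j)
          p <- tryCatch(
            wilcoxon_exact(ba_i[ok], ba_j[ok])$p_value,
            error = function(e) NA_real_)
          pmat[i, j] <- p
          pmat[j, i] <- p
        }
      }
    }
  }

  structure(list(folds = folds, models = fold_results,
                 summary = summary, wilcoxon_p = pmat,
                 predictions = do.call(rbind, predictions),
                 n_snippets = n, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d snippets, %d folds, %d model(s)\n",
              x$n_snippets, length(x$folds), length(x$models)))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf(
      "  %-12s BA %5.1f%% [%5.1f%% %5.1f%%]  Sens %5.1f%%  Spec %5.1f%%\n",
      s$model[i], 100 * s$BA_mean[i], 100 * s$BA_lo[i],
      100 * s$BA_hi[i], 100 * s$TPR_mean[i], 100 * s$TNR_mean[i]))
  }
  invisible(x)
}

#' Export a CV report
#'
#' Writes the full report as JSON, the model-by-metric summary (with CI
#' bounds) as CSV, and the pairwise Wilcoxon p-value matrix as CSV.
#'
#' @param report A `cv_report`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_cv_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  models_plain <- lapply(report$models, function(folds) {
    lapply(folds, function(fr) {
      fr$counts <- unclass(fr$counts)
      fr
    })
  })
  jsonlite::write_json(
    list(summary = report$summary,
         models = models_plain,
         wilcoxon_p = report$wilcoxon_p,
         predictions = report$predictions,
         n_snippets = report$n_snippets, seed = report$seed),
    file.path(out_dir, "cv_report.json"), auto_unbox = TRUE,
    digits = NA, pretty = TRUE)
  utils::write.csv(report$summary,
                   file.path(out_dir, "cv_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$wilcoxon_p),
                   file.path(out_dir, "cv_wilcoxon.csv"))
  invisible(out_dir)
}
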