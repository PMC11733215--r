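# R interface to the compact 1-D temporal CNN used for every
# single-modality and early-fusion model.

#' CNN architecture configuration
#'
#' Three 1-D temporal convolution layers and one fully connected layer
#' by default, each block being Conv -> BatchNorm -> ReLU -> Dropout
#' (FC likewise), followed by a single linear output unit whose logit
#' feeds a binary cross-entropy loss. Convolutions run over the frame
#' axis with feature columns as channels, stride 1, same padding, no
#' pooling.
#'
#' @param conv_layers List of `c(n_kernels, kernel_size)` pairs, one per
#'   convolution layer.
#' @param fc_units Units in the fully connected layer.
#' @param dropout_rate Dropout fraction in `[0, 1)` (default 0.20).
#' @param batch_norm Use batch normalization (default `TRUE`).
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(conv_layers = list(c(32L, 5L), c(64L, 5L),
                                          c(64L, 5L)),
                       fc_units = 64L, dropout_rate = 0.2,
                       batch_norm = TRUE) {
  stopifnot(is.list(conv_layers), length(conv_layers) >= 1L,
            all(vapply(conv_layers, length, integer(1)) == 2L))
  kernels <- vapply(conv_layers, function(l) as.integer(l[1L]),
                    integer(1))
  sizes <- vapply(conv_layers, function(l) as.integer(l[2L]),
                  integer(1))
  if (any(kernels < 1L) || any(sizes < 1L)) {
    stop("kernel counts and sizes must be >= 1")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must lie in [0, 1)")
  }
  structure(list(conv_kernels = kernels, conv_sizes = sizes,
                 fc_units = as.integer(fc_units),
                 dropout = dropout_rate,
                 batch_norm = isTRUE(batch_norm)),
            class = "cnn_config")
}

#' Small desk-scale CNN configuration
#'
#' A reduced architecture (8 kernels of size 5 per layer, 16 FC units)
#' suited to single-CPU cross-validation experiments on synthetic
#' cohorts.
#'
#' @return A [cnn_config()].
#' @export
cnn_config_small <- function() {
  cnn_config(conv_layers = list(c(8L, 5L), c(8L, 5L), c(8L, 5L)),
             fc_units = 16L)
}

#' Training configuration
#'
#' Adam with batch size 4, learning rate 0.001, beta1 0.9, beta2 0.999,
#' epsilon 1e-07; a validation stop holding out the last `val_split`
#' fraction of a seeded snippet-level shuffle, with patience in epochs;
#' and `n_restarts` random re-initializations from which the model with
#' the lowest validation loss is kept.
#'
#' @param batch_size Mini-batch size.
#' @param learning_rate,beta1,beta2,epsilon Adam parameters.
#' @param val_split Fraction of the training snippets held out for
#'   validation (default 1/8).
#' @param patience Early-stopping patience in epochs.
#' @param max_epochs Hard cap on training epochs.
#' @param n_restarts Number of random restarts (the study protocol uses
#'   20; desk-scale experiments typically use fewer).
#' @param seed Master seed for initialization, shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 4L, learning_rate = 0.001,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-07,
                         val_split = 1 / 8, patience = 10L,
                         max_epochs = 200L, n_restarts = 20L,
                         seed = 1L) {
  stopifnot(val_split > 0, val_split < 1, patience >= 1L,
            n_restarts >= 1L, max_epochs >= 1L, batch_size >= 1L)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1,
                 beta2 = beta2, epsilon = epsilon,
                 val_split = val_split, patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Assemble an untrained model
#'
#' Validates the architecture against the input shape (a kernel longer
#' than the input frames is a configuration error).
#'
#' @param config A [cnn_config()].
#' @param input_shape `c(frames, channels)`.
#' @return An object of class `fm_cnn`.
#' @export
build_model <- function(config, input_shape) {
  stopifnot(inherits(config, "cnn_config"), length(input_shape) == 2L)
  input_shape <- as.integer(input_shape)
  if (any(config$conv_sizes > input_shape[1L])) {
    stop("configuration error: kernel size exceeds input frames (",
         input_shape[1L], ")")
  }
  structure(list(config = config, input_shape = input_shape),
            class = "fm_cnn")
}

#' Initialize model weights
#'
#' Glorot-uniform weights, zero biases, unit batch-norm scale. Useful
#' for inspecting the untrained forward pass; [train_model()] performs
#' its own seeded initialization.
#'
#' @param model A [build_model()] result.
#' @param seed Integer seed.
#' @return Weight list (conv layers, fc, output).
#' @export
init_weights <- function(model, seed = 1L) {
  stopifnot(inherits(model, "fm_cnn"))
  cnn_init_cpp(unclass(model$config), model$input_shape[1L],
               model$input_shape[2L], as.double(seed))
}

#' Number of trainable parameters
#'
#' @param model A [build_model()] result.
#' @return Integer parameter count (a deterministic function of the
#'   configuration and input shape).
#' @export
count_params <- function(model) {
  w <- init_weights(model, seed = 0L)
  n <- 0L
  for (lay in w$conv) {
    n <- n + length(lay$W) + length(lay$b)
    if (model$config$batch_norm) {
      n <- n + length(lay$gamma) + length(lay$beta)
    }
  }
  n <- n + length(w$fc$W) + length(w$fc$b)
  if (model$config$batch_norm) {
    n <- n + length(w$fc$gamma) + length(w$fc$beta)
  }
  n + length(w$out$W) + 1L
}

# Stack a list of feature matrices (or pass through a 3-D array) into
# the frames x channels x n cube the C++ core consumes.
stack_features <- function(features) {
  if (is.array(features) && length(dim(features)) == 3L) {
    return(features)
  }
  if (inherits(features, "feature_matrix")) features <- list(features)
  stopifnot(is.list(features), length(features) >= 1L)
  d <- dim(features[[1L]])
  arr <- array(0, dim = c(d[1L], d[2L], length(features)))
  for (i in seq_along(features)) {
    fi <- features[[i]]
    if (!identical(dim(fi), d)) {
      stop("feature matrices do not share one shape")
    }
    arr[, , i] <- unclass(fi)
  }
  arr
}

#' Train the CNN once
#'
#' Holds out the last `val_split` fraction of a seeded shuffle for
#' validation, trains with Adam and mini-batches until the validation
#' loss has not improved for `patience` epochs (or `max_epochs`), and
#' returns the weights of the best-validation epoch. Fully reproducible
#' from `tc$seed`.
#'
#' @param model A [build_model()] result.
#' @param features List of [feature_matrix()] objects sharing one
#'   shape, or a frames x channels x n array.
#' @param labels Integer vector of 0/1 labels, one per snippet.
#' @param tc A [train_config()] (its `n_restarts` is ignored here; see
#'   [train_with_restarts()]).
#' @param norm_stats Optional [fit_norm_stats()] object to store with
#'   the classifier.
#' @return An object of class `trained_classifier` with elements
#'   `config`, `input_shape`, `weights`, `norm_stats`, `training_log`
#'   (data frame epoch/train_loss/val_loss), `best_val_loss`,
#'   `best_epoch` and `seed`.
#' @export
train_model <- function(model, features, labels, tc,
                        norm_stats = NULL) {
  stopifnot(inherits(model, "fm_cnn"), inherits(tc, "train_config"))
  arr <- stack_features(features)
  labels <- as.integer(labels)
  if (length(labels) != dim(arr)[3L]) {
    stop("labels length does not match number of snippets")
  }
  if (!identical(dim(arr)[1:2], model$input_shape)) {
    stop("feature shape ", paste(dim(arr)[1:2], collapse = "x"),
         " does not match model input shape ",
         paste(model$input_shape, collapse = "x"))
  }
  counts <- table(factor(labels, levels = c(0L, 1L)))
  if (any(counts < 2L)) {
    stop("data error: need at least 2 training snippets per class")
  }
  fit <- cnn_train_cpp(arr, as.double(labels), unclass(model$config),
                       unclass(tc))
  log_df <- data.frame(epoch = seq_len(nrow(fit$log)),
                       train_loss = fit$log[, 1L],
                       val_loss = fit$log[, 2L])
  structure(list(config = model$config,
                 input_shape = model$input_shape,
                 weights = fit$weights, norm_stats = norm_stats,
                 training_log = log_df,
                 best_val_loss = fit$best_val_loss,
                 best_epoch = as.integer(fit$best_epoch),
                 seed = tc$seed),
            class = "trained_classifier")
}

restart_seed <- function(seed, restart) {
  as.integer((as.double(seed) + (restart - 1) * 1618033) %% 2147483647)
}

#' Train with random restarts and keep the best validation loss
#'
#' Runs `tc$n_restarts` independent trainings with deterministically
#' derived seeds (restart 1 uses `tc$seed` itself) and returns the
#' classifier with the lowest best validation loss; ties break toward
#' the earliest restart.
#'
#' @inheritParams train_model
#' @return A `trained_classifier` (with attribute `restart` giving the
#'   selected restart index).
#' @export
train_with_restarts <- function(model, features, labels, tc,
                                norm_stats = NULL) {
  arr <- stack_features(features)
  best <- NULL
  best_r <- NA_integer_
  for (r in seq_len(tc$n_restarts)) {
    tc_r <- tc
    tc_r$seed <- restart_seed(tc$seed, r)
    fit <- train_model(model, arr, labels, tc_r, norm_stats)
    if (is.null(best) || fit$best_val_loss < best$best_val_loss) {
      best <- fit
      best_r <- r
    }
  }
  attr(best, "restart") <- best_r
  best
}

#' Predict FM+ probabilities
#'
#' Deterministic inference: dropout off, batch normalization in
#' inference mode (running statistics). Returns the sigmoid of the
#' output logit, the probability of class FM+.
#'
#' @param clf A `trained_classifier`.
#' @param features A [feature_matrix()], list thereof, or
#'   frames x channels x n array matching the classifier input shape.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_proba <- function(clf, features) {
  stopifnot(inherits(clf, "trained_classifier"))
  arr <- stack_features(features)
  if (!identical(dim(arr)[1:2], clf$input_shape)) {
    stop("feature shape ", paste(dim(arr)[1:2], collapse = "x"),
         " does not match classifier input shape ",
         paste(clf$input_shape, collapse = "x"))
  }
  stats::plogis(as.numeric(cnn_forward_cpp(clf$weights, arr,
                                           unclass(clf$config))))
}

#' Reduced grid search over CNN configurations
#'
#' Trains each candidate configuration (with restarts per `tc`) on the
#' given features and ranks configurations by best validation loss.
#'
#' @param features,labels As in [train_model()].
#' @param grid List of [cnn_config()] objects.
#' @param tc A [train_config()].
#' @param top_k Number of top configurations to return (default all).
#' @return List of `list(config, val_loss, restart)` sorted by
#'   non-decreasing validation loss.
#' @export
grid_search_light <- function(features, labels, grid, tc,
                              top_k = length(grid)) {
  stopifnot(is.list(grid), length(grid) >= 1L)
  arr <- stack_features(features)
  shape <- dim(arr)[1:2]
  results <- lapply(grid, function(cfg) {
    fit <- train_with_restarts(build_model(cfg, shape), arr, labels,
                               tc)
    list(config = cfg, val_loss = fit$best_val_loss,
         restart = attr(fit, "restart"))
  })
  ord <- order(vapply(results, function(r) r$val_loss, numeric(1)))
  results[ord][seq_len(min(top_k, length(results)))]
}

#' Save / load a trained classifier as JSON
#'
#' The checkpoint is a plain JSON file holding the architecture,
#' weights, normalization statistics and training log.
#'
#' @param clf A `trained_classifier`.
#' @param path Output path.
#' @return `path`, invisibly (for `save_classifier`); the classifier
#'   (for `load_classifier`).
#' @export
save_classifier <- function(clf, path) {
  stopifnot(inherits(clf, "trained_classifier"))
  payload <- list(
    config = unclass(clf$config), input_shape = clf$input_shape,
    weights = clf$weights,
    norm_stats = if (!is.null(clf$norm_stats)) {
      unclass(clf$norm_stats)
    },
    training_log = as.list(clf$training_log),
    best_val_loss = clf$best_val_loss, best_epoch = clf$best_epoch,
    seed = clf$seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# vectors serialized from arma rowvecs come back as plain vectors;
# matrices as matrices (possibly n x 1)
as_weight <- function(x, matrix_like) {
  if (matrix_like && !is.matrix(x)) matrix(x, ncol = 1L) else x
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE,
                           simplifyMatrix = TRUE)
  fix_layer <- function(lay, has_bn = TRUE) {
    lay$W <- as_weight(lay$W, TRUE)
    lay$b <- as.double(lay$b)
    if (has_bn) {
      for (f in c("gamma", "beta", "rmean", "rvar")) {
        lay[[f]] <- as.double(lay[[f]])
      }
    }
    lay
  }
  weights <- list(conv = lapply(p$weights$conv, fix_layer),
                  fc = fix_layer(p$weights$fc),
                  out = list(W = as_weight(p$weights$out$W, TRUE),
                             b = as.double(p$weights$out$b)))
  cfg <- structure(list(
    conv_kernels = as.integer(p$config$conv_kernels),
    conv_sizes = as.integer(p$config$conv_sizes),
    fc_units = as.integer(p$config$fc_units),
    dropout = p$config$dropout,
    batch_norm = isTRUE(p$config$batch_norm)), class = "cnn_config")
  ns <- if (!is.null(p$norm_stats)) {
    structure(list(groups = lapply(p$norm_stats$groups, function(g) {
      list(mean = g$mean, sd = g$sd)
    }), fitted_on = p$norm_stats$fitted_on), class = "norm_stats")
  }
  structure(list(config = cfg,
                 input_shape = as.integer(p$input_shape),
                 weights = weights, norm_stats = ns,
                 training_log = as.data.frame(p$training_log),
                 best_val_loss = p$best_val_loss,
                 best_epoch = as.integer(p$best_epoch),
                 seed = as.integer(p$seed)),
            class = "trained_classifier")
}
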