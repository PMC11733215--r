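# Feature-matrix container shared by the three modality pipelines.

#' Feature matrix
#'
#' A frames x channels numeric matrix tagged with its modality and
#' ordered channel names. Channel counts per modality: VID 60, MAT 6,
#' IMU 36, FUSED 102 (with the default three-modality fusion).
#'
#' @param values Numeric matrix, frames x channels, all finite.
#' @param modality One of `"VID"`, `"MAT"`, `"IMU"`, `"FUSED"`.
#' @param channel_names Character vector, one per column.
#' @param meta A [snippet_meta()] (optional).
#' @return An object of class `feature_matrix` (a matrix with
#'   attributes).
#' @export
feature_matrix <- function(values, modality, channel_names,
                           meta = NULL) {
  modality <- match.arg(modality, c("VID", "MAT", "IMU", "FUSED"))
  stopifnot(is.matrix(values), ncol(values) == length(channel_names))
  if (any(!is.finite(values))) {
    stop("feature matrix (", modality, ") contains non-finite entries")
  }
  colnames(values) <- channel_names
  structure(values, modality = modality, meta = meta,
            class = c("feature_matrix", "matrix", "array"))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix %s> %d frames x %d channels\n",
              attr(x, "modality"), nrow(x), ncol(x)))
  invisible(x)
}

fm_values <- function(fm) {
  v <- unclass(fm)
  attr(v, "modality") <- NULL
  attr(v, "meta") <- NULL
  v
}
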