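# On-disk dataset format: one directory per dataset holding a JSON
# manifest plus one delimited-text array file per snippet per modality.
# Numbers are written as %.17g so read(write(x)) is bit-exact.
#
# Array layouts (frames-major):
#   keypoints: 250 rows x 30 cols (x1, y1, ..., x15, y15)
#   pressure : 500 rows x 1024 cols (row-major 32x32)
#   imu      : 300 rows x 36 cols (sensor-major ax, ay, az, gx, gy, gz)

LABEL_STRINGS <- c("FM-" = 0L, "FM+" = 1L)

label_to_string <- function(label) {
  if (is.na(label)) "NA" else names(LABEL_STRINGS)[LABEL_STRINGS == label]
}

string_to_label <- function(s) {
  if (s %in% c("NA", "not assessable")) return(NA_integer_)
  if (!s %in% names(LABEL_STRINGS)) {
    stop("unknown label string: ", s, " (expected FM+, FM- or NA)")
  }
  LABEL_STRINGS[[s]]
}

write_array_txt <- function(mat, path) {
  lines <- apply(matrix(sprintf("%.17g", mat), nrow = nrow(mat)), 1L,
                 paste, collapse = "\t")
  writeLines(lines, path)
}

read_array_txt <- function(path, nrow, ncol, what) {
  if (!file.exists(path)) {
    stop("missing array file for ", what, ": ", path)
  }
  vals <- scan(path, what = double(), sep = "\t", quiet = TRUE)
  if (length(vals) != nrow * ncol) {
    stop("shape mismatch in ", what, ": ", path, " has ", length(vals),
         " values, expected ", nrow, "x", ncol)
  }
  matrix(vals, nrow = nrow, ncol = ncol, byrow = TRUE)
}

# frames x 15 x 2 <-> frames x 30 (x1,y1,...,x15,y15)
kp_to_matrix <- function(values) {
  out <- matrix(0, nrow(values), 30L)
  out[, seq(1L, 29L, 2L)] <- values[, , 1L]
  out[, seq(2L, 30L, 2L)] <- values[, , 2L]
  out
}

kp_from_matrix <- function(mat) {
  arr <- array(0, dim = c(nrow(mat), 15L, 2L))
  arr[, , 1L] <- mat[, seq(1L, 29L, 2L)]
  arr[, , 2L] <- mat[, seq(2L, 30L, 2L)]
  arr
}

# frames x 32 x 32 <-> frames x 1024, row-major per frame
pr_to_matrix <- function(values) {
  matrix(aperm(values, c(1L, 3L, 2L)), nrow = dim(values)[1L])
}

pr_from_matrix <- function(mat) {
  aperm(array(mat, dim = c(nrow(mat), 32L, 32L)), c(1L, 3L, 2L))
}

# frames x 6 sensors x 6 channels <-> frames x 36, sensor-major
imu_to_matrix <- function(values) {
  matrix(aperm(values, c(1L, 3L, 2L)), nrow = dim(values)[1L])
}

imu_from_matrix <- function(mat) {
  aperm(array(mat, dim = c(nrow(mat), 6L, 6L)), c(1L, 3L, 2L))
}

#' Write a dataset to a directory
#'
#' Writes a JSON manifest (`manifest.json`) plus one tab-delimited text
#' array file per snippet per present modality. The format round-trips
#' bit-exactly through [read_dataset()].
#'
#' @param dataset An [fm_dataset()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  rows <- lapply(dataset$triples, function(tr) {
    id <- tr$meta$snippet_id
    row <- list(snippet_id = id, infant_id = tr$meta$infant_id,
                session = tr$meta$session,
                label = label_to_string(tr$meta$label),
                keypoints = "none", pressure = "none", imu = "none")
    if (!is.null(tr$keypoints)) {
      row$keypoints <- paste0(id, "_keypoints.tsv")
      write_array_txt(kp_to_matrix(tr$keypoints$values),
                      file.path(out_dir, row$keypoints))
    }
    if (!is.null(tr$pressure)) {
      row$pressure <- paste0(id, "_pressure.tsv")
      write_array_txt(pr_to_matrix(tr$pressure$values),
                      file.path(out_dir, row$pressure))
    }
    if (!is.null(tr$imu)) {
      row$imu <- paste0(id, "_imu.tsv")
      write_array_txt(imu_to_matrix(tr$imu$values),
                      file.path(out_dir, row$imu))
    }
    row
  })
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(rows, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest_path)
}

#' Read a dataset from a manifest
#'
#' @param manifest_path Path to a `manifest.json` written by
#'   [write_dataset()] (or hand-built in the same layout). Modalities
#'   listed as `"none"` are read as absent.
#' @return An [fm_dataset()].
#' @export
read_dataset <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path)
  }
  base <- dirname(manifest_path)
  rows <- jsonlite::read_json(manifest_path)
  triples <- lapply(rows, function(row) {
    meta <- snippet_meta(row$snippet_id, row$infant_id, row$session,
                         string_to_label(row$label))
    kp <- pr <- im <- NULL
    if (!identical(row$keypoints, "none")) {
      mat <- read_array_txt(file.path(base, row$keypoints), 250L, 30L,
                            paste0(row$snippet_id, "/keypoints"))
      kp <- keypoint_snippet(kp_from_matrix(mat), meta)
    }
    if (!identical(row$pressure, "none")) {
      mat <- read_array_txt(file.path(base, row$pressure), 500L, 1024L,
                            paste0(row$snippet_id, "/pressure"))
      pr <- pressure_snippet(pr_from_matrix(mat), meta)
    }
    if (!identical(row$imu, "none")) {
      mat <- read_array_txt(file.path(base, row$imu), 300L, 36L,
                            paste0(row$snippet_id, "/imu"))
      im <- imu_snippet(imu_from_matrix(mat), meta)
    }
    snippet_triple(meta, keypoints = kp, pressure = pr, imu = im)
  })
  fm_dataset(triples)
}
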