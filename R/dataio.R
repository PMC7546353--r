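#' Construct a single head-impact kinematic record
#'
#' A record holds one impact: a uniform time base plus six channels, three
#' linear accelerations (m/s^2; anterior-posterior, inferior-superior,
#' lateral) and three angular velocities (rad/s; coronal, sagittal, axial).
#'
#' @param record_id Character scalar, unique within a dataset.
#' @param lin_acc Numeric m x 3 matrix of linear acceleration (m/s^2).
#' @param ang_vel Numeric m x 3 matrix of angular velocity (rad/s).
#' @param sample_rate Sampling rate in Hz (default 1000).
#' @param time Optional time vector (s); defaults to `0:(m-1) / sample_rate`.
#'
#' @return An object of class `kinematic_record`.
#' @export
#' @examples
#' rec <- kinematic_record("imp1", matrix(0, 100, 3), matrix(0, 100, 3))
#' rec$sample_rate
kinematic_record <- function(record_id, lin_acc, ang_vel,
                             sample_rate = 1000, time = NULL) {
  if (!is.character(record_id) || length(record_id) != 1L || is.na(record_id)) {
    stop("record_id must be a single character string")
  }
  lin_acc <- as.matrix(lin_acc)
  ang_vel <- as.matrix(ang_vel)
  if (ncol(lin_acc) != 3L || ncol(ang_vel) != 3L) {
    stop("lin_acc and ang_vel must each have 3 columns")
  }
  m <- nrow(lin_acc)
  if (nrow(ang_vel) != m) stop("all channels must have the same length")
  if (!all(is.finite(lin_acc)) || !all(is.finite(ang_vel))) {
    stop("channels must be finite; missing samples are not allowed")
  }
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    stop("sample_rate must be a positive number")
  }
  if (is.null(time)) {
    time <- seq.int(0L, m - 1L) / sample_rate
  } else {
    if (length(time) != m) stop("time must match channel length")
    dt <- diff(time)
    if (any(dt <= 0) || max(abs(dt - 1 / sample_rate)) > 1e-9 / sample_rate) {
      stop("time must be strictly increasing with constant step 1/sample_rate")
    }
  }
  colnames(lin_acc) <- LIN_DIRECTIONS
  colnames(ang_vel) <- ANG_DIRECTIONS
  structure(
    list(record_id = record_id, time = as.numeric(time),
         lin_acc = lin_acc, ang_vel = ang_vel,
         sample_rate = as.numeric(sample_rate)),
    class = "kinematic_record"
  )
}

#' Construct a head-impact kinematic dataset
#'
#' @param records List of [kinematic_record()] objects sharing sample rate
#'   and length, with unique ids.
#' @param provenance Free-text provenance string.
#'
#' @return An object of class `kinematic_dataset`.
#' @export
kinematic_dataset <- function(records, provenance = "unspecified") {
  if (!is.list(records) || length(records) == 0L) {
    stop("records must be a non-empty list of kinematic_record objects")
  }
  ok <- vapply(records, inherits, logical(1), "kinematic_record")
  if (!all(ok)) stop("all elements of records must be kinematic_record objects")
  ids <- vapply(records, `[[`, character(1), "record_id")
  if (anyDuplicated(ids)) {
    stop("duplicate record ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  fs <- vapply(records, `[[`, numeric(1), "sample_rate")
  ms <- vapply(records, function(r) nrow(r$ang_vel), integer(1))
  if (length(unique(fs)) != 1L || length(unique(ms)) != 1L) {
    stop("all records must share sample_rate and length")
  }
  names(records) <- ids
  structure(
    list(records = records, provenance = provenance,
         sample_rate = fs[[1]], n_samples = ms[[1]],
         units = list(lin_acc = "m/s^2", ang_vel = "rad/s", time = "s")),
    class = "kinematic_dataset"
  )
}

#' @export
print.kinematic_dataset <- function(x, ...) {
  cat("<kinematic_dataset> ", length(x$records), " impacts, ",
      x$n_samples, " samples @ ", x$sample_rate, " Hz\n",
      "  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' @export
print.kinematic_record <- function(x, ...) {
  cat("<kinematic_record> ", x$record_id, ": ", nrow(x$ang_vel),
      " samples @ ", x$sample_rate, " Hz\n", sep = "")
  invisible(x)
}

DATASET_HEADER <- c("t", "ax", "ay", "az", "wx", "wy", "wz")

#' Write a kinematic dataset to a directory
#'
#' One CSV per impact with header `t,ax,ay,az,wx,wy,wz` (SI units: s, m/s^2,
#' rad/s), plus a JSON manifest listing the files, sample rate and
#' provenance. The format round-trips losslessly through [read_dataset()].
#'
#' @param dataset A [kinematic_dataset()].
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "kinematic_dataset"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(dataset$records))
  for (i in seq_along(dataset$records)) {
    rec <- dataset$records[[i]]
    files[i] <- paste0(rec$record_id, ".csv")
    df <- data.frame(rec$time, rec$lin_acc, rec$ang_vel)
    colnames(df) <- DATASET_HEADER
    utils::write.csv(df, file.path(path, files[i]), row.names = FALSE)
  }
  manifest <- list(
    format = "impactemu-dataset", format_version = 1L,
    sample_rate = dataset$sample_rate, n_samples = dataset$n_samples,
    provenance = dataset$provenance, units = dataset$units,
    records = data.frame(
      record_id = vapply(dataset$records, `[[`, character(1), "record_id"),
      file = files, row.names = NULL)
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a kinematic dataset written by [write_dataset()]
#'
#' @param path Directory containing `manifest.json` and per-impact CSVs.
#' @return A [kinematic_dataset()].
#' @export
read_dataset <- function(path) {
  manifest_path <- file.path(path, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("not found: ", manifest_path)
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  fs <- manifest$sample_rate
  recs <- vector("list", nrow(manifest$records))
  for (i in seq_len(nrow(manifest$records))) {
    f <- file.path(path, manifest$records$file[i])
    if (!file.exists(f)) stop("not found: ", f)
    df <- utils::read.csv(f)
    if (!identical(colnames(df), DATASET_HEADER)) {
      stop("format error in ", f, ": expected header ",
           paste(DATASET_HEADER, collapse = ","), " but found ",
           paste(colnames(df), collapse = ","))
    }
    recs[[i]] <- kinematic_record(
      record_id = manifest$records$record_id[i],
      lin_acc = as.matrix(df[, c("ax", "ay", "az")]),
      ang_vel = as.matrix(df[, c("wx", "wy", "wz")]),
      sample_rate = fs, time = df$t)
  }
  kinematic_dataset(recs, provenance = manifest$provenance)
}

#' First-order forward difference of a sampled trace
#'
#' Differentiates with `(x[i+1] - x[i]) * sample_rate`; the final value is
#' replicated so the output has the same length as the input, keeping all
#' derived data matrices the same shape as their sources.
#' @noRd
forward_diff <- function(x, sample_rate) {
  m <- length(x)
  if (m < 2L) stop("trace must have at least 2 samples")
  d <- diff(x) * sample_rate
  c(d, d[m - 1L])
}

#' Derive angular acceleration from a record's angular velocity
#'
#' Uses the first-order forward divided difference
#' `alpha[i] = (omega[i+1] - omega[i]) * sample_rate`; the last value is
#' replicated so the output length equals the input length. Matched with
#' rectangle-rule integration this differencing is exactly invertible up to
#' the initial value.
#'
#' @param record A [kinematic_record()] (or an m x 3 angular-velocity
#'   matrix, in which case `sample_rate` must be given).
#' @param sample_rate Required only when `record` is a bare matrix.
#' @return m x 3 matrix of angular acceleration (rad/s^2), directions
#'   coronal/sagittal/axial.
#' @export
derive_angular_acceleration <- function(record, sample_rate = NULL) {
  if (inherits(record, "kinematic_record")) {
    w <- record$ang_vel
    fs <- record$sample_rate
  } else {
    w <- as.matrix(record)
    fs <- sample_rate
    if (is.null(fs)) stop("sample_rate required for matrix input")
  }
  if (nrow(w) < 2L) stop("record must have at least 2 samples")
  out <- apply(w, 2, forward_diff, sample_rate = fs)
  colnames(out) <- ANG_DIRECTIONS
  out
}

#' Elementwise resultant (Euclidean norm) of three traces
#'
#' @param traces An m x 3 matrix, or a list/three vectors of equal length.
#' @return Numeric vector of magnitudes.
#' @export
#' @examples
#' resultant(cbind(3, 4, 0))  # 5
resultant <- function(traces) {
  if (is.list(traces)) {
    if (length(unique(lengths(traces))) != 1L) {
      stop("resultant expects three equal-length traces")
    }
    traces <- do.call(cbind, traces)
  }
  traces <- as.matrix(traces)
  if (ncol(traces) != 3L) stop("resultant expects three equal-length traces")
  sqrt(rowSums(traces^2))
}
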