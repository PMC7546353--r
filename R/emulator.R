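#' Fit a truncated stochastic emulator from a PCA basis
#'
#' Retains the first k temporal modes and singular values and the empirical
#' mean and standard deviation of each retained score vector's n entries.
#' New impacts are produced by [emulate_impacts()], which resamples the
#' scores mode by mode.
#'
#' @param basis A [pca_decompose()] result.
#' @param k Truncation level, `1 <= k <= r`.
#' @return An object of class `emulator_model`.
#' @export
fit_emulator <- function(basis, k) {
  stopifnot(inherits(basis, "pca_basis"))
  k <- as.integer(k)
  if (k < 1L || k > basis$r) stop("k out of range [1, r]")
  idx <- seq_len(k)
  Yk <- basis$Y[, idx, drop = FALSE]
  structure(list(
    k = k, sigma = basis$sigma[idx], U = basis$U[, idx, drop = FALSE],
    score_mean = colMeans(Yk),
    score_sd = apply(Yk, 2, stats::sd),
    scores = Yk,  # retained for the empirical resampling family
    n_fit = nrow(Yk), qoi = basis$qoi, direction = basis$direction,
    sample_rate = basis$sample_rate), class = "emulator_model")
}

#' @export
print.emulator_model <- function(x, ...) {
  cat("<emulator_model> k = ", x$k, " modes (", x$qoi, ", ", x$direction,
      "), fitted on n = ", x$n_fit, "\n", sep = "")
  invisible(x)
}

#' Emulate new impact traces from a fitted model
#'
#' Each emulated column is `x* = sum_{i<=k} sigma_i y*_i u_i` with the
#' scores `y*_i` drawn independently across modes and columns. The default
#' `"gaussian"` family draws `y*_i ~ N(score_mean[i], score_sd[i]^2)`,
#' matching each mode's empirical mean and variance; the `"empirical"`
#' family bootstrap-resamples each mode's fitted scores instead, for data
#' whose scores are visibly non-Gaussian.
#'
#' @param model A [fit_emulator()] result.
#' @param n_new Number of impacts to emulate (>= 1).
#' @param seed Integer seed.
#' @param scores `"gaussian"` (default) or `"empirical"`.
#' @return A [data_matrix()] with `n_new` columns (ids `emulated_...`).
#' @export
emulate_impacts <- function(model, n_new, seed = 1L,
                            scores = c("gaussian", "empirical")) {
  stopifnot(inherits(model, "emulator_model"))
  scores <- match.arg(scores)
  n_new <- as.integer(n_new)
  if (n_new < 1L) stop("n_new must be >= 1")
  set.seed(as.integer(seed))
  Ystar <- matrix(0, n_new, model$k)
  for (i in seq_len(model$k)) {
    Ystar[, i] <- if (scores == "gaussian") {
      rnorm(n_new, model$score_mean[i], model$score_sd[i])
    } else {
      sample(model$scores[, i], n_new, replace = TRUE)
    }
  }
  X <- model$U %*% (model$sigma * t(Ystar))
  data_matrix(X, qoi = model$qoi, direction = model$direction,
              record_ids = sprintf("emulated_%05d", seq_len(n_new)),
              sample_rate = model$sample_rate)
}

# Per-column pulse features of a data matrix: peak time (s), peak
# magnitude, and dominant-impulse duration (s) via detect_pulse; duration
# is NA where no pulse is detectable.
trace_features <- function(X) {
  vals <- X$values
  fs <- X$sample_rate
  m <- nrow(vals)
  peak_idx <- apply(abs(vals), 2, which.max)
  duration <- apply(vals, 2, function(col) {
    tryCatch(detect_pulse(col, fs)$dt, error = function(e) NA_real_)
  })
  data.frame(record_id = X$record_ids,
             peak_time = (peak_idx - 1) / fs,
             peak_magnitude = apply(abs(vals), 2, max),
             duration = duration, row.names = NULL)
}

#' Statistically compare an emulated set against a reference set
#'
#' Computes per-impact features - peak time, peak magnitude, dominant
#' impulse duration (via [detect_pulse()]) - and the projections of the
#' reference's first `k` temporal modes onto both sets, then reports a
#' two-sample Kolmogorov-Smirnov test per feature.
#'
#' @param emulated,reference [data_matrix()] objects for the same QoI with
#'   equal sample rates.
#' @param k Number of reference modes to project onto (default 3).
#' @param alpha Significance level for the `significant` flag (default
#'   0.01).
#' @return A `data.frame` (class `feature_comparison`) with one row per
#'   feature: means/SDs on both sides, KS statistic, p-value, and a
#'   significance flag.
#' @export
compare_features <- function(emulated, reference, k = 3, alpha = 0.01) {
  stopifnot(inherits(emulated, "data_matrix"), inherits(reference, "data_matrix"))
  if (ncol(emulated$values) == 0L || ncol(reference$values) == 0L) {
    stop("both data sets must be non-empty")
  }
  if (!isTRUE(all.equal(emulated$sample_rate, reference$sample_rate))) {
    stop("sample rates must match")
  }
  fe <- trace_features(emulated)
  fr <- trace_features(reference)
  feats <- list(
    peak_time = list(e = fe$peak_time, r = fr$peak_time),
    peak_magnitude = list(e = fe$peak_magnitude, r = fr$peak_magnitude),
    duration = list(e = fe$duration[!is.na(fe$duration)],
                    r = fr$duration[!is.na(fr$duration)]))
  basis_ref <- pca_decompose(reference)
  k <- min(as.integer(k), basis_ref$r)
  for (i in seq_len(k)) {
    u <- basis_ref$U[, i]
    feats[[paste0("mode", i, "_projection")]] <-
      list(e = as.numeric(crossprod(emulated$values, u)),
           r = as.numeric(crossprod(reference$values, u)))
  }
  rows <- lapply(names(feats), function(name) {
    e <- feats[[name]]$e
    r <- feats[[name]]$r
    ks <- suppressWarnings(stats::ks.test(e, r))
    data.frame(feature = name,
               mean_reference = mean(r), sd_reference = stats::sd(r),
               mean_emulated = mean(e), sd_emulated = stats::sd(e),
               statistic = unname(ks$statistic), p_value = ks$p.value,
               significant = ks$p.value < alpha)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("feature_comparison", "data.frame")
  out
}

#' Paired score coordinates for distribution inspection
#'
#' Returns the coordinates of each impact's score on mode 1 paired with its
#' score on modes 2..k, the view used to judge whether modal scores are
#' Gaussian.
#'
#' @param basis A [pca_decompose()] result.
#' @param k Highest mode to pair against mode 1 (`k >= 2`).
#' @return `data.frame(mode_j, y1, yj)` with `n * (k - 1)` rows.
#' @export
score_projections <- function(basis, k) {
  stopifnot(inherits(basis, "pca_basis"))
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (k > basis$r) stop("k out of range [2, r]")
  y1 <- basis$Y[, 1]
  do.call(rbind, lapply(2:k, function(j) {
    data.frame(mode_j = j, y1 = y1, yj = basis$Y[, j])
  }))
}
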