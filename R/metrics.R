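# Windowed power-law functional shared by HIC and RIC: maximum over all
# sample-aligned windows (t1, t2), 0 < t2 - t1 <= max_window, of
#   (t2 - t1) * [ mean of a over the window ] ^ 2.5
# with the window integral taken by trapezoid. Runs in O(m * w_max).
windowed_severity <- function(a, sample_rate, max_window) {
  m <- length(a)
  if (m < 2L) stop("record too short: need at least 2 samples")
  dt <- 1 / sample_rate
  t <- (seq_len(m) - 1) * dt
  ct <- c(0, cumsum((a[-m] + a[-1]) / 2 * dt))  # cumulative trapezoid
  w_max <- min(m - 1L, floor(max_window * sample_rate + 1e-9))
  best <- 0
  for (w in seq_len(w_max)) {
    I <- ct[(1L + w):m] - ct[seq_len(m - w)]
    span <- w * dt
    best <- max(best, max(I)^2.5 / span^1.5)
  }
  best
}

#' Head injury criterion over a 15 ms maximum window (HIC15)
#'
#' Maximum over all sample-aligned windows up to 15 ms of
#' `(t2-t1) * [mean resultant linear acceleration in g]^2.5`, with the
#' resultant linear acceleration converted from m/s^2 using standard
#' gravity 9.80665.
#'
#' @param record A [kinematic_record()].
#' @param max_window Maximum window length in seconds (default 0.015).
#' @return HIC value (dimensionless).
#' @export
#' @examples
#' rec <- kinematic_record("c", matrix(c(100, 0, 0) * 9.80665,
#'                         100, 3, byrow = TRUE), matrix(0, 100, 3))
#' hic15(rec)  # 1500
hic15 <- function(record, max_window = 0.015) {
  stopifnot(inherits(record, "kinematic_record"))
  a_g <- resultant(record$lin_acc) / GRAVITY
  windowed_severity(a_g, record$sample_rate, max_window)
}

#' Rotational injury criterion over a 36 ms maximum window (RIC36)
#'
#' Same windowed functional as [hic15()] applied to the resultant angular
#' acceleration (rad/s^2, derived from angular velocity by forward
#' differencing) with a 36 ms maximum window.
#'
#' @param record A [kinematic_record()].
#' @param max_window Maximum window length in seconds (default 0.036).
#' @return RIC value.
#' @export
ric36 <- function(record, max_window = 0.036) {
  stopifnot(inherits(record, "kinematic_record"))
  alpha <- resultant(derive_angular_acceleration(record))
  windowed_severity(alpha, record$sample_rate, max_window)
}

#' Brain injury criterion (BrIC)
#'
#' `sqrt(sum_d (max_t |omega_d(t)| / omega_crit_d)^2)` with per-axis peak
#' angular velocities taken independently over time. Default critical
#' values (66.25, 56.45, 42.87) rad/s for the coronal/sagittal/axial axes
#' follow the published crash-dummy calibration; all are overridable.
#'
#' @param record A [kinematic_record()].
#' @param critical_values Positive length-3 vector of critical angular
#'   velocities (rad/s).
#' @return BrIC value (dimensionless; 0.5 is the 50% concussion-risk
#'   threshold).
#' @export
bric <- function(record, critical_values = c(coronal = 66.25,
                                             sagittal = 56.45,
                                             axial = 42.87)) {
  stopifnot(inherits(record, "kinematic_record"))
  if (length(critical_values) != 3L || any(critical_values <= 0)) {
    stop("critical_values must be three positive angular velocities")
  }
  peaks <- apply(abs(record$ang_vel), 2, max)
  sqrt(sum((peaks / critical_values)^2))
}

#' Lumped-parameter brain-skull model parameters for BAM
#'
#' Per-axis rotational inertia, torsional stiffness and damping of the
#' rigid-brain / rigid-skull second-order model. No physiological defaults
#' are shipped: the values must come from a calibrated lumped model.
#'
#' @param inertia Rotational inertia (kg m^2), length 3 or scalar.
#' @param stiffness Torsional stiffness (N m/rad), length 3 or scalar.
#' @param damping Torsional damping (N m s/rad), length 3 or scalar.
#' @param substeps Integration substeps per sample interval (default 2).
#' @return A validated list of class `bam_params`.
#' @export
bam_params <- function(inertia, stiffness, damping, substeps = 2L) {
  rec3 <- function(x) if (length(x) == 1L) rep(x, 3) else as.numeric(x)
  inertia <- rec3(inertia); stiffness <- rec3(stiffness); damping <- rec3(damping)
  if (any(lengths(list(inertia, stiffness, damping)) != 3L)) {
    stop("inertia, stiffness and damping must have length 1 or 3")
  }
  if (any(inertia <= 0) || any(stiffness <= 0)) {
    stop("inertia and stiffness must be positive")
  }
  if (any(damping < 0)) stop("damping must be non-negative")
  substeps <- as.integer(substeps)
  if (substeps < 1L) stop("substeps must be >= 1")
  structure(list(inertia = inertia, stiffness = stiffness, damping = damping,
                 substeps = substeps), class = "bam_params")
}

# Fixed-step RK4 for one axis of the base-excitation oscillator
#   I theta'' + c theta' + k theta = -I alpha(t)
# with alpha piecewise-linear between samples; returns theta at every
# substep node (length (m-1)*substeps + 1).
bam_axis_rk4 <- function(alpha, sample_rate, I, k, c, substeps) {
  m <- length(alpha)
  h <- 1 / (sample_rate * substeps)
  n_steps <- (m - 1L) * substeps
  # forcing at substep nodes and midpoints by linear interpolation
  t_nodes <- seq.int(0L, n_steps) * h
  t_data <- (seq_len(m) - 1) / sample_rate
  a_nodes <- stats::approx(t_data, alpha, xout = t_nodes, rule = 2)$y
  a_mid <- stats::approx(t_data, alpha, xout = t_nodes[-1] - h / 2, rule = 2)$y
  theta <- numeric(n_steps + 1L)
  th <- 0; om <- 0
  ci <- c / I; ki <- k / I
  for (s in seq_len(n_steps)) {
    a0 <- a_nodes[s]; am <- a_mid[s]; a1 <- a_nodes[s + 1L]
    f <- function(th_, om_, a_) c(om_, -a_ - ci * om_ - ki * th_)
    k1 <- f(th, om, a0)
    k2 <- f(th + h / 2 * k1[1], om + h / 2 * k1[2], am)
    k3 <- f(th + h / 2 * k2[1], om + h / 2 * k2[2], am)
    k4 <- f(th + h * k3[1], om + h * k3[2], a1)
    th <- th + h / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
    om <- om + h / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
    theta[s + 1L] <- th
  }
  theta
}

#' Brain angle metric (BAM)
#'
#' Drives a per-axis second-order lumped model
#' `I theta'' + c theta' + k theta = -I alpha(t)` from rest with the
#' record's derived head angular acceleration as base excitation, and
#' returns the maximum over time of the Euclidean norm of the three
#' relative brain-skull angles. Integration is fixed-step RK4 at the
#' signal's sample step with optional substepping; the forcing is treated
#' as piecewise-linear between samples.
#'
#' @param record A [kinematic_record()].
#' @param params A [bam_params()].
#' @return Maximum resultant relative brain angle (rad).
#' @export
bam <- function(record, params) {
  stopifnot(inherits(record, "kinematic_record"), inherits(params, "bam_params"))
  alpha <- derive_angular_acceleration(record)
  thetas <- sapply(1:3, function(d) {
    bam_axis_rk4(alpha[, d], record$sample_rate, params$inertia[d],
                 params$stiffness[d], params$damping[d], params$substeps)
  })
  if (!all(is.finite(thetas))) {
    stop("BAM integration unstable: non-finite brain angle; ",
         "max |alpha| = ", signif(max(abs(alpha)), 4),
         ", stiffness = ", paste(signif(params$stiffness, 4), collapse = "/"),
         ", substeps = ", params$substeps)
  }
  max(sqrt(rowSums(thetas^2)))
}

#' Percent error of an approximated injury metric
#'
#' `|approx - gt| / |gt| * 100`, vectorized; records with a zero
#' ground-truth value are flagged as `NA` (excluded, not zeroed).
#'
#' @param approx_value,gt_value Numeric vectors (recycled).
#' @return Percent errors; `NA` where `gt_value == 0`.
#' @export
metric_error <- function(approx_value, gt_value) {
  out <- abs(approx_value - gt_value) / abs(gt_value) * 100
  out[gt_value == 0] <- NA_real_
  out
}

#' Threshold classification of approximated metrics against ground truth
#'
#' Labels both series as positive when the value exceeds the threshold;
#' ground-truth labels define the condition and approximation labels the
#' prediction.
#'
#' @param gt_values,approx_values Equal-length numeric vectors.
#' @param threshold Decision threshold (positive means above).
#' @return An object of class `classification_report`: counts `tp`, `fp`,
#'   `tn`, `fn` and rates `sensitivity`, `specificity` (NA when the
#'   denominator class is empty).
#' @export
#' @examples
#' classify_and_confuse(c(1, 3, 5, 7), c(1, 5, 3, 7), 4)
classify_and_confuse <- function(gt_values, approx_values, threshold) {
  if (length(gt_values) != length(approx_values)) {
    stop("gt_values and approx_values must have equal length")
  }
  gt_pos <- gt_values > threshold
  ap_pos <- approx_values > threshold
  tp <- sum(gt_pos & ap_pos); fn <- sum(gt_pos & !ap_pos)
  fp <- sum(!gt_pos & ap_pos); tn <- sum(!gt_pos & !ap_pos)
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn, n = length(gt_values),
    threshold = threshold,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_),
    class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "<classification_report> thr=%g  tp=%d fp=%d tn=%d fn=%d  sens=%.3f spec=%.3f\n",
    x$threshold, x$tp, x$fp, x$tn, x$fn, x$sensitivity, x$specificity))
  invisible(x)
}

#' Friedman rank test across repeated-measures columns
#'
#' Within-row mid-ranks with the standard tie correction:
#' `chi2 = 12 * sum_j (Rj - n(k+1)/2)^2 / (n k (k+1) - sum(t^3 - t)/(k-1))`
#' where `Rj` are rank column sums and `t` runs over tie-group sizes per
#' row; the p-value comes from the chi-squared distribution with k - 1
#' degrees of freedom. If every row is completely tied the statistic is
#' degenerate and the test returns `chi2 = 0, p = 1` with a warning.
#'
#' @param values Numeric matrix, rows = records, columns = methods
#'   (`n >= 2`, `k >= 2`).
#' @return List with `chi2`, `df`, `p_value`, `n`, `k`.
#' @export
friedman_rank_test <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (n < 2L || k < 2L) stop("need at least 2 records and 2 methods")
  r <- t(apply(values, 1, rank))  # mid-ranks
  tie_term <- sum(apply(values, 1, function(row) {
    tab <- table(row)
    sum(tab^3 - tab)
  }))
  denom <- n * k * (k + 1) - tie_term / (k - 1)
  if (denom <= 0) {
    warning("degenerate Friedman test: all rows completely tied")
    return(list(chi2 = 0, df = k - 1L, p_value = 1, n = n, k = k))
  }
  chi2 <- 12 * sum((colSums(r) - n * (k + 1) / 2)^2) / denom
  list(chi2 = chi2, df = k - 1L,
       p_value = stats::pchisq(chi2, k - 1L, lower.tail = FALSE),
       n = n, k = k)
}

#' Compute injury metrics for every record in a dataset
#'
#' @param dataset A [kinematic_dataset()].
#' @param metrics Subset of `c("hic15", "ric36", "bric", "bam")`.
#' @param bam_parameters A [bam_params()]; required when `"bam"` is
#'   requested.
#' @return `data.frame` with `record_id` and one column per metric.
#' @export
compute_metrics <- function(dataset,
                            metrics = c("hic15", "ric36", "bric"),
                            bam_parameters = NULL) {
  stopifnot(inherits(dataset, "kinematic_dataset"))
  metrics <- match.arg(metrics, c("hic15", "ric36", "bric", "bam"),
                       several.ok = TRUE)
  if ("bam" %in% metrics && is.null(bam_parameters)) {
    stop("bam_parameters required when metric 'bam' is requested")
  }
  out <- data.frame(record_id = names(dataset$records), row.names = NULL)
  for (mt in metrics) {
    out[[mt]] <- vapply(dataset$records, function(rec) {
      switch(mt,
             hic15 = hic15(rec), ric36 = ric36(rec), bric = bric(rec),
             bam = bam(rec, bam_parameters))
    }, numeric(1), USE.NAMES = FALSE)
  }
  out
}
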