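#' Construct a data matrix for one quantity of interest
#'
#' An m x n matrix whose columns are impacts and rows are time steps, for
#' one QoI (linear acceleration, angular velocity, or angular acceleration)
#' in one anatomical direction.
#'
#' @param values Numeric m x n matrix with finite entries.
#' @param qoi One of `"lin_acc"`, `"ang_vel"`, `"ang_acc"`.
#' @param direction Direction index 1..3 or anatomical name.
#' @param record_ids Length-n character vector of impact ids.
#' @param sample_rate Sampling rate in Hz.
#' @return An object of class `data_matrix`.
#' @export
data_matrix <- function(values, qoi, direction, record_ids, sample_rate) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("data matrix entries must be finite")
  qoi <- match.arg(qoi, c("lin_acc", "ang_vel", "ang_acc"))
  d <- resolve_direction(direction, qoi)
  dname <- if (qoi == "lin_acc") LIN_DIRECTIONS[d] else ANG_DIRECTIONS[d]
  if (length(record_ids) != ncol(values)) {
    stop("record_ids must have one entry per column")
  }
  structure(list(values = values, qoi = qoi, direction = dname,
                 record_ids = as.character(record_ids),
                 sample_rate = sample_rate),
            class = "data_matrix")
}

#' @export
print.data_matrix <- function(x, ...) {
  cat("<data_matrix> ", nrow(x$values), " x ", ncol(x$values), " (",
      x$qoi, ", ", x$direction, ") @ ", x$sample_rate, " Hz\n", sep = "")
  invisible(x)
}

#' Assemble the data matrix of one QoI/direction from a dataset
#'
#' Column j is record j's trace for the requested quantity and direction;
#' angular acceleration is derived on the fly via
#' [derive_angular_acceleration()].
#'
#' @param dataset A [kinematic_dataset()].
#' @param qoi `"lin_acc"`, `"ang_vel"` or `"ang_acc"`.
#' @param direction Direction index 1..3 or anatomical name.
#' @return A [data_matrix()] of size m x n.
#' @export
assemble_data_matrix <- function(dataset, qoi = c("ang_vel", "lin_acc", "ang_acc"),
                                 direction = 1) {
  stopifnot(inherits(dataset, "kinematic_dataset"))
  qoi <- match.arg(qoi)
  if (length(dataset$records) == 0L) stop("dataset is empty")
  d <- resolve_direction(direction, qoi)
  cols <- vapply(dataset$records, function(rec) {
    switch(qoi,
           lin_acc = rec$lin_acc[, d],
           ang_vel = rec$ang_vel[, d],
           ang_acc = derive_angular_acceleration(rec)[, d])
  }, numeric(dataset$n_samples))
  data_matrix(unname(cols), qoi = qoi, direction = d,
              record_ids = names(dataset$records),
              sample_rate = dataset$sample_rate)
}

#' Singular value decomposition of a data matrix
#'
#' Computes the economy SVD `X = U diag(sigma) Y^T` with r = min(m, n)
#' modes: `U` holds orthonormal temporal modes, `sigma` the descending
#' singular values, and `Y` orthonormal per-impact score vectors. A
#' deterministic sign convention is applied: each temporal mode is flipped
#' so that its largest-magnitude element is positive (scores flipped to
#' match), making repeated decompositions bit-identical.
#'
#' By default the matrix is factored directly (no mean removal), so the
#' first mode absorbs the mean impact shape; `center = TRUE` removes the
#' mean trace first (exploratory option; reconstruction adds it back).
#'
#' @param X A [data_matrix()] (or bare numeric matrix).
#' @param center Subtract the mean trace before decomposing (default
#'   `FALSE`).
#' @return An object of class `pca_basis` with elements `U` (m x r),
#'   `sigma` (length r), `Y` (n x r), `r`, optional `center`, and source
#'   metadata.
#' @export
pca_decompose <- function(X, center = FALSE) {
  meta <- list(qoi = NA_character_, direction = NA_character_,
               record_ids = NULL, sample_rate = NA_real_)
  if (inherits(X, "data_matrix")) {
    meta <- X[c("qoi", "direction", "record_ids", "sample_rate")]
    X <- X$values
  }
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("data matrix entries must be finite")
  mean_trace <- NULL
  if (isTRUE(center)) {
    mean_trace <- rowMeans(X)
    X <- X - mean_trace
  }
  s <- svd(X)
  r <- length(s$d)
  for (i in seq_len(r)) {
    j <- which.max(abs(s$u[, i]))
    if (s$u[j, i] < 0) {
      s$u[, i] <- -s$u[, i]
      s$v[, i] <- -s$v[, i]
    }
  }
  structure(list(U = s$u, sigma = s$d, Y = s$v, r = r,
                 center = mean_trace,
                 qoi = meta$qoi, direction = meta$direction,
                 record_ids = meta$record_ids,
                 sample_rate = meta$sample_rate),
            class = "pca_basis")
}

#' @export
print.pca_basis <- function(x, ...) {
  cat("<pca_basis> ", nrow(x$U), " x ", nrow(x$Y), " source (",
      x$qoi, ", ", x$direction, "), r = ", x$r, "\n",
      "  leading singular values: ",
      paste(signif(utils::head(x$sigma, 5), 4), collapse = ", "),
      if (x$r > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Fraction of summed singular values captured by the first k modes
#'
#' `eta(k) = sum(sigma[1:k]) / sum(sigma)`, the reduction-quality criterion
#' (first-power singular values, not squared). `eta(0) = 0`, `eta(r) = 1`.
#' A squared-singular-value (variance-fraction) variant is available via
#' `squared = TRUE` but is never the default.
#'
#' @param basis A [pca_decompose()] result.
#' @param k Number of retained modes, `0 <= k <= r`.
#' @param squared Use squared singular values (default `FALSE`).
#' @return Fraction in `[0, 1]`.
#' @export
energy_fraction <- function(basis, k, squared = FALSE) {
  stopifnot(inherits(basis, "pca_basis"))
  k <- as.integer(k)
  if (k < 0L || k > basis$r) stop("k out of range [0, r]")
  if (k == 0L) return(0)
  s <- if (isTRUE(squared)) basis$sigma^2 else basis$sigma
  sum(s[seq_len(k)]) / sum(s)
}

#' Minimal number of modes meeting an eta target
#'
#' Smallest k with `energy_fraction(basis, k) >= eta_target`.
#'
#' @param basis A [pca_decompose()] result.
#' @param eta_target Target fraction in `(0, 1]`; 0.90 is the reduction
#'   criterion used throughout.
#' @param squared Use squared singular values (default `FALSE`).
#' @return Integer mode count.
#' @export
min_modes <- function(basis, eta_target = 0.90, squared = FALSE) {
  stopifnot(inherits(basis, "pca_basis"))
  if (!is.numeric(eta_target) || eta_target <= 0 || eta_target > 1) {
    stop("eta_target must be in (0, 1]")
  }
  s <- if (isTRUE(squared)) basis$sigma^2 else basis$sigma
  eta <- cumsum(s) / sum(s)
  which(eta >= eta_target - 1e-12)[1]
}

#' Rank-k reconstruction of the source data matrix
#'
#' `X_k = sum_{i<=k} sigma_i u_i y_i^T`, the best rank-k approximation in
#' the Frobenius norm (truncation error `sqrt(sum(sigma[(k+1):r]^2))`).
#'
#' @param basis A [pca_decompose()] result.
#' @param k Number of modes, `1 <= k <= r`.
#' @return A [data_matrix()] with the source metadata.
#' @export
pca_reconstruct <- function(basis, k) {
  stopifnot(inherits(basis, "pca_basis"))
  k <- as.integer(k)
  if (k < 1L || k > basis$r) stop("k out of range [1, r]")
  idx <- seq_len(k)
  Xk <- basis$U[, idx, drop = FALSE] %*%
    (basis$sigma[idx] * t(basis$Y[, idx, drop = FALSE]))
  if (!is.null(basis$center)) Xk <- Xk + basis$center
  if (is.na(basis$qoi)) return(Xk)
  data_matrix(Xk, qoi = basis$qoi, direction = basis$direction,
              record_ids = basis$record_ids, sample_rate = basis$sample_rate)
}

#' Mode-count convergence under subsampling
#'
#' Repeatedly subsamples the dataset without replacement at each requested
#' size, decomposes the subsampled data matrix and records the minimal mode
#' count meeting `eta_target`. Used to judge whether the dataset is large
#' enough that the required mode count has levelled off.
#'
#' @param dataset A [kinematic_dataset()].
#' @param qoi,direction Passed to [assemble_data_matrix()].
#' @param subset_sizes Integer vector of subsample sizes (each `<= n`).
#' @param n_repeats Subsamples per size (>= 1).
#' @param eta_target Reduction criterion (default 0.90).
#' @param seed Integer seed; each (size, repeat) cell gets its own derived
#'   seed so results are reproducible cell-by-cell.
#' @return `data.frame(subset_size, repeat_index, k_min)`.
#' @export
convergence_analysis <- function(dataset, qoi = "ang_vel", direction = 1,
                                 subset_sizes = c(100, 200, 300, 400, 500),
                                 n_repeats = 5, eta_target = 0.90, seed = 1L) {
  stopifnot(inherits(dataset, "kinematic_dataset"))
  n <- length(dataset$records)
  subset_sizes <- as.integer(subset_sizes)
  if (any(subset_sizes > n)) stop("subset size exceeds dataset size")
  if (any(subset_sizes < 1L)) stop("subset sizes must be >= 1")
  if (n_repeats < 1L) stop("n_repeats must be >= 1")
  X <- assemble_data_matrix(dataset, qoi = qoi, direction = direction)
  out <- expand.grid(repeat_index = seq_len(n_repeats),
                     subset_size = subset_sizes)[, 2:1]
  out$k_min <- NA_integer_
  for (row in seq_len(nrow(out))) {
    size <- out$subset_size[row]
    rep_i <- out$repeat_index[row]
    set.seed(seed + 131L * match(size, subset_sizes) + rep_i)
    cols <- sample.int(n, size, replace = FALSE)
    sub <- data_matrix(X$values[, cols, drop = FALSE], qoi = X$qoi,
                       direction = X$direction,
                       record_ids = X$record_ids[cols],
                       sample_rate = X$sample_rate)
    out$k_min[row] <- min_modes(pca_decompose(sub), eta_target)
  }
  rownames(out) <- NULL
  out
}
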