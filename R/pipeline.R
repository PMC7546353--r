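#' Approximate a dataset with a low-rank or biphasic representation
#'
#' Rebuilds every channel of every record under one of the competing
#' representations:
#'
#' * `"pca"`: per QoI/direction, the data matrix is decomposed and
#'   reconstructed with the minimal mode count meeting `eta` (applied to
#'   angular velocity and linear acceleration; angular acceleration then
#'   follows by differencing).
#' * `"triangle"` / `"half_sine"`: per record and direction, the dominant
#'   impulse of the angular *acceleration* is detected, replaced by the
#'   idealized pulse, and integrated back to angular velocity; linear
#'   acceleration channels are fitted and replaced directly.
#'
#' Channels with no detectable pulse (identically zero) are left at zero.
#'
#' @param dataset A [kinematic_dataset()].
#' @param method `"pca"`, `"triangle"` or `"half_sine"`.
#' @param eta Reduction criterion for the PCA branch (default 0.90).
#' @return A [kinematic_dataset()] with the same ids and sample rate.
#' @export
approximate_dataset <- function(dataset, method = c("pca", "triangle", "half_sine"),
                                eta = 0.90) {
  stopifnot(inherits(dataset, "kinematic_dataset"))
  method <- match.arg(method)
  fs <- dataset$sample_rate
  m <- dataset$n_samples
  n <- length(dataset$records)
  ids <- names(dataset$records)
  new_ang <- array(0, c(m, 3, n))
  new_lin <- array(0, c(m, 3, n))
  if (method == "pca") {
    for (d in 1:3) {
      for (qoi in c("ang_vel", "lin_acc")) {
        X <- assemble_data_matrix(dataset, qoi = qoi, direction = d)
        basis <- pca_decompose(X)
        k <- min_modes(basis, eta)
        Xk <- pca_reconstruct(basis, k)$values
        if (qoi == "ang_vel") new_ang[, d, ] <- Xk else new_lin[, d, ] <- Xk
      }
    }
  } else {
    time_grid <- (seq_len(m) - 1) / fs
    fit_channel <- function(trace) {
      window <- tryCatch(detect_pulse(trace, fs), error = function(e) NULL)
      if (is.null(window)) return(numeric(m))
      synthesize_pulse(fit_biphasic(window, method), time_grid)
    }
    for (j in seq_len(n)) {
      rec <- dataset$records[[j]]
      alpha <- derive_angular_acceleration(rec)
      for (d in 1:3) {
        a_syn <- fit_channel(alpha[, d])
        new_ang[, d, j] <- integrate_to_velocity(a_syn, fs, omega0 = 0)
        new_lin[, d, j] <- fit_channel(rec$lin_acc[, d])
      }
    }
  }
  records <- lapply(seq_len(n), function(j) {
    kinematic_record(ids[j], lin_acc = new_lin[, , j],
                     ang_vel = new_ang[, , j], sample_rate = fs)
  })
  kinematic_dataset(records, provenance = paste0(
    dataset$provenance, " | approximated: ", method,
    if (method == "pca") sprintf(" (eta=%.2f)", eta) else ""))
}
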