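# Shared fixtures. The BAM lumped-model parameters are synthetic but
# representative: brain rotational inertia 0.016 kg m^2, stiffness giving a
# ~15 Hz natural frequency, damping ratio ~0.3.
test_bam_params <- function(substeps = 2L) {
  bam_params(inertia = 0.016, stiffness = 142, damping = 0.9,
             substeps = substeps)
}

# Small realistic dataset reused across tests (generation is cheap).
small_dataset <- function(n = 12, seed = 401, ...) {
  generate_impact_dataset(impact_config(n, seed = seed, ...))
}

# A record with prescribed angular velocity (m x 3) and zero linear
# acceleration, or vice versa.
record_from_angvel <- function(w, id = "w", fs = 1000) {
  kinematic_record(id, lin_acc = matrix(0, nrow(w), 3), ang_vel = w,
                   sample_rate = fs)
}
record_from_linacc <- function(a, id = "a", fs = 1000) {
  kinematic_record(id, lin_acc = a, ang_vel = matrix(0, nrow(a), 3),
                   sample_rate = fs)
}

# Brute-force oracle for the windowed severity functionals: explicit
# O(m^2) search over all sample-aligned window pairs with trapezoidal
# integrals, independent of the packaged implementation.
brute_windowed <- function(a, fs, max_window) {
  m <- length(a)
  dt <- 1 / fs
  best <- 0
  for (i1 in 1:(m - 1)) {
    for (i2 in (i1 + 1):m) {
      span <- (i2 - i1) * dt
      if (span > max_window + 1e-12) break
      seg <- a[i1:i2]
      I <- sum((seg[-1] + seg[-length(seg)]) / 2) * dt
      best <- max(best, span * (I / span)^2.5)
    }
  }
  best
}

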