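fs <- 1000
tgrid <- 0:99 / fs

# piecewise-linear triangle on the sample grid
triangle_trace <- function(t0, tM, t1, amp, t = tgrid) {
  up <- t >= t0 & t <= tM
  down <- t > tM & t <= t1
  out <- numeric(length(t))
  out[up] <- amp * (t[up] - t0) / (tM - t0)
  out[down] <- amp * (t1 - t[down]) / (t1 - tM)
  out
}

test_that("pulse detection recovers planted triangle windows", {
  tri <- triangle_trace(0.020, 0.027, 0.035, 200)
  w <- detect_pulse(tri, fs)
  expect_lte(abs(w$t0 - 0.020), 1e-3 + 1e-12)
  expect_lte(abs(w$t1 - 0.035), 1e-3 + 1e-12)
  expect_equal(w$t_M, 0.027)
  expect_equal(w$alpha_M, 200)
  # analytic area of the triangle: amp * dt / 2 = 1.5 rad/s
  expect_lt(abs(w$delta_omega - 1.5) / 1.5, 0.01)
  expect_identical(w$half_pulse, "none")
})

test_that("pulse detection is idempotent on synthesized triangles", {
  set.seed(12)
  for (i in 1:20) {
    t0 <- sample(10:40, 1) / fs
    dtp <- sample(6:30, 1) / fs
    tM <- t0 + round(runif(1, 0.2, 0.8) * dtp * fs) / fs
    if (tM <= t0) tM <- t0 + 1 / fs
    if (tM >= t0 + dtp) tM <- t0 + dtp - 1 / fs
    amp <- runif(1, 50, 500) * sample(c(-1, 1), 1)
    tri <- triangle_trace(t0, tM, t0 + dtp, amp)
    w <- detect_pulse(tri, fs)
    expect_lte(abs(w$t0 - t0), 1e-3 + 1e-12)
    expect_lte(abs(w$t1 - (t0 + dtp)), 1e-3 + 1e-12)
  }
})

test_that("edge-peaked traces trigger the half-pulse rule", {
  # peak at the very first sample
  x <- c(300, 250, 180, 90, 10, -20, -10, rep(0, 93))
  w <- detect_pulse(x, fs)
  expect_identical(w$half_pulse, "right_only")
  expect_equal(w$t0, w$t_M)
  # peak at the very last sample
  wr <- detect_pulse(rev(x), fs)
  expect_identical(wr$half_pulse, "left_only")
  expect_equal(wr$t1, wr$t_M)
})

test_that("a full sine period has boundaries at the zero crossings", {
  # 20 Hz tone: one period in 50 ms, crests at 12.5 and zero crossings at
  # 0/25/50 ms after onset
  x <- numeric(100)
  seg <- 0:50
  x[11 + seg] <- sin(2 * pi * 20 * seg / fs)
  w <- detect_pulse(x, fs)
  expect_lte(abs(w$t_M - (0.010 + 0.0125)), 1e-3 + 1e-12)
  expect_lte(abs(w$t0 - 0.010), 1e-3 + 1e-12)
  expect_lte(abs(w$t1 - 0.035), 1e-3 + 1e-12)
})

test_that("degenerate traces are rejected", {
  expect_error(detect_pulse(numeric(100), fs), "no pulse")
  expect_error(detect_pulse(c(1, 2), fs), "too short")
})

test_that("biphasic amplitudes follow the area-preserving closed forms", {
  w <- detect_pulse(triangle_trace(0.020, 0.025, 0.030, 100), fs)
  w$delta_omega <- 1
  w$dt <- 0.01
  expect_equal(fit_biphasic(w, "triangle")$amplitude, 200)
  expect_equal(fit_biphasic(w, "half_sine")$amplitude, pi / 2 * 100)
  # the ratio 4/pi is forced by the closed forms for any window
  for (dw in c(0.3, -1.2, 5)) {
    w$delta_omega <- dw
    r <- fit_biphasic(w, "triangle")$amplitude /
      fit_biphasic(w, "half_sine")$amplitude
    expect_equal(r, 4 / pi)
  }
  w$dt <- 0
  expect_error(fit_biphasic(w, "triangle"), "positive")
})

test_that("synthesized pulses conserve the velocity change and respect support", {
  set.seed(5)
  for (shape in c("triangle", "half_sine")) {
    for (i in 1:10) {
      tri <- triangle_trace(0.02, 0.02 + sample(3:10, 1) / fs,
                            0.02 + sample(12:30, 1) / fs,
                            runif(1, 50, 400))
      w <- detect_pulse(tri, fs)
      p <- fit_biphasic(w, shape)
      x <- synthesize_pulse(p, tgrid)
      # area conservation to 0.5% at 1 kHz
      expect_lt(abs(pracma::trapz(tgrid, x) - w$delta_omega) /
                  abs(w$delta_omega), 0.005)
      # zero outside the window
      expect_true(all(x[tgrid < w$t0 - 1e-12 | tgrid > w$t1 + 1e-12] == 0))
    }
  }
  # peak values by construction
  w <- detect_pulse(triangle_trace(0.020, 0.026, 0.034, 150), fs)
  ptri <- fit_biphasic(w, "triangle")
  xtri <- synthesize_pulse(ptri, tgrid)
  expect_equal(xtri[which.min(abs(tgrid - w$t_M))], ptri$amplitude)
  phs <- fit_biphasic(w, "half_sine")
  xhs <- synthesize_pulse(phs, tgrid)
  expect_equal(max(xhs), phs$amplitude, tolerance = 1e-2)
  # grid coarser than the pulse is rejected
  expect_error(synthesize_pulse(ptri, seq(0, 0.1, by = 0.05)), "coarser")
})

test_that("integration to velocity plateaus at the velocity change", {
  # constant acceleration: omega(T) = a T
  a <- rep(12, 100)
  w_out <- integrate_to_velocity(a, fs, omega0 = 0)
  expect_equal(w_out[100], 12 * 0.099, tolerance = 1e-12)
  # synthesized biphasic pulse: omega settles at delta_omega after t1
  w <- detect_pulse(triangle_trace(0.020, 0.026, 0.034, 150), fs)
  x <- synthesize_pulse(fit_biphasic(w, "triangle"), tgrid)
  v <- integrate_to_velocity(x, fs)
  after <- tgrid > w$t1 + 1e-12
  expect_lt(max(abs(v[after] - w$delta_omega)) / abs(w$delta_omega), 0.005)
  expect_equal(diff(range(v[after])), 0)
  # zero acceleration keeps omega at omega0
  expect_equal(integrate_to_velocity(numeric(50), fs, omega0 = 3), rep(3, 50))
})

test_that("triangle peak bounds the original peak for matched area and duration", {
  # sub-triangular pulses (half-sine lobes): with the same delta_omega and
  # dt, the fitted triangle must peak at least as high
  set.seed(8)
  for (i in 1:10) {
    dtp <- sample(8:30, 1) / fs
    amp <- runif(1, 50, 400)
    x <- numeric(100)
    idx <- which(tgrid >= 0.02 & tgrid <= 0.02 + dtp)
    x[idx] <- amp * sin(pi * (tgrid[idx] - 0.02) / dtp)
    w <- detect_pulse(x, fs)
    tri_amp <- fit_biphasic(w, "triangle")$amplitude
    hs_amp <- fit_biphasic(w, "half_sine")$amplitude
    expect_gte(abs(tri_amp), max(abs(x)) * 0.999)
    expect_lte(abs(hs_amp), abs(tri_amp))
  }
})
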