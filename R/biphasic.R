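# sign with 0 as its own state: a boundary is any pair of consecutive
# samples whose signs differ, so touching zero counts as a change.
sign_change <- function(a, b) sign(a) != sign(b)

#' Locate the dominant acceleration impulse in a trace
#'
#' The peak time `t_M` is the sample of maximum absolute value. Scanning
#' outward from the peak, the initiation time `t0` (backward) and
#' completion time `t1` (forward) are set at the first samples where either
#' the trace's sign changes (zeros count) or its second derivative -
#' three-point central stencil - changes sign, whichever occurs first; the
#' boundary is placed on the outer sample (away from `t_M`) of the first
#' offending pair, so a pulse that touches zero keeps its zero-valued
#' endpoints and the trapezoidal area below is unbiased. The velocity change `delta_omega` is the trapezoidal
#' integral of the trace over `[t0, t1]`. If the peak sits at (or within
#' one sample of) either record end, only the available side is
#' characterized and `half_pulse` is set. When no sign/convexity change
#' exists before a record edge the boundary is clamped to the edge and the
#' window flagged (`clamped`).
#'
#' @param alpha_trace Numeric acceleration trace (length >= 3).
#' @param sample_rate Sampling rate in Hz.
#' @param quadrature `"trapezoid"` (default) or `"rectangle"` rule for the
#'   area under the impulse (sensitivity-check alternative).
#' @return An object of class `pulse_window` with fields `t_M`, `alpha_M`
#'   (signed peak), `t0`, `t1`, `dt`, `delta_omega`, `half_pulse`
#'   (`"none"`, `"left_only"`, `"right_only"`) and `clamped`.
#' @export
#' @examples
#' t <- 0:99 / 1000
#' tri <- pmax(0, 1 - abs(t - 0.027) / 0.007) * 200
#' detect_pulse(tri, 1000)
detect_pulse <- function(alpha_trace, sample_rate,
                         quadrature = c("trapezoid", "rectangle")) {
  quadrature <- match.arg(quadrature)
  x <- as.numeric(alpha_trace)
  m <- length(x)
  if (m < 3L) stop("trace too short: need at least 3 samples")
  if (max(abs(x)) == 0) stop("no pulse: trace is identically zero")
  dt <- 1 / sample_rate
  i_M <- which.max(abs(x))
  # 3-point central second derivative on interior samples (index i valid
  # for 2..m-1); scale factor irrelevant for sign tests.
  d2 <- c(NA, x[1:(m - 2)] - 2 * x[2:(m - 1)] + x[3:m], NA)
  # flush rounding noise on exactly-straight segments to zero so the
  # convexity test sees them as flat
  d2[!is.na(d2) & abs(d2) < 1e-9 * max(abs(x))] <- 0
  boundary_ok <- function(i, j) {
    # is there a change between inner sample i and outer sample j? The
    # convexity test skips pairs touching the peak: a kinked peak carries a
    # second-derivative spike that is not an impulse boundary.
    if (sign_change(x[i], x[j])) return(TRUE)
    if (i != i_M && !is.na(d2[i]) && !is.na(d2[j]) &&
        sign_change(d2[i], d2[j])) return(TRUE)
    FALSE
  }
  scan <- function(step) {
    i <- i_M
    clamped <- FALSE
    repeat {
      j <- i + step
      if (j < 1L || j > m) { clamped <- TRUE; break }
      if (boundary_ok(i, j)) { i <- j; break }  # boundary on the outer sample
      i <- j
    }
    list(index = i, clamped = clamped)
  }
  half_pulse <- "none"
  clamped <- FALSE
  if (i_M <= 2L) {
    half_pulse <- "right_only"
    fwd <- scan(+1L)
    i0 <- i_M; i1 <- fwd$index; clamped <- fwd$clamped
  } else if (i_M >= m - 1L) {
    half_pulse <- "left_only"
    bwd <- scan(-1L)
    i0 <- bwd$index; i1 <- i_M; clamped <- bwd$clamped
  } else {
    bwd <- scan(-1L)
    fwd <- scan(+1L)
    i0 <- bwd$index; i1 <- fwd$index
    clamped <- bwd$clamped || fwd$clamped
  }
  if (i1 <= i0) i1 <- min(i0 + 1L, m)
  tt <- (seq_len(m) - 1L) * dt
  dw <- if (quadrature == "trapezoid") {
    pracma::trapz(tt[i0:i1], x[i0:i1])
  } else {
    sum(x[i0:(i1 - 1L)]) * dt
  }
  structure(list(t_M = tt[i_M], alpha_M = x[i_M], t0 = tt[i0], t1 = tt[i1],
                 dt = tt[i1] - tt[i0], delta_omega = dw,
                 half_pulse = half_pulse, clamped = clamped,
                 sample_rate = sample_rate),
            class = "pulse_window")
}

#' @export
print.pulse_window <- function(x, ...) {
  cat(sprintf(
    "<pulse_window> t0=%.3fs tM=%.3fs t1=%.3fs dt=%.3fs peak=%.4g dOmega=%.4g%s%s\n",
    x$t0, x$t_M, x$t1, x$dt, x$alpha_M, x$delta_omega,
    if (x$half_pulse != "none") paste0(" [", x$half_pulse, "]") else "",
    if (x$clamped) " [clamped]" else ""))
  invisible(x)
}

#' Fit a biphasic (triangle or half-sine) pulse to a detected window
#'
#' The pulse amplitude is chosen so that the idealized shape carries the
#' window's velocity change over its duration:
#' `amp_tri = 2 * delta_omega / dt` for the triangle and
#' `amp_hs = (pi / 2) * delta_omega / dt` for the half-sine, so the two
#' amplitudes always stand in the ratio 4/pi.
#'
#' @param window A [detect_pulse()] result.
#' @param shape `"triangle"` or `"half_sine"`.
#' @return An object of class `biphasic_pulse` holding the shape, the
#'   window, and the signed `amplitude`.
#' @export
fit_biphasic <- function(window, shape = c("triangle", "half_sine")) {
  stopifnot(inherits(window, "pulse_window"))
  shape <- match.arg(shape)
  if (window$dt <= 0) stop("window duration dt must be positive")
  amplitude <- switch(shape,
                      triangle = 2 * window$delta_omega / window$dt,
                      half_sine = (pi / 2) * window$delta_omega / window$dt)
  structure(list(shape = shape, window = window, amplitude = amplitude),
            class = "biphasic_pulse")
}

#' @export
print.biphasic_pulse <- function(x, ...) {
  cat(sprintf("<biphasic_pulse> %s, amplitude=%.4g over dt=%.3fs\n",
              x$shape, x$amplitude, x$window$dt))
  invisible(x)
}

#' Synthesize a biphasic pulse on a time grid
#'
#' Triangle: linear rise from 0 at `t0` to the amplitude at `t_M`, linear
#' fall back to 0 at `t1`. Half-sine: `amplitude * sin(pi*(t - t0)/dt)` on
#' `[t0, t1]`, discretized by averaging the continuous pulse over each
#' sample cell so the sampled pulse carries exactly the analytic area
#' `delta_omega` (the triangle's point samples are already area-exact
#' because its vertices lie on the grid). Zero everywhere outside the
#' window; half pulses emit only the defined side (the peak sits at the
#' window's closed end).
#'
#' @param pulse A [fit_biphasic()] result.
#' @param time_grid Time vector (s) covering `[t0, t1]`.
#' @return Numeric trace on `time_grid`.
#' @export
synthesize_pulse <- function(pulse, time_grid) {
  stopifnot(inherits(pulse, "biphasic_pulse"))
  w <- pulse$window
  t <- as.numeric(time_grid)
  step <- stats::median(diff(t))
  if (step > w$dt * (1 + 1e-9)) {
    stop("time grid is coarser than the pulse duration")
  }
  amp <- pulse$amplitude
  out <- numeric(length(t))
  if (pulse$shape == "half_sine") {
    # cell-average of amp*sin(pi*(s - t0)/dt) over [t-h/2, t+h/2] clamped
    # to the pulse support: h * sum(out) equals delta_omega exactly
    lo <- pmax(t - step / 2, w$t0)
    hi <- pmin(t + step / 2, w$t1)
    inside <- hi > lo
    out[inside] <- amp * w$dt / (pi * step) *
      (cos(pi * (lo[inside] - w$t0) / w$dt) -
         cos(pi * (hi[inside] - w$t0) / w$dt))
  } else {
    # peak position: at t_M for a full window, at the closed end for halves
    t_peak <- switch(w$half_pulse, none = w$t_M,
                     right_only = w$t0, left_only = w$t1)
    up <- t >= w$t0 & t <= t_peak & t_peak > w$t0
    down <- t > t_peak & t <= w$t1
    if (t_peak > w$t0) out[up] <- amp * (t[up] - w$t0) / (t_peak - w$t0)
    if (w$t1 > t_peak) {
      out[down] <- amp * (w$t1 - t[down]) / (w$t1 - t_peak)
    }
    if (t_peak == w$t0 && any(t == t_peak)) out[t == t_peak] <- amp
  }
  out
}

#' Integrate an acceleration trace to velocity
#'
#' Cumulative trapezoidal integral plus the initial velocity. After a
#' synthesized biphasic pulse returns to zero the velocity stays constant
#' at `omega0 + delta_omega`.
#'
#' @param alpha_trace Acceleration trace.
#' @param sample_rate Sampling rate in Hz.
#' @param omega0 Initial velocity (default 0).
#' @return Velocity trace of the same length.
#' @export
integrate_to_velocity <- function(alpha_trace, sample_rate, omega0 = 0) {
  x <- as.numeric(alpha_trace)
  if (!all(is.finite(x))) stop("trace must be finite")
  t <- (seq_along(x) - 1) / sample_rate
  as.numeric(pracma::cumtrapz(t, x)) + omega0
}
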