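# Tissue equivalent-circuit estimation from constant-current pulse responses.
#
# The electrode-tissue interface is modeled as a series resistance Rs in line
# with a parallel RC pair (Rp, Cp). Under a constant current i the driven
# voltage is
#
#   V(t) = i*Rs + i*Rp*(1 - exp(-t/tau)),   tau = Rp*Cp,
#
# so the waveform jumps to V0 = i*Rs at the rising edge (the capacitor is
# initially a short), charges with time constant tau, and saturates at
# Vx = i*(Rs + Rp). Rs and Rp follow from the two landmark voltages; tau is
# recovered by least-squares fitting of the charging segment and Cp = tau/Rp.

#' Pulse response of a constant-current stimulus
#'
#' Container for one sampled driven-voltage waveform together with its
#' detected landmarks: the rising-edge time `t0`, the plateau-start time
#' `tx`, the voltage `v0` immediately after the rising edge and the
#' saturated plateau voltage `vx`.
#'
#' @param time Sample times in seconds, strictly increasing and uniformly
#'   spaced (within 1 ppm).
#' @param voltage Sampled voltage in volts, same length as `time`.
#' @param current Constant pulse amplitude in amperes (> 0).
#' @param t0,tx Rising-edge and plateau-start times in seconds, `t0 < tx`.
#' @param v0,vx Edge and plateau voltages in volts.
#' @param pulse_end Time of the last pulse sample in seconds (falling edge,
#'   or the end of the record if the pulse runs to the end).
#'
#' @return An object of class `pulse_response`.
#' @seealso [detect_pulse_edges()] which constructs one from a raw waveform,
#'   [fit_rc_from_pulse()].
#' @export
pulse_response <- function(time, voltage, current, t0, tx, v0, vx,
                           pulse_end = time[length(time)]) {
  time <- as.numeric(time)
  voltage <- as.numeric(voltage)
  if (length(time) != length(voltage)) {
    nl_stop("malformed_input", "time and voltage must have equal length")
  }
  dt <- diff(time)
  if (any(dt <= 0)) {
    nl_stop("malformed_input", "time must be strictly increasing")
  }
  if (length(dt) > 1 && (max(dt) - min(dt)) > 1e-6 * mean(dt)) {
    nl_stop("malformed_input", "time must be uniformly sampled (within 1 ppm)")
  }
  if (!is.numeric(current) || length(current) != 1 || current <= 0) {
    nl_stop("malformed_input", "current must be a single positive number")
  }
  if (!(t0 < tx) || tx > time[length(time)]) {
    nl_stop("malformed_input", "landmarks must satisfy t0 < tx <= last sample")
  }
  structure(
    list(
      time = time, voltage = voltage, current = current,
      sample_rate = 1 / mean(dt),
      t0 = t0, tx = tx, v0 = v0, vx = vx, pulse_end = pulse_end
    ),
    class = "pulse_response"
  )
}

#' @export
print.pulse_response <- function(x, ...) {
  cat(sprintf(
    "<pulse_response> %d samples @ %.4g Hz, i = %.4g A\n  t0 = %.4g s, tx = %.4g s, V0 = %.4g V, Vx = %.4g V\n",
    length(x$time), x$sample_rate, x$current, x$t0, x$tx, x$v0, x$vx
  ))
  invisible(x)
}

#' Detect the stimulus pulse and its landmark voltages in a raw waveform
#'
#' Locates the single constant-current pulse in a sampled voltage trace and
#' measures the landmarks needed for equivalent-circuit estimation: the
#' rising-edge time `t0`, the voltage `v0` at the edge, the plateau-start
#' time `tx` (where the charging slope has decayed below a fraction of its
#' initial value) and the plateau voltage `vx`.
#'
#' Edges are found on the forward difference of the trace: a rising (falling)
#' edge is a run of consecutive differences exceeding `noise_mult` times the
#' pre-pulse noise SD (or, for noiseless traces, a small fraction of the
#' voltage range). Exactly one pulse must be present.
#'
#' @param waveform Either a numeric voltage vector (with `sample_rate`
#'   supplied) or a two-column data frame with columns `time_s`, `voltage_V`.
#' @param current Stimulus current in amperes.
#' @param sample_rate Sampling rate in Hz; required when `waveform` is a bare
#'   numeric vector.
#' @param noise_mult Edge threshold as a multiple of the pre-pulse noise SD.
#' @param slope_frac Fraction of the initial charging slope below which the
#'   plateau is considered reached (defines `tx`).
#' @param v0_method `"edge"` (default) takes `v0` as the voltage at the first
#'   pulse sample — exact for a sampled RC charging curve, whose value at the
#'   edge instant is `i*Rs`; `"median3"` takes the median of the first three
#'   pulse samples, slightly more noise-robust but biased upward by
#'   charging within those samples.
#'
#' @return A [pulse_response()].
#' @export
detect_pulse_edges <- function(waveform, current, sample_rate = NULL,
                               noise_mult = 10, slope_frac = 0.01,
                               v0_method = c("edge", "median3")) {
  v0_method <- match.arg(v0_method)
  if (is.data.frame(waveform)) {
    if (!all(c("time_s", "voltage_V") %in% names(waveform))) {
      nl_stop("malformed_input", "waveform data frame needs columns time_s, voltage_V")
    }
    time <- as.numeric(waveform$time_s)
    v <- as.numeric(waveform$voltage_V)
  } else {
    if (is.null(sample_rate)) {
      nl_stop("malformed_input", "sample_rate is required for a bare voltage vector")
    }
    v <- as.numeric(waveform)
    time <- seq_along(v) / sample_rate - 1 / sample_rate
  }
  n <- length(v)
  if (n < 16) nl_stop("malformed_input", "waveform must have at least 16 samples")

  rng <- max(v) - min(v)
  if (rng == 0) nl_stop("no_pulse", "no rising edge detected (flat waveform)")

  # Pulse region = run of samples above the pre-pulse baseline by more than
  # the noise threshold. Thresholding the values (not the sample-to-sample
  # differences) keeps detection robust for slowly charging responses whose
  # per-sample increments sit below the noise floor; on noiseless traces the
  # range-fraction floor makes the detected edge exact.
  n_base <- max(8L, floor(0.04 * n))
  base <- v[seq_len(min(n_base, n))]
  thr <- max(noise_mult * stats::sd(base), 0.02 * rng)
  above <- which(v - stats::median(base) > thr)
  if (length(above) == 0) {
    nl_stop("no_pulse", "no rising edge exceeds the noise threshold")
  }

  # Collapse indices into runs; runs separated by small gaps (noise flicker
  # around the threshold) are merged, and isolated spikes shorter than 3
  # samples are discarded.
  gap <- max(3L, ceiling(0.01 * n))
  breaks <- which(diff(above) > gap)
  starts <- above[c(1, breaks + 1)]
  ends <- above[c(breaks, length(above))]
  keep <- (ends - starts + 1L) >= 3L
  starts <- starts[keep]
  ends <- ends[keep]
  if (length(starts) == 0) {
    nl_stop("no_pulse", "no rising edge exceeds the noise threshold")
  }
  if (length(starts) > 1) {
    nl_stop("ambiguous_pulse", "%d pulses detected; expected one", length(starts))
  }

  k_r <- starts[1] # first pulse sample
  k_f <- ends[1] # last pulse sample
  if (k_f <= k_r) nl_stop("no_pulse", "pulse region too short")

  t0 <- time[k_r]
  v0 <- switch(v0_method,
    edge = v[k_r],
    median3 = stats::median(v[k_r:min(k_r + 2L, k_f)])
  )

  pulse_idx <- k_r:k_f
  n_tail <- max(3L, ceiling(0.1 * length(pulse_idx)))
  vx <- mean(v[pulse_idx[(length(pulse_idx) - n_tail + 1L):length(pulse_idx)]])

  # Plateau start: first pulse sample whose local slope has decayed below
  # slope_frac of the initial charging slope. An ideal square step (zero
  # charging slope) plateaus immediately.
  s0 <- if (k_r < k_f) v[k_r + 1L] - v[k_r] else 0
  if (abs(s0) <= thr * .Machine$double.eps^0.5 || abs(s0) < 1e-12 * rng) {
    k_x <- k_f
  } else {
    dp <- abs(diff(v[pulse_idx]))
    below <- which(dp < slope_frac * abs(s0))
    k_x <- if (length(below) > 0) pulse_idx[below[1]] else k_f
    if (k_x <= k_r) k_x <- k_f
  }

  pulse_response(
    time = time, voltage = v, current = current,
    t0 = t0, tx = time[k_x], v0 = v0, vx = vx, pulse_end = time[k_f]
  )
}

#' Tissue equivalent-circuit estimate
#'
#' @param rs,rp Series and parallel resistance in ohms (>= 0).
#' @param cp Parallel capacitance in farads, or `NA` when undefined (purely
#'   resistive limit, `rp = 0`).
#' @param tau Charging time constant in seconds (`rp * cp`).
#' @param r_squared Coefficient of determination of the tau fit.
#'
#' @return An object of class `tissue_rc`.
#' @export
tissue_rc <- function(rs, rp, cp, tau = rp * cp, r_squared = NA_real_) {
  if (rs < 0 || rp < 0 || (!is.na(cp) && cp < 0)) {
    nl_stop("malformed_input", "rs, rp, cp must be non-negative")
  }
  if (!is.na(cp) && rp > 0 && abs(tau - rp * cp) > 1e-9 * max(tau, rp * cp)) {
    nl_stop("malformed_input", "tau must equal rp * cp")
  }
  structure(
    list(rs = rs, rp = rp, cp = cp, tau = tau, r_squared = r_squared),
    class = "tissue_rc"
  )
}

#' @export
print.tissue_rc <- function(x, ...) {
  cat(sprintf(
    "<tissue_rc> Rs = %.4g ohm, Rp = %.4g ohm, Cp = %s, tau = %.4g s, R^2 = %.4g\n",
    x$rs, x$rp,
    if (is.na(x$cp)) "undefined" else sprintf("%.4g F", x$cp),
    x$tau, x$r_squared
  ))
  invisible(x)
}

# Sum of squared residuals of the one-parameter charging model
# F(tau, t) = v0 + (vx - v0) * (1 - exp(-(t - t0)/tau))
# over the fit window. Used by both the optimizer and the grid oracle.
charging_sse <- function(tau, t_rel, v, v0, vx) {
  f <- v0 + (vx - v0) * (1 - exp(-t_rel / tau))
  sum((v - f)^2)
}

#' Estimate the RC equivalent circuit from a detected pulse response
#'
#' Applies the landmark estimators `Rs = V0 / i` and `Rp = Vx / i - Rs`,
#' then recovers the time constant by least-squares fitting of the charging
#' curve `V0 + (Vx - V0)(1 - exp(-(t - t0)/tau))` over `[t0, tx]` and sets
#' `Cp = tau / Rp`. The fit is one-dimensional (V0 and Vx are fixed at their
#' landmark values) and solved by a coarse logarithmic grid refined with
#' golden-section search, which is deterministic and exact on noiseless data.
#'
#' When the plateau voltage does not exceed the edge voltage the circuit is
#' purely resistive: `rp = 0` and `cp` is undefined (`NA`).
#'
#' @param pulse A [pulse_response()].
#' @param degenerate_tol Relative tolerance on `vx - v0` below which the
#'   charging is considered degenerate.
#'
#' @return A [tissue_rc()].
#' @export
fit_rc_from_pulse <- function(pulse, degenerate_tol = 1e-4) {
  stopifnot(inherits(pulse, "pulse_response"))
  i <- pulse$current
  rs <- pulse$v0 / i
  swing <- pulse$vx - pulse$v0
  if (swing <= degenerate_tol * max(abs(pulse$vx), abs(pulse$v0), 1e-12)) {
    return(tissue_rc(rs = rs, rp = 0, cp = NA_real_, tau = 0, r_squared = NA_real_))
  }
  rp <- pulse$vx / i - rs

  # Fit window: the charging segment [t0, tx]; fall back to the whole pulse
  # when the detected plateau leaves too few samples to fit.
  idx <- which(pulse$time >= pulse$t0 & pulse$time <= pulse$tx)
  if (length(idx) < 8) {
    idx <- which(pulse$time >= pulse$t0 & pulse$time <= pulse$pulse_end)
  }
  t_rel <- pulse$time[idx] - pulse$t0
  v <- pulse$voltage[idx]

  dt <- 1 / pulse$sample_rate
  dur <- pulse$pulse_end - pulse$t0
  lo <- dt
  hi <- max(dur, 2 * dt)

  # coarse log grid, then golden-section refinement in the bracketing cell
  grid <- exp(seq(log(lo), log(hi), length.out = 200))
  sse <- vapply(grid, charging_sse, numeric(1), t_rel = t_rel, v = v,
                v0 = pulse$v0, vx = pulse$vx)
  k <- which.min(sse)
  lo_k <- grid[max(1L, k - 1L)]
  hi_k <- grid[min(length(grid), k + 1L)]
  opt <- stats::optimize(charging_sse, c(lo_k, hi_k), t_rel = t_rel, v = v,
                         v0 = pulse$v0, vx = pulse$vx,
                         tol = .Machine$double.eps^0.5 * lo_k)
  tau <- opt$minimum
  if (!is.finite(tau) || !is.finite(opt$objective)) {
    nl_stop("fit_not_converged", "tau fit did not produce a finite optimum")
  }

  ss_tot <- sum((v - mean(v))^2)
  r2 <- if (ss_tot > 0) 1 - opt$objective / ss_tot else NA_real_

  if (dur < 5 * tau) {
    nl_warn("short_pulse", "pulse duration (%.3g s) < 5 x estimated tau (%.3g s); Vx and Rp may be biased", dur, tau)
  }

  tissue_rc(rs = rs, rp = rp, cp = tau / rp, tau = tau, r_squared = r2)
}

#' Impedance magnitude of the tissue equivalent circuit
#'
#' Computes `|Z(f)| = |Rs + Rp / (1 + j 2 pi f Rp Cp)|`, the magnitude of the
#' series resistance in line with the parallel RC pair. At `f = 0` this is
#' `Rs + Rp` (capacitor open); as `f` grows it decreases monotonically
#' towards `Rs`.
#'
#' @param rc A [tissue_rc()].
#' @param frequency Frequency in Hz (>= 0). Default 500 kHz, the frequency at
#'   which mock-material impedances are conventionally reported here.
#'
#' @return Impedance magnitude in ohms.
#' @export
impedance_magnitude <- function(rc, frequency = 5e5) {
  stopifnot(inherits(rc, "tissue_rc"))
  if (length(frequency) != 1 || frequency < 0) {
    nl_stop("malformed_input", "frequency must be a single non-negative number")
  }
  if (frequency == 0) return(rc$rs + rc$rp)
  if (is.na(rc$cp)) {
    nl_stop("undefined_capacitance", "cp is undefined; impedance at f > 0 unavailable")
  }
  Mod(rc$rs + rc$rp / (1 + 1i * 2 * pi * frequency * rc$rp * rc$cp))
}
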