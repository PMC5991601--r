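# CMAP feature extraction from trigger-aligned EMG.
#
# A trial stimulates at four intensities — the motor threshold (MT) and 110%,
# 120%, 130% of it — with several pulses per level. Per level the stimulus-
# aligned sweeps are grand-averaged, the compound muscle action potential
# (CMAP) is measured as the peak-to-peak voltage of the average, amplitudes
# are normalized to the MT and 130% levels (0 and 100%), and a straight line
# through (intensity, normalized amplitude) summarizes the nerve-muscle
# transfer as a slope theta1 and intercept theta2.

#' Four-level stimulus series anchored at the motor threshold
#'
#' @param i_mt Motor threshold current in amperes.
#' @param pulses_per_level Pulses applied at each level (default 4).
#' @param isi Interstimulus interval in seconds (default 0.5).
#'
#' @return An object of class `stimulus_series` with `levels` equal to
#'   100%, 110%, 120% and 130% of `i_mt`.
#' @export
stimulus_series <- function(i_mt, pulses_per_level = 4L, isi = 0.5) {
  if (i_mt <= 0) nl_stop("malformed_input", "i_mt must be positive")
  structure(
    list(
      i_mt = i_mt,
      levels = i_mt * c(1, 1.1, 1.2, 1.3),
      pulses_per_level = as.integer(pulses_per_level),
      isi = isi
    ),
    class = "stimulus_series"
  )
}

#' Trigger-aligned EMG recording
#'
#' @param signal Sampled EMG in volts.
#' @param sample_rate Sampling rate in Hz.
#' @param trigger_times Stimulus trigger instants in seconds, strictly
#'   increasing, all within the recording.
#'
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(signal, sample_rate, trigger_times) {
  signal <- as.numeric(signal)
  trigger_times <- as.numeric(trigger_times)
  if (any(diff(trigger_times) <= 0)) {
    nl_stop("malformed_input", "trigger_times must be strictly increasing")
  }
  dur <- length(signal) / sample_rate
  if (any(trigger_times < 0) || any(trigger_times >= dur)) {
    nl_stop("malformed_input", "all triggers must lie within the recording")
  }
  structure(
    list(signal = signal, sample_rate = sample_rate, trigger_times = trigger_times),
    class = "emg_recording"
  )
}

#' Segment an EMG recording around its stimulus triggers
#'
#' Cuts one fixed-length window per trigger, aligned so that the first sample
#' of each segment is the trigger instant.
#'
#' @param rec An [emg_recording()].
#' @param window Window length in seconds (> 0).
#'
#' @return A numeric matrix with one row per trigger and
#'   `floor(window * sample_rate)` columns.
#' @export
segment_by_trigger <- function(rec, window) {
  stopifnot(inherits(rec, "emg_recording"))
  if (window <= 0) nl_stop("malformed_input", "window must be positive")
  n_win <- floor(window * rec$sample_rate)
  starts <- round(rec$trigger_times * rec$sample_rate) + 1L
  ends <- starts + n_win - 1L
  if (any(ends > length(rec$signal))) {
    bad <- which(ends > length(rec$signal))[1]
    nl_stop("incomplete_window",
            "window for trigger %d (t = %.4g s) runs past the recording end",
            bad, rec$trigger_times[bad])
  }
  seg <- matrix(0, nrow = length(starts), ncol = n_win)
  for (j in seq_along(starts)) {
    seg[j, ] <- rec$signal[starts[j]:ends[j]]
  }
  seg
}

#' Grand average of stimulus-aligned segments
#'
#' Pointwise arithmetic mean over repeated equal-length sweeps; uncorrelated
#' noise is attenuated by `1/sqrt(n)`.
#'
#' @param segments A matrix (rows = sweeps) or a list of equal-length
#'   numeric vectors.
#'
#' @return A numeric vector, the averaged segment.
#' @export
grand_average <- function(segments) {
  if (is.list(segments)) {
    lens <- lengths(segments)
    if (length(unique(lens)) != 1) {
      nl_stop("shape_mismatch", "segments have unequal lengths (%s)",
              paste(unique(lens), collapse = ", "))
    }
    segments <- do.call(rbind, segments)
  }
  if (!is.matrix(segments) || nrow(segments) < 1) {
    nl_stop("malformed_input", "need at least one segment")
  }
  colMeans(segments)
}

#' CMAP amplitude and latency of an averaged response
#'
#' The amplitude is the peak-to-peak voltage (max minus min) within the
#' post-trigger search window; the latency is the time from the trigger to
#' the largest-magnitude peak. The default window 2-50 ms excludes the
#' stimulus artifact immediately after the trigger.
#'
#' @param avg Averaged segment (sample 1 = trigger instant).
#' @param sample_rate Sampling rate in Hz.
#' @param search_window Two times in seconds (post-trigger) bounding the
#'   search.
#' @param noise_sd Baseline noise SD in volts used for response detection;
#'   `NULL` estimates it from the pre-window (blanked) part of the segment.
#' @param detection_mult Detection threshold as a multiple of `noise_sd`.
#' @param require_response Error with class `nerveloc_no_response` when the
#'   peak-to-peak voltage is below the detection threshold (default); set
#'   `FALSE` to return the measurement with `detected = FALSE`.
#'
#' @return A list with `vpp` (volts), `latency` (seconds, `NA` when not
#'   detected) and `detected`.
#' @export
extract_amplitude_latency <- function(avg, sample_rate,
                                      search_window = c(0.002, 0.050),
                                      noise_sd = NULL, detection_mult = 5,
                                      require_response = TRUE) {
  t <- (seq_along(avg) - 1L) / sample_rate
  idx <- which(t >= search_window[1] & t <= search_window[2])
  if (length(idx) < 2) nl_stop("malformed_input", "search window contains < 2 samples")
  if (is.null(noise_sd)) {
    pre <- which(t < search_window[1])
    noise_sd <- if (length(pre) >= 4) stats::sd(avg[pre]) else 0
  }
  thr <- max(detection_mult * noise_sd, 1e-6)
  vpp <- max(avg[idx]) - min(avg[idx])
  detected <- vpp > thr
  if (!detected && require_response) {
    nl_stop("no_response", "peak-to-peak %.3g V below detection threshold %.3g V", vpp, thr)
  }
  latency <- if (detected) t[idx[which.max(abs(avg[idx]))]] else NA_real_
  list(vpp = vpp, latency = latency, detected = detected)
}

#' Normalize four CMAP amplitudes to the threshold and 130% levels
#'
#' `NCMAP_i = (CMAP_i - CMAP_1) / (CMAP_4 - CMAP_1) * 100`, so the MT-level
#' response maps to 0% and the 130%-MT response to 100% by construction.
#'
#' @param vpp Numeric vector of four peak-to-peak amplitudes in volts,
#'   ordered by stimulus level.
#'
#' @return Four percentages.
#' @export
normalize_cmaps <- function(vpp) {
  if (length(vpp) != 4) nl_stop("malformed_input", "expected four amplitudes")
  denom <- vpp[4] - vpp[1]
  if (denom == 0) {
    nl_stop("degenerate_range", "CMAP4 equals CMAP1; normalization undefined")
  }
  (vpp - vpp[1]) / denom * 100
}

#' Linear nerve-muscle model across stimulus levels
#'
#' Ordinary least squares of the normalized amplitudes on the stimulus
#' currents with an intercept, `theta = (X'X)^{-1} X'y`: `theta1` is the
#' slope (percent per ampere), `theta2` the intercept (percent).
#'
#' @param levels Four stimulus currents in amperes (not all equal).
#' @param ncmap Four normalized amplitudes in percent.
#'
#' @return A list with `theta1`, `theta2` and `r_squared`.
#' @export
fit_linear_nerve_model <- function(levels, ncmap) {
  if (length(levels) != length(ncmap) || length(levels) < 2) {
    nl_stop("malformed_input", "levels and ncmap must be equal length >= 2")
  }
  if (length(unique(levels)) == 1) {
    nl_stop("singular_design", "all stimulus levels equal; slope undefined")
  }
  X <- cbind(levels, 1)
  theta <- solve(crossprod(X), crossprod(X, ncmap))
  fitted <- X %*% theta
  ss_res <- sum((ncmap - fitted)^2)
  ss_tot <- sum((ncmap - mean(ncmap))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  list(theta1 = theta[1], theta2 = theta[2], r_squared = r2)
}

#' Search the motor threshold on a current grid
#'
#' Increases the stimulus current from `start` in steps of `step` until the
#' trial oracle reports a detected CMAP; that first responsive current is the
#' motor threshold i_MT. A response at the very first tested current is
#' flagged (the true threshold may lie below the grid).
#'
#' @param stimulate A function of one argument (current in amperes) returning
#'   `TRUE` when a CMAP is detected at that intensity.
#' @param start First tested current in amperes.
#' @param step Grid step in amperes (> 0).
#' @param max_current Safety limit in amperes; exceeding it without a
#'   response raises `nerveloc_threshold_not_found`.
#'
#' @return The motor threshold in amperes, with attribute `at_lower_bound`
#'   set to `TRUE` when the response was already present at `start`.
#' @export
find_motor_threshold <- function(stimulate, start, step, max_current) {
  if (!(start < max_current)) nl_stop("malformed_input", "start must be < max_current")
  if (step <= 0) nl_stop("malformed_input", "step must be positive")
  current <- start
  while (current <= max_current + 1e-15 * max_current) {
    if (isTRUE(stimulate(current))) {
      at_lb <- current == start
      if (at_lb) {
        nl_warn("threshold_at_start",
                "response at the first tested current (%.3g A); true threshold may be lower", current)
      }
      return(structure(current, at_lower_bound = at_lb))
    }
    current <- current + step
  }
  nl_stop("threshold_not_found",
          "no CMAP detected up to the %.3g A safety limit", max_current)
}

#' Extract the full CMAP feature set of one trial
#'
#' Runs the per-trial pipeline: segment the EMG at its triggers, grand-average
#' the sweeps of each of the four stimulus levels (triggers are assumed
#' ordered level-by-level), measure peak-to-peak amplitude and latency per
#' averaged response, normalize the amplitudes, and fit the linear
#' nerve-muscle model. The trial latency `t_l` is the mean latency over the
#' four grand-averaged responses.
#'
#' @param rec An [emg_recording()] whose triggers are the pulses of `series`
#'   in order (all pulses of level 1, then level 2, ...).
#' @param series A [stimulus_series()].
#' @param window Segment window in seconds.
#' @param ... Passed to [extract_amplitude_latency()].
#'
#' @return A list of class `cmap_feature_set` with `vpp` (4 amplitudes,
#'   volts), `ncmap` (4 percentages), `theta1`, `theta2`, `lin_r_squared`,
#'   `t_l` (seconds) and `levels` (amperes).
#' @export
extract_trial_features <- function(rec, series, window = 0.05, ...) {
  stopifnot(inherits(rec, "emg_recording"), inherits(series, "stimulus_series"))
  ppl <- series$pulses_per_level
  if (length(rec$trigger_times) != 4 * ppl) {
    nl_stop("malformed_input", "expected %d triggers (4 levels x %d pulses), got %d",
            4 * ppl, ppl, length(rec$trigger_times))
  }
  seg <- segment_by_trigger(rec, window)
  vpp <- numeric(4)
  lat <- numeric(4)
  for (lvl in 1:4) {
    rows <- ((lvl - 1) * ppl + 1):(lvl * ppl)
    avg <- grand_average(seg[rows, , drop = FALSE])
    m <- extract_amplitude_latency(avg, rec$sample_rate, ...)
    vpp[lvl] <- m$vpp
    lat[lvl] <- m$latency
  }
  ncmap <- normalize_cmaps(vpp)
  lin <- fit_linear_nerve_model(series$levels, ncmap)
  structure(
    list(
      vpp = vpp, ncmap = ncmap,
      theta1 = lin$theta1, theta2 = lin$theta2, lin_r_squared = lin$r_squared,
      t_l = mean(lat), levels = series$levels
    ),
    class = "cmap_feature_set"
  )
}
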