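# Seeded phantom simulator of the bench protocol.
#
# Emulates the full experiment with no external data: per subject and mock
# material, the stimulating probe is retracted from contact (d = 0) to 4 mm
# in 1 mm steps; at each distance the motor threshold is searched on a
# current grid, four pulses are applied at each of MT, 110%, 120% and 130%
# MT (~500 ms apart), the constant-current pulse waveform and the 2 kHz EMG
# are synthesized, and the records are produced by running the REAL
# extraction pipeline (edge detection + RC fit, segmentation, grand
# averaging, normalization, linear nerve-muscle fit) on the synthetic
# traces.
#
# Generative laws: CMAP amplitude at the MT level follows
# amp = lambda1 * iMT / (d_eff * Z) + eta1 with effective distance
# d_eff = d + d_offset (a finite electrode standoff keeps the law usable at
# contact); latency follows tL = lambda2 * (Z * d_eff) + eta2; the motor
# threshold grows with distance and falls with impedance,
# iMT = a0 (1 + a1 d_eff)(1 + a2 / Z). The law coefficients are synthetic
# defaults chosen to span a realistic bench range (~10-300 uA thresholds,
# ~0.5-3 mV CMAPs, 7-13 ms latencies); they are configuration, not
# calibrated claims about real tissue.

#' Default mock-material equivalent circuits
#'
#' Four gelatin-like materials ordered from highest to lowest impedance
#' (rising NaCl content): series and parallel resistance fall and parallel
#' capacitance rises across the sequence.
#'
#' @return A data frame with columns `name`, `rs_ohm`, `rp_ohm`, `cp_f`.
#' @export
default_materials <- function() {
  data.frame(
    name = c("mat1", "mat2", "mat3", "mat4"),
    rs_ohm = c(1087.36, 858.11, 577.51, 330.75),
    rp_ohm = c(19520, 7360, 6720, 6480),
    cp_f = c(0.82, 5.67, 7.83, 10.39) * 1e-9,
    stringsAsFactors = FALSE
  )
}

#' Phantom configuration
#'
#' All tunable parameters of the simulator. Defaults reproduce the study
#' conditions: 12 subjects x 4 mock materials x 5 distances (0-4 mm), four
#' pulses per stimulus level at 0.5 s interstimulus interval, EMG sampled at
#' 2 kHz, pulse waveforms at 1 MHz.
#'
#' @param n_subjects Number of simulated subjects.
#' @param materials Data frame like [default_materials()].
#' @param distances_mm Probe-to-nerve distances in millimetres.
#' @param d_offset_mm Electrode standoff added to the geometric distance in
#'   the generative laws (keeps the amplitude law finite at contact).
#' @param lambda1 Amplitude gain, volts x mm x ohm / ampere.
#' @param eta1 Amplitude offset in volts.
#' @param recruit_gain Fractional amplitude growth per fractional increase
#'   in current above threshold (sets the recruitment slope across levels).
#' @param lambda2 Latency slope, seconds / (ohm x mm).
#' @param eta2 Baseline latency in seconds (7.25 ms at contact).
#' @param mt_a0,mt_a1,mt_a2 Motor-threshold law coefficients: base current
#'   (A), growth per mm, impedance offset (ohm).
#' @param mt_start,mt_step,mt_max Motor-threshold search grid in amperes.
#' @param pulses_per_level,isi Stimuli per level and interstimulus interval
#'   (s).
#' @param emg_sample_rate,waveform_sample_rate Sampling rates in Hz.
#' @param pulse_duration,pulse_pre,pulse_post Stimulus pulse length and
#'   zero-baseline padding in seconds.
#' @param impedance_freq Frequency (Hz) at which the impedance feature is
#'   evaluated.
#' @param template_w1,template_w2,template_pos_frac Biphasic CMAP template:
#'   widths (s) of the positive and negative lobes and the positive share of
#'   the peak-to-peak amplitude.
#' @param waveform_noise_sd,emg_noise_sd Additive Gaussian noise SDs (V).
#' @param amp_noise_rel,mt_noise_rel Log-normal relative jitter of per-pulse
#'   amplitude and of the true threshold.
#' @param latency_noise_sd Per-pulse latency jitter SD (s).
#' @param subject_rc_jitter Log-normal SD of the per-subject multiplicative
#'   jitter on the material RC values.
#' @param noise_scale Common multiplier applied to the five noise SDs
#'   (convenience for noise sweeps; `0` gives a fully noiseless phantom).
#' @param window CMAP segmentation window in seconds.
#' @param seed Integer seed; regeneration with the same config is identical.
#' @param keep_raw Keep the synthetic waveform and EMG traces per trial.
#'
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(n_subjects = 12L,
                           materials = default_materials(),
                           distances_mm = 0:4,
                           d_offset_mm = 0.5,
                           lambda1 = 2e4, eta1 = 0, recruit_gain = 1.5,
                           lambda2 = 1e-6, eta2 = 7.25e-3,
                           mt_a0 = 20e-6, mt_a1 = 0.8, mt_a2 = 200,
                           mt_start = 10e-6, mt_step = 5e-6, mt_max = 500e-6,
                           pulses_per_level = 4L, isi = 0.5,
                           emg_sample_rate = 2000, waveform_sample_rate = 1e6,
                           pulse_duration = 1e-3, pulse_pre = 2e-4,
                           pulse_post = 2e-4,
                           impedance_freq = 5e5,
                           template_w1 = 3e-3, template_w2 = 3e-3,
                           template_pos_frac = 0.6,
                           waveform_noise_sd = 5e-3, emg_noise_sd = 2e-5,
                           amp_noise_rel = 0.05, latency_noise_sd = 1e-4,
                           mt_noise_rel = 0.05,
                           subject_rc_jitter = 0.1,
                           noise_scale = 1,
                           window = 0.05, seed = 1L, keep_raw = FALSE) {
  cfg <- as.list(environment())
  sds <- c("waveform_noise_sd", "emg_noise_sd", "amp_noise_rel",
           "latency_noise_sd", "mt_noise_rel", "subject_rc_jitter",
           "noise_scale")
  if (any(unlist(cfg[sds]) < 0)) nl_stop("malformed_input", "noise SDs must be >= 0")
  if (any(distances_mm < 0)) nl_stop("malformed_input", "distances must be >= 0")
  if (!all(c("name", "rs_ohm", "rp_ohm", "cp_f") %in% names(materials)) ||
      any(materials$rs_ohm <= 0 | materials$rp_ohm <= 0 | materials$cp_f <= 0)) {
    nl_stop("malformed_input", "materials need positive rs_ohm, rp_ohm, cp_f")
  }
  if (isi <= window) nl_stop("malformed_input", "isi must exceed the CMAP window")
  structure(cfg, class = "phantom_config")
}

#' Simulate the driven-voltage waveform of a constant-current pulse
#'
#' Samples the closed-form response of the series-Rs / parallel-RpCp circuit,
#' `V(t) = i Rs + i Rp (1 - exp(-t / (Rp Cp)))` during the pulse with zero
#' baseline before and after, plus optional additive Gaussian noise. The
#' pulse onset falls exactly on a sample so the first pulse sample equals
#' `i * Rs`.
#'
#' @param rc A [tissue_rc()] (or list with `rs`, `rp`, `cp`).
#' @param current Pulse amplitude in amperes (>= 0; `0` yields an all-zero
#'   trace).
#' @param duration Pulse length in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param noise_sd Additive noise SD in volts.
#' @param pre,post Zero-baseline padding in seconds.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#'
#' @return A data frame with columns `time_s`, `voltage_V` and attribute
#'   `current_a`.
#' @export
simulate_pulse_response <- function(rc, current, duration, sample_rate,
                                    noise_sd = 0, pre = 0.2 * duration,
                                    post = 0.2 * duration, seed = NULL) {
  if (rc$rs < 0 || rc$rp < 0 || (!is.na(rc$cp) && rc$cp < 0)) {
    nl_stop("malformed_input", "RC values must be non-negative")
  }
  if (current < 0) nl_stop("malformed_input", "current must be >= 0")
  n_pre <- round(pre * sample_rate)
  n_pulse <- round(duration * sample_rate)
  n_post <- round(post * sample_rate)
  n <- n_pre + n_pulse + n_post
  t <- (seq_len(n) - 1L) / sample_rate
  v <- numeric(n)
  if (current > 0 && n_pulse > 0) {
    tp <- (seq_len(n_pulse) - 1L) / sample_rate # time since pulse onset
    tau <- if (is.na(rc$cp) || rc$rp == 0) 0 else rc$rp * rc$cp
    charge <- if (tau > 0) 1 - exp(-tp / tau) else rep(1, n_pulse)
    v[n_pre + seq_len(n_pulse)] <- current * rc$rs + current * rc$rp * charge
  }
  wave <- with_seed(seed, {
    if (noise_sd > 0) v + stats::rnorm(n, sd = noise_sd) else v
  })
  structure(
    data.frame(time_s = t, voltage_V = wave),
    current_a = current
  )
}

# Add a biphasic CMAP lobe pair to `signal` in place: a positive raised-sine
# lobe of width w1 peaking exactly on the sample grid at t_peak, followed by
# a negative lobe of width w2. Peak snapping keeps the sampled extrema equal
# to the designed amplitudes.
add_biphasic <- function(signal, fs, t_peak, vpp, w1, w2, pos_frac) {
  t_peak <- round(t_peak * fs) / fs
  a <- pos_frac * vpp
  b <- (1 - pos_frac) * vpp
  n <- length(signal)
  k0 <- floor((t_peak - w1 / 2) * fs) + 1L
  k1 <- ceiling((t_peak + w1 / 2 + w2) * fs) + 1L
  ks <- max(1L, k0):min(n, k1)
  t <- (ks - 1L) / fs
  d <- t - t_peak
  pos <- abs(d) <= w1 / 2
  neg <- d > w1 / 2 & d <= w1 / 2 + w2
  add <- numeric(length(ks))
  add[pos] <- a * cos(pi * d[pos] / w1)^2
  add[neg] <- -b * sin(pi * (d[neg] - w1 / 2) / w2)^2
  signal[ks] <- signal[ks] + add
  signal
}

#' Simulate one stimulation trial and extract its features
#'
#' Runs the per-trial protocol at one (subject circuit, distance): searches
#' the motor threshold on the configured current grid, synthesizes the
#' constant-current pulse waveform and the trigger-aligned EMG with four
#' pulses at each of the four stimulus levels, then extracts the feature
#' record by running the real estimation pipeline on the synthetic traces.
#'
#' @param rc A [tissue_rc()] describing the subject/material circuit.
#' @param distance_mm Geometric probe-to-nerve distance in millimetres.
#' @param config A [phantom_config()].
#'
#' @return A list with `record` (one-row data frame of features and the
#'   ground-truth distance), `truth` (generative quantities: true threshold,
#'   per-level amplitudes, latency, impedance), and when `config$keep_raw`
#'   is set, `waveform` and `emg`. Uses the current RNG stream; seed at the
#'   dataset level. When no CMAP can be elicited within the safety limit the
#'   record is returned flagged (`response = FALSE`) with missing features.
#' @export
simulate_trial <- function(rc, distance_mm, config) {
  cfg <- config
  ns <- cfg$noise_scale
  d_eff <- distance_mm + cfg$d_offset_mm
  z_true <- impedance_magnitude(rc, cfg$impedance_freq)

  mt_true <- cfg$mt_a0 * (1 + cfg$mt_a1 * d_eff) * (1 + cfg$mt_a2 / z_true) *
    exp(stats::rnorm(1) * cfg$mt_noise_rel * ns)

  detect_floor <- max(5 * cfg$emg_noise_sd * ns, 1e-6)
  amp_at <- function(i) {
    if (i < mt_true) return(0)
    cfg$lambda1 * i / (d_eff * z_true) + cfg$eta1
  }
  i_mt <- tryCatch(
    withCallingHandlers(
      find_motor_threshold(function(i) amp_at(i) > detect_floor,
                           cfg$mt_start, cfg$mt_step, cfg$mt_max),
      nerveloc_warning = function(w) invokeRestart("muffleWarning")
    ),
    nerveloc_threshold_not_found = function(e) NULL
  )

  na_record <- function() {
    data.frame(
      subject = NA_integer_, material = NA_character_,
      distance_mm = distance_mm, i_mt_a = NA_real_, cmap_amp_v = NA_real_,
      z_ohm = NA_real_, t_l_s = NA_real_, theta1 = NA_real_,
      theta2 = NA_real_, lin_r_squared = NA_real_, rs_ohm = NA_real_,
      rp_ohm = NA_real_, cp_f = NA_real_, tau_s = NA_real_,
      tau_r_squared = NA_real_, response = FALSE, at_lower_bound = NA,
      stringsAsFactors = FALSE
    )
  }
  if (is.null(i_mt)) {
    return(list(record = na_record(),
                truth = list(mt_true = mt_true, z_true = z_true)))
  }

  # stimulus waveform at the found threshold current
  wave <- simulate_pulse_response(
    rc, current = as.numeric(i_mt), duration = cfg$pulse_duration,
    sample_rate = cfg$waveform_sample_rate,
    noise_sd = cfg$waveform_noise_sd * ns,
    pre = cfg$pulse_pre, post = cfg$pulse_post
  )

  series <- stimulus_series(as.numeric(i_mt), cfg$pulses_per_level, cfg$isi)
  n_pulses <- 4L * cfg$pulses_per_level
  trig <- 0.1 + (seq_len(n_pulses) - 1L) * cfg$isi
  fs <- cfg$emg_sample_rate
  n_emg <- ceiling((max(trig) + cfg$window + 0.25) * fs)
  emg <- stats::rnorm(n_emg) * cfg$emg_noise_sd * ns

  amp_mt <- amp_at(as.numeric(i_mt))
  ratio <- rep(c(1, 1.1, 1.2, 1.3), each = cfg$pulses_per_level)
  amp_levels <- amp_mt * (1 + cfg$recruit_gain * (ratio - 1))
  t_l_true <- cfg$lambda2 * z_true * d_eff + cfg$eta2

  amp_jit <- exp(stats::rnorm(n_pulses) * cfg$amp_noise_rel * ns)
  lat_jit <- stats::rnorm(n_pulses) * cfg$latency_noise_sd * ns
  for (j in seq_len(n_pulses)) {
    lat_j <- min(max(t_l_true + lat_jit[j], 0.004), 0.045)
    emg <- add_biphasic(emg, fs, trig[j] + lat_j, amp_levels[j] * amp_jit[j],
                        cfg$template_w1, cfg$template_w2, cfg$template_pos_frac)
  }
  rec <- emg_recording(emg, fs, trig)

  # --- real extraction pipeline on the synthetic traces ---
  pulse <- detect_pulse_edges(wave, current = as.numeric(i_mt))
  rc_est <- fit_rc_from_pulse(pulse)
  z_est <- impedance_magnitude(rc_est, cfg$impedance_freq)
  feats <- extract_trial_features(rec, series, window = cfg$window,
                                  noise_sd = cfg$emg_noise_sd * ns)

  record <- data.frame(
    subject = NA_integer_, material = NA_character_,
    distance_mm = distance_mm,
    i_mt_a = as.numeric(i_mt),
    cmap_amp_v = feats$vpp[1],
    z_ohm = z_est, t_l_s = feats$t_l,
    theta1 = feats$theta1, theta2 = feats$theta2,
    lin_r_squared = feats$lin_r_squared,
    rs_ohm = rc_est$rs, rp_ohm = rc_est$rp, cp_f = rc_est$cp,
    tau_s = rc_est$tau, tau_r_squared = rc_est$r_squared,
    response = TRUE,
    at_lower_bound = isTRUE(attr(i_mt, "at_lower_bound")),
    stringsAsFactors = FALSE
  )
  out <- list(
    record = record,
    truth = list(
      mt_true = mt_true, i_mt = as.numeric(i_mt), z_true = z_true,
      amp_levels = amp_mt * (1 + cfg$recruit_gain * (c(1, 1.1, 1.2, 1.3) - 1)),
      t_l_true = t_l_true, rc = rc, d_eff_mm = d_eff
    )
  )
  if (cfg$keep_raw) {
    out$waveform <- wave
    out$emg <- rec
  }
  out
}

#' Generate a full phantom dataset
#'
#' Full factorial subjects x materials x distances. Each subject-material
#' pair draws a multiplicative jitter of the material's RC values (subject
#' variation); every trial's features come from the real extraction pipeline
#' run on the synthetic traces. Bit-reproducible from `config$seed`.
#'
#' @param config A [phantom_config()].
#'
#' @return An object of class `phantom_dataset`: a list with `records` (one
#'   row per trial, `response = FALSE` rows flagged rather than dropped),
#'   `truth` (per-trial generative values) and `config`.
#' @export
generate_dataset <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  mats <- config$materials
  with_seed(config$seed, {
    records <- vector("list", config$n_subjects * nrow(mats) * length(config$distances_mm))
    truths <- vector("list", length(records))
    i <- 0L
    for (s in seq_len(config$n_subjects)) {
      for (m in seq_len(nrow(mats))) {
        jit <- exp(stats::rnorm(3) * config$subject_rc_jitter)
        rc <- tissue_rc(
          rs = mats$rs_ohm[m] * jit[1],
          rp = mats$rp_ohm[m] * jit[2],
          cp = mats$cp_f[m] * jit[3]
        )
        for (d in config$distances_mm) {
          i <- i + 1L
          tr <- simulate_trial(rc, d, config)
          tr$record$subject <- s
          tr$record$material <- mats$name[m]
          records[[i]] <- tr$record
          truths[[i]] <- tr$truth
        }
      }
    }
    structure(
      list(records = do.call(rbind, records), truth = truths, config = config),
      class = "phantom_dataset"
    )
  })
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf(
    "<phantom_dataset> %d records (%d subjects x %d materials x %d distances), seed %d, %d without response\n",
    nrow(x$records), x$config$n_subjects, nrow(x$config$materials),
    length(x$config$distances_mm), x$config$seed, sum(!x$records$response)
  ))
  invisible(x)
}
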