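# Shared fixtures, built in code. Heavyweight phantom datasets are generated
# once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# Evaluate expr under a temporary seed without disturbing the session RNG.
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Noiseless study-scale phantom: the five stochastic noise sources are off,
# subject-to-subject RC variation stays on (it provides the informative
# spread in Rs, Rp). Short ISI keeps the synthetic EMG traces small.
noiseless_config <- function(seed = 42, ...) {
  phantom_config(noise_scale = 0, isi = 0.06, seed = seed, ...)
}

phantom_240_noiseless <- function() {
  cached("p240", generate_dataset(noiseless_config()))
}

# Reduced noisy phantom for noise-sweep checks.
small_config <- function(seed, noise_scale = 1) {
  phantom_config(n_subjects = 3, isi = 0.06, seed = seed,
                 noise_scale = noise_scale)
}

# Closed-form charging curve used to build synthetic waveforms in tests
# independently of simulate_pulse_response().
rc_curve_df <- function(rs, rp, cp, current, fs, pre, dur, post) {
  n_pre <- round(pre * fs); n_p <- round(dur * fs); n_post <- round(post * fs)
  t <- (seq_len(n_pre + n_p + n_post) - 1) / fs
  v <- numeric(length(t))
  tp <- (seq_len(n_p) - 1) / fs
  v[n_pre + seq_len(n_p)] <- current * rs + current * rp * (1 - exp(-tp / (rp * cp)))
  data.frame(time_s = t, voltage_V = v)
}

# A labeled base-variant record set: phantom features relabeled by a known
# raw-space base model, so exact recovery is well defined.
base_relabeled_240 <- function() {
  cached("base240", {
    ds <- phantom_240_noiseless()
    rec <- ds$records
    truth <- list(lambda1 = 1.5e4, lambda2 = 120, eta = 0.35)
    m <- prediction_model("base", truth)
    rec$distance_mm <- predict_distance(m, rec)
    list(records = rec, truth = truth)
  })
}

# Extended-variant analogue: coefficients act in the standardized feature
# space of the full record set.
extended_coefficients <- function() {
  list(lambda1 = 0.8, lambda2 = 0.3,
       b1 = c(2.0, 0.5, -0.4, 0.3, 0.25),
       b2 = c(0.35, -0.2, 0.15, 0.3),
       alpha = c(0.45, -0.35), beta = c(0.5, -0.6))
}

extended_relabeled_240 <- function() {
  cached("ext240", {
    ds <- phantom_240_noiseless()
    rec <- ds$records
    m <- prediction_model("extended", extended_coefficients(), records = rec)
    rec$distance_mm <- predict_distance(m, rec)
    list(records = rec, model = m)
  })
}
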