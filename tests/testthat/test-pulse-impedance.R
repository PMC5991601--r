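# Equivalent-circuit estimation from pulse responses.

test_that("edge detection reads back an ideal square step", {
  fs <- 1e6
  v <- numeric(2000)
  v[201:1800] <- 1.0 # step at sample 200 (0-based), fall at 1800
  p <- detect_pulse_edges(v, current = 1e-3, sample_rate = fs)
  expect_equal(p$t0, 200e-6)
  expect_equal(p$v0, 1.0)
  expect_equal(p$vx, 1.0)
})

test_that("edge detection recovers landmarks of a noiseless charging curve", {
  # V0 = 1 V, Vx = 2.5 V, tau = 150 us, pulse 0.2-1.8 ms at 1 MHz
  fs <- 1e6
  t <- (0:1999) / fs
  v <- numeric(length(t))
  on <- t >= 0.2e-3 & t < 1.8e-3
  v[on] <- 1 + (2.5 - 1) * (1 - exp(-(t[on] - 0.2e-3) / 150e-6))
  p <- detect_pulse_edges(v, current = 1e-3, sample_rate = fs)
  expect_equal(p$t0, 200e-6)
  expect_lt(abs(p$v0 - 1.0) / 1.0, 0.02)
  expect_lt(abs(p$vx - 2.5) / 2.5, 0.01)
})

test_that("degenerate waveforms raise the documented conditions", {
  expect_error(detect_pulse_edges(numeric(2000), 1e-3, sample_rate = 1e6),
               class = "nerveloc_no_pulse")
  # two separated pulses
  v <- numeric(3000)
  v[201:800] <- 1
  v[1601:2200] <- 1
  expect_error(detect_pulse_edges(v, 1e-3, sample_rate = 1e6),
               class = "nerveloc_ambiguous_pulse")
  expect_error(detect_pulse_edges(numeric(8), 1e-3, sample_rate = 1e6),
               class = "nerveloc_malformed_input")
})

test_that("full pipeline round-trips both printed circuits within 1%", {
  cases <- list(
    list(rs = 1000, rp = 15000, cp = 10e-9, i = 1e-3, dur = 2e-3),
    list(rs = 8210, rp = 48480, cp = 2.27e-9, i = 30e-6, dur = 1e-3)
  )
  for (cs in cases) {
    w <- rc_curve_df(cs$rs, cs$rp, cs$cp, cs$i, fs = 1e6,
                     pre = 2e-4, dur = cs$dur, post = 2e-4)
    rc <- fit_rc_from_pulse(detect_pulse_edges(w, cs$i))
    expect_lt(abs(rc$rs - cs$rs) / cs$rs, 0.01)
    expect_lt(abs(rc$rp - cs$rp) / cs$rp, 0.01)
    expect_lt(abs(rc$cp - cs$cp) / cs$cp, 0.01)
    expect_equal(rc$tau, rc$rp * rc$cp, tolerance = 1e-9)
  }
})

test_that("purely resistive pulse yields rp = 0 and undefined cp", {
  v <- numeric(2000)
  v[201:1800] <- 1.0
  rc <- fit_rc_from_pulse(detect_pulse_edges(v, 1e-3, sample_rate = 1e6))
  expect_equal(rc$rs, 1000)
  expect_equal(rc$rp, 0)
  expect_true(is.na(rc$cp))
  expect_error(impedance_magnitude(rc, 5e5),
               class = "nerveloc_undefined_capacitance")
  expect_equal(impedance_magnitude(rc, 0), 1000)
})

test_that("tau fit agrees with an exhaustive grid-search oracle", {
  set.seed(11)
  for (k in 1:20) {
    rs <- runif(1, 200, 5000)
    rp <- runif(1, 2000, 50000)
    cp <- runif(1, 0.5e-9, 20e-9)
    i <- runif(1, 20e-6, 2e-3)
    tau_true <- rp * cp
    dur <- max(8 * tau_true, 60 / 1e6)
    w <- rc_curve_df(rs, rp, cp, i, fs = 1e6, pre = 2e-4, dur = dur, post = 1e-4)
    p <- detect_pulse_edges(w, i)
    rc <- fit_rc_from_pulse(p)
    # independent oracle: brute-force SSE over a 10,000-point log grid
    idx <- which(w$time_s >= p$t0 & w$time_s <= p$tx)
    tr <- w$time_s[idx] - p$t0
    vv <- w$voltage_V[idx]
    grid <- exp(seq(log(1e-6), log(dur), length.out = 10000))
    sse <- vapply(grid, function(tau) {
      sum((vv - (p$v0 + (p$vx - p$v0) * (1 - exp(-tr / tau))))^2)
    }, numeric(1))
    tau_grid <- grid[which.min(sse)]
    expect_lt(abs(rc$tau - tau_grid) / tau_grid, 0.005)
  }
})

test_that("tau-fit R^2 is 1 on noiseless input and falls with noise", {
  w <- rc_curve_df(1000, 15000, 10e-9, 1e-3, fs = 1e6,
                   pre = 2e-4, dur = 2e-3, post = 2e-4)
  rc0 <- fit_rc_from_pulse(detect_pulse_edges(w, 1e-3))
  expect_equal(rc0$r_squared, 1.0, tolerance = 1e-9)

  set.seed(5)
  r2 <- vapply(c(0.05, 0.2, 0.8), function(sd) {
    wn <- w
    wn$voltage_V <- w$voltage_V + rnorm(nrow(w), sd = sd)
    suppressWarnings(fit_rc_from_pulse(detect_pulse_edges(wn, 1e-3))$r_squared)
  }, numeric(1))
  expect_true(all(diff(c(rc0$r_squared, r2)) < 0))
})

test_that("impedance magnitude reproduces the printed mock-material values", {
  # printed (Rs, Rp, Cp) triples against printed |Z| at 500 kHz
  tab <- data.frame(
    rs = c(1087.36, 858.11, 577.51, 330.75),
    rp = c(19520, 7360, 6720, 6480),
    cp = c(0.82, 5.67, 7.83, 10.39) * 1e-9,
    z = c(1161.44, 860.37, 579.19, 332.31)
  )
  for (r in seq_len(nrow(tab))) {
    z <- impedance_magnitude(tissue_rc(tab$rs[r], tab$rp[r], tab$cp[r]))
    expect_lt(abs(z - tab$z[r]) / tab$z[r], 0.005)
  }
  # DC limit: capacitor open
  expect_equal(impedance_magnitude(tissue_rc(1087.36, 19520, 0.82e-9), 0),
               20607.36)
})

test_that("impedance magnitude is monotone non-increasing in frequency", {
  set.seed(3)
  for (k in 1:10) {
    rc <- tissue_rc(runif(1, 100, 5000), runif(1, 1000, 50000),
                    runif(1, 0.1e-9, 50e-9))
    f <- 10^seq(0, 8, length.out = 60)
    z <- vapply(f, function(fi) impedance_magnitude(rc, fi), numeric(1))
    expect_true(all(diff(z) <= 1e-9))
    expect_equal(impedance_magnitude(rc, 0), rc$rs + rc$rp)
    expect_equal(z[length(z)], rc$rs, tolerance = 1e-3)
  }
})
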