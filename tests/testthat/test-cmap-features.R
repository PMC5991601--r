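# CMAP segmentation, averaging, amplitude/latency, normalization, linear
# nerve-muscle model, motor-threshold search.

biphasic <- function(n, fs, t_peak, a = 1.2e-3, b = 0.8e-3, w = 3e-3) {
  # independent template builder (positive cosine lobe peaking at t_peak,
  # negative lobe after it)
  t <- (seq_len(n) - 1) / fs
  d <- t - t_peak
  v <- numeric(n)
  pos <- abs(d) <= w / 2
  neg <- d > w / 2 & d <= 1.5 * w
  v[pos] <- a * cos(pi * d[pos] / w)^2
  v[neg] <- -b * sin(pi * (d[neg] - w / 2) / w)^2
  v
}

test_that("segmentation cuts one aligned window per trigger", {
  fs <- 2000
  trig <- c(0.1, 0.6, 1.1, 1.6)
  sig <- numeric(2 * fs)
  # inject a template 7 ms after trigger 2
  k0 <- round((trig[2] + 0.007) * fs) + 1
  sig[k0] <- 1
  rec <- emg_recording(sig, fs, trig)
  seg <- segment_by_trigger(rec, 0.05)
  expect_equal(dim(seg), c(4, 100))
  expect_equal(seg[2, 15], 1) # sample 14 (0-based) = 7 ms at 2 kHz
  expect_true(all(seg[c(1, 3, 4), ] == 0))

  rec2 <- emg_recording(sig, fs, c(trig, 2 * fs / fs - 0.010))
  expect_error(segment_by_trigger(rec2, 0.05),
               class = "nerveloc_incomplete_window")
})

test_that("grand averaging is the pointwise mean, linear, noise-reducing", {
  seg <- matrix(rnorm(400), nrow = 4)
  expect_equal(grand_average(seg), colMeans(seg))
  one <- seg[1, , drop = FALSE]
  expect_equal(grand_average(one), seg[1, ])
  expect_equal(grand_average(rbind(one, one, one, one)), seg[1, ])
  # linearity
  expect_equal(grand_average(3.5 * seg), 3.5 * grand_average(seg))
  # residual noise ~ sigma/2 after averaging 4 sweeps
  set.seed(21)
  sigma <- 1e-4
  tmpl <- biphasic(200, 2000, 0.01)
  noise <- matrix(rnorm(4 * 200, sd = sigma), nrow = 4)
  avg <- grand_average(sweep(noise, 2, tmpl, "+"))
  expect_lt(abs(sd(avg - tmpl) - sigma / 2) / (sigma / 2), 0.2)
  expect_error(grand_average(list(1:5, 1:6)), class = "nerveloc_shape_mismatch")
})

test_that("amplitude and latency read back template placement", {
  fs <- 4000 # 7.25 ms falls exactly on the sample grid
  avg <- biphasic(400, fs, 7.25e-3)
  m <- extract_amplitude_latency(avg, fs)
  expect_equal(m$vpp, 2.0e-3)
  expect_equal(m$latency, 7.25e-3)
  # shift equivariance under integer-sample delays
  m2 <- extract_amplitude_latency(biphasic(400, fs, 7.25e-3 + 1e-3), fs)
  expect_equal(m2$latency - m$latency, 1e-3)
  expect_equal(m2$vpp, m$vpp)
  expect_error(extract_amplitude_latency(numeric(400), fs),
               class = "nerveloc_no_response")
  flat <- extract_amplitude_latency(numeric(400), fs, require_response = FALSE)
  expect_false(flat$detected)
  expect_true(is.na(flat$latency))
})

test_that("normalization forces the 0/100 endpoints and exact interior values", {
  expect_equal(normalize_cmaps(c(2, 4, 6, 8) * 1e-3),
               c(0, 100 / 3, 200 / 3, 100))
  set.seed(9)
  for (k in 1:25) {
    vpp <- rnorm(4)
    if (vpp[4] == vpp[1]) next
    nc <- normalize_cmaps(vpp)
    expect_identical(nc[1], 0)
    expect_identical(nc[4], 100)
  }
  expect_error(normalize_cmaps(c(5, 5, 5, 5)), class = "nerveloc_degenerate_range")
})

test_that("linear nerve-muscle fit matches the closed-form line and lm()", {
  lv <- c(70, 77, 84, 91) * 1e-6
  nc <- c(0, 100 / 3, 200 / 3, 100)
  f <- fit_linear_nerve_model(lv, nc)
  expect_equal(f$theta1, 100 / (21e-6)) # 4.762 % per uA
  expect_equal(f$theta2, -100 * 70 / 21) # -333.33 %
  expect_equal(f$r_squared, 1.0)

  # flat response
  ff <- fit_linear_nerve_model(lv, rep(7, 4))
  expect_equal(ff$theta1, 0)
  expect_equal(ff$theta2, 7)

  # exact recovery of a planted line
  y <- 3 * lv - 10
  fr <- fit_linear_nerve_model(lv, y)
  expect_equal(fr$theta1, 3, tolerance = 1e-9)
  expect_equal(fr$theta2, -10, tolerance = 1e-9)

  # oracle: lm() on random data
  set.seed(13)
  for (k in 1:10) {
    x <- runif(4, 50e-6, 150e-6)
    y <- runif(4, -50, 150)
    f1 <- fit_linear_nerve_model(x, y)
    f2 <- stats::lm(y ~ x)
    expect_equal(f1$theta1, unname(coef(f2)[2]))
    expect_equal(f1$theta2, unname(coef(f2)[1]))
    expect_equal(f1$r_squared, summary(f2)$r.squared)
  }
  expect_error(fit_linear_nerve_model(rep(1e-4, 4), nc),
               class = "nerveloc_singular_design")
})

test_that("motor-threshold search returns the first responsive grid value", {
  oracle <- function(th) function(i) i >= th
  expect_equal(as.numeric(suppressWarnings(
    find_motor_threshold(oracle(70e-6), 10e-6, 5e-6, 500e-6))), 70e-6)
  # threshold below the start: returns start with a warning
  expect_warning(
    r <- find_motor_threshold(oracle(1e-6), 10e-6, 5e-6, 500e-6),
    class = "nerveloc_threshold_at_start"
  )
  expect_equal(as.numeric(r), 10e-6)
  expect_true(attr(r, "at_lower_bound"))
  expect_error(find_motor_threshold(oracle(1), 10e-6, 5e-6, 500e-6),
               class = "nerveloc_threshold_not_found")

  # property: smallest grid value >= true threshold
  set.seed(31)
  for (k in 1:30) {
    th <- runif(1, 15e-6, 400e-6)
    step <- runif(1, 1e-6, 20e-6)
    got <- suppressWarnings(
      find_motor_threshold(oracle(th), 10e-6, step, 600e-6))
    grid <- seq(10e-6, 600e-6, by = step)
    expect_equal(as.numeric(got), min(grid[grid >= th]))
  }
})

test_that("stimulus series enforces the 110/120/130% ladder", {
  s <- stimulus_series(70e-6)
  expect_equal(s$levels / s$i_mt, c(1, 1.1, 1.2, 1.3), tolerance = 1e-6)
  expect_true(all(diff(s$levels) > 0))
  expect_error(stimulus_series(-1), class = "nerveloc_malformed_input")
})
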