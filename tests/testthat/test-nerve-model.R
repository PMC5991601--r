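# Distance model: feature assembly, prediction, fitting.

fake_record <- function(i_mt = 1e-4, cmap = 2e-3, z = 1e3, t_l = 8e-3,
                        theta1 = 5e6, theta2 = -330, lin_r2 = 0.98,
                        rs = 1000, rp = 15000, cp = 10e-9, tau_r2 = 0.99) {
  data.frame(i_mt_a = i_mt, cmap_amp_v = cmap, z_ohm = z, t_l_s = t_l,
             theta1 = theta1, theta2 = theta2, lin_r_squared = lin_r2,
             rs_ohm = rs, rp_ohm = rp, cp_f = cp, tau_r_squared = tau_r2)
}

test_that("base predictor vector is the documented arithmetic", {
  v <- assemble_features(fake_record(), "base")
  expect_equal(unname(v), c(1e-4 / (2e-3 * 1e3), 8e-3 / 1e3, 1))
  expect_error(assemble_features(fake_record(z = 0), "base"),
               class = "nerveloc_invalid_record")
  expect_error(assemble_features(fake_record()[, -1], "base"),
               class = "nerveloc_missing_feature")
})

test_that("extended predictors include the ratio terms from the same record", {
  v <- assemble_features(fake_record(), "extended")
  expect_equal(unname(v["imt_rp"]), 1e-4 / 15000)
  expect_equal(unname(v["rs_cp"]), 1000 / 10e-9)
  expect_equal(unname(v["cp"]), 10e-9)
  expect_equal(unname(v["t_l"]), 8e-3)
  # product readings behind the config switch
  vp <- assemble_features(fake_record(), "extended",
                          feature_options(latency_term = "product",
                                          mt_rp_term = "product",
                                          rs_cp_term = "product"))
  expect_equal(unname(vp["x2"]), 8e-3 * 1e3)
  expect_equal(unname(vp["imt_rp"]), 1e-4 * 15000)
  expect_equal(unname(vp["rs_cp"]), 1000 * 10e-9)
})

test_that("prediction applies the linear and constant forms exactly", {
  r <- fake_record()
  m <- prediction_model("base", list(lambda1 = 2, lambda2 = 0, eta = 0))
  x1 <- 1e-4 / (2e-3 * 1e3)
  expect_equal(predict_distance(m, r), 2 * x1)
  # constant extended model: only the error-function offset b1(0) = 3
  me <- prediction_model("extended", list(
    lambda1 = 0, lambda2 = 0, b1 = c(3, 0, 0, 0, 0), b2 = rep(0, 4),
    alpha = c(0, 0), beta = c(0, 0)
  ))
  expect_equal(predict_distance(me, r), 3)
  expect_equal(unname(predict(me, rbind(r, r))), c(3, 3))
})

test_that("base fit equals the closed-form OLS oracle on random data", {
  set.seed(17)
  for (k in 1:50) {
    n <- 40
    rec <- data.frame(
      i_mt_a = runif(n, 2e-5, 3e-4), cmap_amp_v = runif(n, 5e-4, 5e-3),
      z_ohm = runif(n, 300, 1500), t_l_s = runif(n, 7e-3, 13e-3)
    )
    rec$distance_mm <- runif(n, 0, 4)
    fit <- fit_model(rec, "base")
    x1 <- rec$i_mt_a / (rec$cmap_amp_v * rec$z_ohm)
    x2 <- rec$t_l_s / rec$z_ohm
    oracle <- stats::lm(distance_mm ~ x1 + x2, data = cbind(rec, x1 = x1, x2 = x2))
    cr <- fit$coefficients_raw
    expect_equal(cr$lambda1, unname(coef(oracle)["x1"]), tolerance = 1e-8)
    expect_equal(cr$lambda2, unname(coef(oracle)["x2"]), tolerance = 1e-8)
    expect_equal(cr$eta, unname(coef(oracle)[1]), tolerance = 1e-8)
    expect_equal(unname(predict_distance(fit, rec)),
                 unname(predict(oracle)), tolerance = 1e-8)
  }
})

test_that("base coefficients are recovered from relabeled phantom records", {
  rl <- base_relabeled_240()
  fit <- fit_model(rl$records, "base")
  cr <- fit$coefficients_raw
  expect_lt(abs(cr$lambda1 - rl$truth$lambda1) / abs(rl$truth$lambda1), 1e-3)
  expect_lt(abs(cr$lambda2 - rl$truth$lambda2) / abs(rl$truth$lambda2), 1e-3)
  expect_lt(abs(cr$eta - rl$truth$eta) / abs(rl$truth$eta), 1e-3)
  expect_lt(fit$sse, 1e-10)
})

test_that("extended fit reproduces labels generated by a known extended model", {
  rl <- extended_relabeled_240()
  fit <- fit_model(rl$records, "extended", seed = 1)
  expect_lt(fit$sse, 1e-6)
  pred <- predict_distance(fit, rl$records)
  expect_lt(max(abs(pred - rl$records$distance_mm)), 0.01)
})

test_that("extended training SSE never exceeds base training SSE", {
  ds <- cached("noisy60", generate_dataset(small_config(seed = 8)))
  rec <- ds$records[ds$records$response, , drop = FALSE]
  fb <- fit_model(rec, "base")
  fe <- fit_model(rec, "extended", seed = 2)
  expect_lte(fe$sse, fb$sse + 1e-9)
})

test_that("fit is invariant to record order and to raw unit changes", {
  rl <- base_relabeled_240()
  rec <- rl$records
  fit <- fit_model(rec, "base")
  perm <- rev(seq_len(nrow(rec)))
  fit_p <- fit_model(rec[perm, ], "base")
  expect_equal(predict_distance(fit_p, rec), predict_distance(fit, rec),
               tolerance = 1e-9)

  # unit rescaling of raw fields transforms every assembled predictor
  # affinely; standardization absorbs it
  ds <- cached("noisy60", generate_dataset(small_config(seed = 8)))
  nrec <- ds$records[ds$records$response, , drop = FALSE]
  fe <- fit_model(nrec, "extended", seed = 3)
  scaled <- nrec
  scaled$t_l_s <- scaled$t_l_s * 1e3 # ms instead of s
  scaled$i_mt_a <- scaled$i_mt_a * 1e6 # uA instead of A
  scaled$cp_f <- scaled$cp_f * 1e9 # nF instead of F
  fe_s <- fit_model(scaled, "extended", seed = 3)
  expect_equal(predict_distance(fe_s, scaled), predict_distance(fe, nrec),
               tolerance = 1e-6)
})

test_that("extended fitting with a fixed seed is run-to-run reproducible", {
  ds <- cached("noisy60", generate_dataset(small_config(seed = 8)))
  rec <- ds$records[ds$records$response, , drop = FALSE]
  f1 <- fit_model(rec, "extended", seed = 7)
  f2 <- fit_model(rec, "extended", seed = 7)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$sse, f2$sse)
})

test_that("fitting guards its preconditions", {
  rec <- do.call(rbind, replicate(4, fake_record(), simplify = FALSE))
  rec$distance_mm <- 1:4
  expect_error(fit_model(rec, "base"), class = "nerveloc_malformed_input")
  rl <- base_relabeled_240()
  unlabeled <- rl$records[, setdiff(names(rl$records), "distance_mm")]
  expect_error(fit_model(unlabeled, "base"),
               class = "nerveloc_missing_feature")
  # constant features: rank-deficient base design
  rec2 <- do.call(rbind, replicate(10, fake_record(), simplify = FALSE))
  rec2$distance_mm <- rnorm(10)
  expect_error(fit_model(rec2, "base"), class = "nerveloc_rank_deficient")
})
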