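# Probe-to-nerve distance model.
#
# Two generative assumptions link the measurements to the distance d:
# the CMAP amplitude falls with distance and intervening impedance,
# CMAP = lambda1 * iMT / (d * Z) + eta1, and the CMAP latency grows with
# them, tL = lambda2 * (Z * d) + eta2. Combining and solving for d gives the
# base regression
#
#   d = lambda1 * iMT / (CMAP * Z) + lambda2 * tL / Z + eta.
#
# The extended model replaces the scalar offset eta with two structured
# error functions: eta1 = sum_j b1(j) X1(j) over
# X1 = [1, theta1, theta2, linear-fit R^2, iMT/Rp], and
# eta2 = sum_j b2(j) X2(j) + sum_k alpha(k) exp(beta(k) R(k)) over
# X2 = [Cp, tau-fit R^2, Rs/Cp, tL] and R = [Rs, Rp]. All predictors are
# standardized internally (the exponents act on scaled resistances; raw
# Rp ~ 1e4 ohm would overflow exp for any useful beta), and fitting
# minimizes the sum of squared distance residuals. For fixed exponents the
# model is linear in the remaining 13 parameters, so the fit profiles an
# exact least-squares solution over the two exponents.

# Canonical order of the linear predictor columns (before the intercept and
# exponential terms). Base uses the first two.
LIN_COLS_BASE <- c("x1", "x2")
LIN_COLS_EXT <- c("x1", "x2", "theta1", "theta2", "lin_r_squared",
                  "imt_rp", "cp", "tau_r_squared", "rs_cp", "t_l")

#' Feature-reading switches for the distance model
#'
#' The source formulas render fractions by juxtaposition, leaving three terms
#' with two possible readings. The defaults use the dimensionally consistent
#' ratio readings; the product readings are available for comparison.
#'
#' @param latency_term `"ratio"` for `tL / Z` (default; the latency
#'   assumption `tL = lambda2 * Z * d` inverts to `d` proportional to
#'   `tL / Z`) or `"product"` for `tL * Z`.
#' @param mt_rp_term `"ratio"` for `iMT / Rp` (default) or `"product"`.
#' @param rs_cp_term `"ratio"` for `Rs / Cp` (default) or `"product"`.
#' @param cmap_level Which grand-averaged amplitude enters the base term:
#'   an index 1-4 (default 1, the MT level, matching the `iMT` in the same
#'   term) or `"mean"` for the mean of the four.
#'
#' @return A list of class `feature_options`.
#' @export
feature_options <- function(latency_term = c("ratio", "product"),
                            mt_rp_term = c("ratio", "product"),
                            rs_cp_term = c("ratio", "product"),
                            cmap_level = 1) {
  structure(
    list(
      latency_term = match.arg(latency_term),
      mt_rp_term = match.arg(mt_rp_term),
      rs_cp_term = match.arg(rs_cp_term),
      cmap_level = cmap_level
    ),
    class = "feature_options"
  )
}

# Raw (unscaled) predictor columns for a set of feature records.
# Returns list(lin = matrix of linear columns, r = matrix [rs, rp] or NULL).
raw_feature_matrix <- function(records, variant, options = feature_options()) {
  need <- c("i_mt_a", "cmap_amp_v", "z_ohm", "t_l_s")
  if (variant == "extended") {
    need <- c(need, "theta1", "theta2", "lin_r_squared",
              "rs_ohm", "rp_ohm", "cp_f", "tau_r_squared")
  }
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0) {
    nl_stop("missing_feature", "records lack required columns: %s",
            paste(missing_cols, collapse = ", "))
  }
  bad <- records$z_ohm <= 0 | records$cmap_amp_v <= 0 | records$i_mt_a <= 0
  if (variant == "extended") {
    bad <- bad | records$rp_ohm <= 0 | records$cp_f <= 0
  }
  if (any(bad, na.rm = TRUE) || anyNA(bad)) {
    nl_stop("invalid_record",
            "record %d has a non-positive or missing value in a divisor field",
            which(bad | is.na(bad))[1])
  }
  x1 <- records$i_mt_a / (records$cmap_amp_v * records$z_ohm)
  x2 <- if (options$latency_term == "ratio") {
    records$t_l_s / records$z_ohm
  } else {
    records$t_l_s * records$z_ohm
  }
  if (variant == "base") {
    return(list(lin = cbind(x1 = x1, x2 = x2), r = NULL))
  }
  imt_rp <- if (options$mt_rp_term == "ratio") {
    records$i_mt_a / records$rp_ohm
  } else {
    records$i_mt_a * records$rp_ohm
  }
  rs_cp <- if (options$rs_cp_term == "ratio") {
    records$rs_ohm / records$cp_f
  } else {
    records$rs_ohm * records$cp_f
  }
  lin <- cbind(
    x1 = x1, x2 = x2,
    theta1 = records$theta1, theta2 = records$theta2,
    lin_r_squared = records$lin_r_squared,
    imt_rp = imt_rp,
    cp = records$cp_f, tau_r_squared = records$tau_r_squared,
    rs_cp = rs_cp, t_l = records$t_l_s
  )
  list(lin = lin, r = cbind(rs = records$rs_ohm, rp = records$rp_ohm))
}

#' Assemble the predictor vector of one feature record
#'
#' @param record A one-row data frame (or coercible list) with the feature
#'   columns produced by the extraction pipeline (`i_mt_a`, `cmap_amp_v`,
#'   `z_ohm`, `t_l_s`, and for the extended variant `theta1`, `theta2`,
#'   `lin_r_squared`, `rs_ohm`, `rp_ohm`, `cp_f`, `tau_r_squared`).
#' @param variant `"base"` or `"extended"`.
#' @param options A [feature_options()].
#'
#' @return A named numeric vector in raw SI units: base
#'   `[x1, x2, intercept]`; extended appends the error-function predictors
#'   and the raw resistances `rs`, `rp` used by the exponential terms.
#' @export
assemble_features <- function(record, variant = c("base", "extended"),
                              options = feature_options()) {
  variant <- match.arg(variant)
  record <- as.data.frame(record)
  m <- raw_feature_matrix(record, variant, options)
  v <- c(m$lin[1, ], intercept = 1)
  if (variant == "extended") v <- c(v, m$r[1, ])
  v
}

# Per-column location/scale computed on a training set. Intercept and
# constant columns are left unscaled.
compute_scaling <- function(raw) {
  sc <- function(mat) {
    ctr <- colMeans(mat)
    scl <- apply(mat, 2, stats::sd)
    scl[!is.finite(scl) | scl == 0] <- 1
    list(center = ctr, scale = scl)
  }
  out <- list(lin = sc(raw$lin))
  if (!is.null(raw$r)) out$r <- sc(raw$r)
  out
}

apply_scaling <- function(raw, scaling) {
  out <- list(lin = sweep(sweep(raw$lin, 2, scaling$lin$center), 2,
                          scaling$lin$scale, "/"))
  if (!is.null(raw$r)) {
    out$r <- sweep(sweep(raw$r, 2, scaling$r$center), 2, scaling$r$scale, "/")
  }
  out
}

identity_scaling <- function(variant) {
  lin_cols <- if (variant == "base") LIN_COLS_BASE else LIN_COLS_EXT
  zero1 <- function(nm) list(center = stats::setNames(rep(0, length(nm)), nm),
                             scale = stats::setNames(rep(1, length(nm)), nm))
  out <- list(lin = zero1(lin_cols))
  if (variant == "extended") out$r <- zero1(c("rs", "rp"))
  out
}

# Linear-coefficient vector in canonical column order + intercept, from the
# model's named coefficient list.
lin_coef_vector <- function(coef, variant) {
  if (variant == "base") {
    list(beta_lin = c(coef$lambda1, coef$lambda2), intercept = coef$eta)
  } else {
    list(
      beta_lin = c(coef$lambda1, coef$lambda2, coef$b1[2:5], coef$b2[1:4]),
      intercept = coef$b1[1]
    )
  }
}

model_predict_scaled <- function(scaled, coef, variant) {
  cv <- lin_coef_vector(coef, variant)
  d <- drop(scaled$lin %*% cv$beta_lin) + cv$intercept
  if (variant == "extended") {
    d <- d +
      coef$alpha[1] * exp(coef$beta[1] * scaled$r[, "rs"]) +
      coef$alpha[2] * exp(coef$beta[2] * scaled$r[, "rp"])
  }
  unname(d)
}

#' Construct a distance-prediction model from explicit coefficients
#'
#' Builds a fitted-model object without estimation, e.g. for simulation
#' studies where records are labeled by a known model. Coefficients are
#' interpreted in the standardized feature space defined by `records`; when
#' `records` is `NULL` the scaling is the identity and coefficients act on
#' raw features.
#'
#' @param variant `"base"` or `"extended"`.
#' @param coefficients For `"base"`, a list or named vector with `lambda1`,
#'   `lambda2`, `eta`. For `"extended"`, a list with `lambda1`, `lambda2`,
#'   `b1` (5 values, `b1[1]` the intercept term), `b2` (4 values), `alpha`
#'   (2) and `beta` (2).
#' @param records Optional feature records from which to compute the
#'   standardization.
#' @param options A [feature_options()].
#'
#' @return An object of class `nerve_model`.
#' @export
prediction_model <- function(variant = c("base", "extended"), coefficients,
                             records = NULL, options = feature_options()) {
  variant <- match.arg(variant)
  coefficients <- as.list(coefficients)
  if (variant == "base") {
    stopifnot(all(c("lambda1", "lambda2", "eta") %in% names(coefficients)))
  } else {
    stopifnot(all(c("lambda1", "lambda2", "b1", "b2", "alpha", "beta") %in%
                    names(coefficients)),
              length(coefficients$b1) == 5, length(coefficients$b2) == 4,
              length(coefficients$alpha) == 2, length(coefficients$beta) == 2)
  }
  scaling <- if (is.null(records)) {
    identity_scaling(variant)
  } else {
    compute_scaling(raw_feature_matrix(as.data.frame(records), variant, options))
  }
  structure(
    list(
      variant = variant, options = options, scaling = scaling,
      coefficients = coefficients,
      coefficients_raw = if (variant == "base") {
        base_raw_coefficients(coefficients, scaling)
      },
      sse = NA_real_, converged = TRUE, n_obs = NA_integer_, seed = NA_integer_
    ),
    class = "nerve_model"
  )
}

# Back-transform base coefficients from scaled to raw feature space:
# y = sum c_j (x_j - m_j)/s_j + c0  =>  raw slope c_j/s_j,
# raw intercept c0 - sum c_j m_j/s_j.
base_raw_coefficients <- function(coef, scaling) {
  s <- scaling$lin$scale
  m <- scaling$lin$center
  sl <- unname(c(coef$lambda1, coef$lambda2) / s)
  list(lambda1 = sl[1], lambda2 = sl[2],
       eta = unname(coef$eta - sum(c(coef$lambda1, coef$lambda2) * m / s)))
}

ols_fit <- function(D, y) {
  fit <- stats::lm.fit(D, y)
  co <- fit$coefficients
  co[is.na(co)] <- 0
  list(coef = co, sse = sum(fit$residuals^2), rank = fit$rank)
}

#' Fit the probe-to-nerve distance model
#'
#' Minimizes the sum of squared distance residuals over the training
#' records. The base variant (3 parameters) is an ordinary least-squares
#' problem solved in closed form. The extended variant (15 parameters) is
#' solved by profiling: for fixed exponents `beta` the remaining 13
#' parameters are linear and solved exactly, and the two exponents are
#' optimized by multi-start bounded quasi-Newton search (|beta| <= 10 on
#' standardized resistances; starts at (+-0.1, +-0.1) plus seeded random
#' points).
#'
#' @param records Data frame of labeled feature records with a
#'   `distance_mm` column.
#' @param variant `"base"` or `"extended"`.
#' @param options A [feature_options()].
#' @param seed Integer seed controlling the random multi-starts; fits are
#'   bit-reproducible given the seed.
#' @param n_starts Number of exponent starts (>= 4; the first four are the
#'   deterministic sign combinations).
#' @param beta_bound Bound on the exponents in scaled-resistance space.
#'
#' @return A fitted `nerve_model`.
#' @export
fit_model <- function(records, variant = c("base", "extended"),
                      options = feature_options(), seed = 1L,
                      n_starts = 8L, beta_bound = 10) {
  variant <- match.arg(variant)
  records <- as.data.frame(records)
  if (!"distance_mm" %in% names(records)) {
    nl_stop("missing_feature", "records need a distance_mm label column")
  }
  n_par <- if (variant == "base") 3L else 15L
  if (nrow(records) < 2L * n_par) {
    nl_stop("malformed_input", "need at least %d records to fit %d parameters",
            2L * n_par, n_par)
  }
  y <- records$distance_mm
  raw <- raw_feature_matrix(records, variant, options)
  scaling <- compute_scaling(raw)
  scaled <- apply_scaling(raw, scaling)

  if (variant == "base") {
    D <- cbind(scaled$lin, intercept = 1)
    if (qr(D)$rank < ncol(D)) {
      nl_stop("rank_deficient", "base design matrix is rank deficient")
    }
    f <- ols_fit(D, y)
    coef <- list(lambda1 = f$coef[[1]], lambda2 = f$coef[[2]], eta = f$coef[[3]])
    model <- structure(
      list(variant = variant, options = options, scaling = scaling,
           coefficients = coef,
           coefficients_raw = base_raw_coefficients(coef, scaling),
           sse = f$sse, converged = TRUE, n_obs = nrow(records),
           seed = as.integer(seed)),
      class = "nerve_model"
    )
    return(model)
  }

  # Extended: profile the linear subproblem over the two exponents.
  lin1 <- cbind(scaled$lin, intercept = 1)
  rs_s <- scaled$r[, "rs"]
  rp_s <- scaled$r[, "rp"]
  profile_sse <- function(beta) {
    D <- cbind(lin1, exp(beta[1] * rs_s), exp(beta[2] * rp_s))
    ols_fit(D, y)$sse
  }

  starts <- rbind(
    c(-0.1, -0.1), c(-0.1, 0.1), c(0.1, -0.1), c(0.1, 0.1)
  )
  if (n_starts > 4) {
    extra <- with_seed(seed, matrix(stats::runif((n_starts - 4) * 2, -2, 2),
                                    ncol = 2))
    starts <- rbind(starts, extra)
  }
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    opt <- tryCatch(
      stats::optim(starts[k, ], profile_sse, method = "L-BFGS-B",
                   lower = -beta_bound, upper = beta_bound,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL
    )
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) {
    nl_stop("fit_not_converged", "all exponent starts failed in the extended fit")
  }
  beta <- best$par
  D <- cbind(lin1, exp(beta[1] * rs_s), exp(beta[2] * rp_s))
  f <- ols_fit(D, y)
  co <- f$coef
  p <- ncol(scaled$lin) # 10 linear columns
  coef <- list(
    lambda1 = co[[1]], lambda2 = co[[2]],
    b1 = c(co[[p + 1]], co[[3]], co[[4]], co[[5]], co[[6]]),
    b2 = c(co[[7]], co[[8]], co[[9]], co[[10]]),
    alpha = c(co[[p + 2]], co[[p + 3]]),
    beta = beta
  )
  structure(
    list(variant = variant, options = options, scaling = scaling,
         coefficients = coef, coefficients_raw = NULL,
         sse = f$sse, converged = best$convergence == 0, n_obs = nrow(records),
         seed = as.integer(seed)),
    class = "nerve_model"
  )
}

#' Predict probe-to-nerve distances for feature records
#'
#' @param model A fitted `nerve_model`.
#' @param records Data frame of feature records.
#'
#' @return Predicted distances in millimetres.
#' @export
predict_distance <- function(model, records) {
  if (!inherits(model, "nerve_model")) {
    nl_stop("unfitted_model", "model must be a nerve_model")
  }
  records <- as.data.frame(records)
  raw <- raw_feature_matrix(records, model$variant, model$options)
  scaled <- apply_scaling(raw, model$scaling)
  model_predict_scaled(scaled, model$coefficients, model$variant)
}

#' @export
predict.nerve_model <- function(object, newdata, ...) {
  predict_distance(object, newdata)
}

#' @export
print.nerve_model <- function(x, ...) {
  cat(sprintf("<nerve_model> variant = %s, n = %s, SSE = %.4g mm^2\n",
              x$variant, x$n_obs, x$sse))
  if (x$variant == "base" && !is.null(x$coefficients_raw)) {
    cat(sprintf("  raw-space: lambda1 = %.6g, lambda2 = %.6g, eta = %.6g\n",
                x$coefficients_raw$lambda1, x$coefficients_raw$lambda2,
                x$coefficients_raw$eta))
  } else {
    cat(sprintf("  beta (scaled Rs, Rp) = (%.4g, %.4g), alpha = (%.4g, %.4g)\n",
                x$coefficients$beta[1], x$coefficients$beta[2],
                x$coefficients$alpha[1], x$coefficients$alpha[2]))
  }
  invisible(x)
}

#' @export
coef.nerve_model <- function(object, ...) {
  if (object$variant == "base") {
    unlist(object$coefficients_raw)
  } else {
    object$coefficients
  }
}
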