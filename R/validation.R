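# Cross-validation of the distance model with the two headline metrics:
# correlation-based prediction accuracy (Pearson r x 100 between predictions
# and held-out labels, a per-fold statistic) and average absolute error in
# millimetres. Note the accuracy metric is invariant under any
# positive-slope affine transform of the predictions; it measures linear
# association, not calibration — the error metric covers the latter.

#' Correlation-based prediction accuracy
#'
#' Pearson correlation coefficient between predicted and actual distances,
#' expressed as a signed percentage.
#'
#' @param predicted,actual Equal-length numeric vectors (length >= 3).
#'
#' @return Accuracy in percent, in `[-100, 100]`.
#' @export
prediction_accuracy <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    nl_stop("length_mismatch", "predicted and actual differ in length")
  }
  if (length(actual) < 3) nl_stop("malformed_input", "need at least 3 pairs")
  if (stats::sd(actual) == 0) {
    nl_stop("constant_truth", "actual distances have zero variance")
  }
  100 * stats::cor(predicted, actual)
}

#' Average absolute prediction error
#'
#' @param predicted,actual Equal-length numeric vectors in millimetres.
#' @param type `"mae"` (default, mean absolute error) or `"rmse"`.
#'
#' @return Error in millimetres.
#' @export
average_error <- function(predicted, actual, type = c("mae", "rmse")) {
  type <- match.arg(type)
  if (length(predicted) != length(actual)) {
    nl_stop("length_mismatch", "predicted and actual differ in length")
  }
  if (length(actual) < 1) nl_stop("malformed_input", "need at least one pair")
  r <- predicted - actual
  switch(type, mae = mean(abs(r)), rmse = sqrt(mean(r^2)))
}

#' k-fold cross-validation of the distance model
#'
#' Shuffles the records with the given seed, partitions them into `k`
#' near-equal disjoint folds, and for each fold fits the model on the
#' remaining records and evaluates both metrics on the held-out fold.
#' With `group_by`, entire groups (e.g. subjects) are assigned to folds so
#' that no group straddles a train/test split.
#'
#' @param records Labeled feature records (data frame with `distance_mm`).
#' @param variant `"base"` or `"extended"`.
#' @param k Number of folds (>= 2, <= number of records).
#' @param seed Integer seed for the shuffle (and the extended fit's starts).
#' @param group_by Optional name of a grouping column; folds then partition
#'   groups rather than records.
#' @param error_type Passed to [average_error()].
#' @param options A [feature_options()].
#'
#' @return An object of class `cv_report` with per-fold accuracies (percent)
#'   and errors (mm), their means and sample (n-1) SDs across folds, the
#'   record-to-fold assignment and the seed. Folds whose fit fails are
#'   flagged in `failed_folds` and excluded from the summaries.
#' @export
cross_validate <- function(records, variant = c("base", "extended"), k = 10L,
                           seed = 1L, group_by = NULL,
                           error_type = c("mae", "rmse"),
                           options = feature_options()) {
  variant <- match.arg(variant)
  error_type <- match.arg(error_type)
  records <- as.data.frame(records)
  n <- nrow(records)
  if (k < 2) nl_stop("malformed_input", "k must be >= 2")
  if (n < k) nl_stop("malformed_input", "need at least k = %d records", k)

  fold_of <- integer(n)
  if (is.null(group_by)) {
    perm <- with_seed(seed, sample.int(n))
    fold_of[perm] <- rep_len(seq_len(k), n)
  } else {
    g <- records[[group_by]]
    if (is.null(g)) nl_stop("missing_feature", "no column '%s' to group by", group_by)
    gl <- unique(g)
    if (length(gl) < k) nl_stop("malformed_input", "fewer groups than folds")
    perm <- with_seed(seed, sample(length(gl)))
    gf <- integer(length(gl))
    gf[perm] <- rep_len(seq_len(k), length(gl))
    fold_of <- gf[match(g, gl)]
  }

  fold_acc <- rep(NA_real_, k)
  fold_err <- rep(NA_real_, k)
  failed <- logical(k)
  oof <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    test <- fold_of == f
    res <- tryCatch({
      m <- fit_model(records[!test, , drop = FALSE], variant,
                     options = options, seed = seed)
      pred <- predict_distance(m, records[test, , drop = FALSE])
      list(
        acc = prediction_accuracy(pred, records$distance_mm[test]),
        err = average_error(pred, records$distance_mm[test], type = error_type),
        pred = pred
      )
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[f] <- TRUE
      nl_warn("fold_failed", "fold %d failed: %s", f, conditionMessage(res))
    } else {
      fold_acc[f] <- res$acc
      fold_err[f] <- res$err
      oof[test] <- res$pred
    }
  }

  ok <- !failed
  structure(
    list(
      k = k, variant = variant, seed = as.integer(seed),
      fold_accuracy = fold_acc, fold_error = fold_err,
      mean_accuracy = mean(fold_acc[ok]), sd_accuracy = stats::sd(fold_acc[ok]),
      mean_error = mean(fold_err[ok]), sd_error = stats::sd(fold_err[ok]),
      fold_assignments = fold_of, failed_folds = which(failed),
      predictions = oof, error_type = error_type
    ),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "<cv_report> %d-fold, %s variant, seed %d\n  accuracy = %.2f%% (SD = %.2f%%, n = %d)\n  %s error = %.3g mm (SD = %.3g mm, n = %d)\n",
    x$k, x$variant, x$seed,
    x$mean_accuracy, x$sd_accuracy, sum(!is.na(x$fold_accuracy)),
    toupper(x$error_type), x$mean_error, x$sd_error,
    sum(!is.na(x$fold_error))
  ))
  if (length(x$failed_folds)) {
    cat("  failed folds:", paste(x$failed_folds, collapse = ", "), "\n")
  }
  invisible(x)
}
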