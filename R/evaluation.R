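# Accuracy and comparison statistics. "MAD" follows the field's usage in
# epigenetic age prediction: the mean absolute deviation between predicted
# and chronological age in years (not the robust median-absolute-deviation
# statistic), exposed as mad_prediction() to avoid the name collision.

#' Mean absolute deviation between predicted and chronological age
#'
#' @param predicted,chronological numeric vectors in years.
#' @param na.rm drop pairs with missing values.
#' @return mean of `|predicted - chronological|`, in years.
#' @export
mad_prediction <- function(predicted, chronological, na.rm = FALSE) {
  if (length(predicted) != length(chronological)) {
    stop_validation("prediction and age vectors differ in length")
  }
  mean(abs(predicted - chronological), na.rm = na.rm)
}

#' Summarize prediction accuracy
#'
#' Computes the accuracy statistics used throughout the buccal-swab age
#' prediction analyses: MAD (mean absolute deviation, years), mean signed
#' error (years; positive = overestimation) and squared Pearson correlation.
#' Note that R^2 is invariant to affine rescaling of the predictions, so a
#' high R^2 alone cannot certify calibration -- a blood-trained model applied
#' to swabs can correlate strongly with age while overestimating it by more
#' than a decade.
#'
#' @param predicted,chronological numeric vectors in years (pairs with
#'   missing values are dropped).
#' @return object of class `evaluation_report`: list with `n`, `mad`,
#'   `mean_signed_error`, `r2` (`NA` with `r2_reason` when undefined).
#' @export
evaluate_predictions <- function(predicted, chronological) {
  if (length(predicted) != length(chronological)) {
    stop_validation("prediction and age vectors differ in length")
  }
  ok <- !is.na(predicted) & !is.na(chronological)
  p <- predicted[ok]; a <- chronological[ok]
  if (!length(p)) stop_validation("no complete prediction pairs")
  r2 <- NA_real_; reason <- NULL
  if (length(p) < 2) {
    reason <- "fewer than 2 pairs"
  } else if (stats::sd(p) == 0 || stats::sd(a) == 0) {
    reason <- "zero variance in predictions or ages"
  } else {
    r2 <- stats::cor(p, a)^2
  }
  structure(list(n = length(p), mad = mean(abs(p - a)),
                 mean_signed_error = mean(p - a), r2 = r2,
                 r2_reason = reason),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("n = %d: MAD = %.3g y, mean signed error = %+.3g y, R^2 = %s\n",
              x$n, x$mad, x$mean_signed_error,
              if (is.na(x$r2)) paste0("NA (", x$r2_reason, ")")
              else sprintf("%.4g", x$r2)))
  invisible(x)
}

#' Paired comparison of two models' absolute errors
#'
#' Classical paired two-sided Student's t-test on per-sample absolute
#' prediction errors, the test used to compare age predictors on the same
#' samples.
#'
#' @param abs_errors_a,abs_errors_b equal-length vectors (>= 3) of per-sample
#'   absolute errors in years, aligned by sample.
#' @return list with `t`, `df`, `p` and `mean_difference` (a minus b).
#' @export
compare_model_errors <- function(abs_errors_a, abs_errors_b) {
  if (length(abs_errors_a) != length(abs_errors_b)) {
    stop_validation("paired error vectors differ in length")
  }
  if (length(abs_errors_a) < 3) {
    stop_validation("need at least 3 pairs")
  }
  d <- abs_errors_a - abs_errors_b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      # identical error vectors: no evidence of any difference
      return(list(t = 0, df = length(d) - 1, p = 1, mean_difference = 0))
    }
    stop_compute("zero variance of paired differences; t-test undefined")
  }
  ht <- stats::t.test(abs_errors_a, abs_errors_b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_difference = mean(d))
}

#' Unpaired two-group comparison
#'
#' Two-sided t-test between two groups of values (e.g. signature output in
#' smokers vs non-smokers). Classical equal-variance t by default; Welch
#' behind `welch = TRUE`.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @param welch use the Welch correction.
#' @return list with `t`, `df`, `p` and `mean_difference` (a minus b).
#' @export
compare_groups <- function(values_a, values_b, welch = FALSE) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop_validation("each group needs at least 2 values")
  }
  if (stats::sd(c(values_a - mean(values_a), values_b - mean(values_b))) == 0) {
    stop_compute("zero within-group variance; t-test undefined")
  }
  ht <- stats::t.test(values_a, values_b, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_difference = mean(values_a) - mean(values_b))
}

#' Age-stratified accuracy
#'
#' Splits samples at a chronological-age cutpoint (the published analyses use
#' 30 or 35 years) and reports per-stratum n and MAD. An empty stratum is
#' reported with `n = 0` and missing MAD.
#'
#' @param predicted,chronological numeric vectors in years.
#' @param cutpoint_years stratification age (default 30).
#' @return data frame with columns `stratum`, `n`, `mad`.
#' @export
stratify_mad <- function(predicted, chronological, cutpoint_years = 30) {
  if (length(predicted) != length(chronological)) {
    stop_validation("prediction and age vectors differ in length")
  }
  young <- !is.na(chronological) & chronological < cutpoint_years
  old <- !is.na(chronological) & chronological >= cutpoint_years
  one <- function(sel, label) {
    p <- predicted[sel]; a <- chronological[sel]
    ok <- !is.na(p)
    data.frame(stratum = label, n = sum(sel),
               mad = if (any(ok)) mean(abs(p[ok] - a[ok])) else NA_real_,
               stringsAsFactors = FALSE)
  }
  rbind(one(young, sprintf("<%g y", cutpoint_years)),
        one(old, sprintf(">=%g y", cutpoint_years)))
}
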