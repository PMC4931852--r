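# Training: re-derive every model class from annotated beta-value data.
#
# All estimators are plain least squares (the published models use no
# regularization). Each returns a "swabage_fit" report holding the fitted
# model plus training diagnostics: n, MAD (mean absolute deviation between
# predicted and chronological age, the field's usage -- not the robust
# median statistic) and squared Pearson correlation.

swabage_fit <- function(model, n_samples, residual_mad, r2, excluded,
                        extra = list()) {
  structure(c(list(model = model, n_samples = n_samples,
                   residual_mad = residual_mad, r2 = r2,
                   excluded = excluded), extra),
            class = "swabage_fit")
}

#' @export
print.swabage_fit <- function(x, ...) {
  cat(sprintf("Fit of '%s' on %d samples: MAD = %.3g y, R^2 = %s\n",
              x$model$name, x$n_samples, x$residual_mad,
              if (is.na(x$r2)) "NA" else sprintf("%.4g", x$r2)))
  if (nrow(x$excluded)) {
    cat(sprintf("  %d sample(s) excluded (%s, ...)\n", nrow(x$excluded),
                x$excluded$reason[1]))
  }
  invisible(x)
}

#' @export
coef.swabage_fit <- function(object, ...) coef(object$model)

#' @export
summary.swabage_fit <- function(object, ...) {
  print(object)
  print(object$model)
  invisible(object)
}

#' @export
predict.swabage_fit <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}

# rows usable for fitting + exclusion report
select_complete <- function(data, probes, need_age = TRUE,
                            extra_cols = character(0)) {
  X <- probe_values(data, probes)
  keep <- !apply(X, 1, anyNA)
  reasons <- ifelse(keep, "", "missing beta-value")
  if (need_age) {
    has_age <- !is.na(data$samples$age_years)
    reasons[keep & !has_age] <- "missing age"
    keep <- keep & has_age
  }
  for (col in extra_cols) {
    v <- data$samples[[col]]
    if (is.null(v)) v <- rep(NA_real_, length(keep))
    ok <- !is.na(v)
    reasons[keep & !ok] <- paste("missing", col)
    keep <- keep & ok
  }
  excluded <- data.frame(sample_id = data$samples$sample_id[!keep],
                         reason = reasons[!keep], stringsAsFactors = FALSE)
  list(X = X[keep, , drop = FALSE],
       samples = data$samples[keep, , drop = FALSE],
       excluded = excluded)
}

# least squares via QR with an explicit rank check naming the offending column
ls_solve <- function(D, y) {
  q <- qr(D)
  if (q$rank < ncol(D)) {
    dropped <- colnames(D)[q$pivot[(q$rank + 1):ncol(D)]]
    stop_compute("design is rank deficient; aliased column(s): ",
                 paste(dropped, collapse = ", "))
  }
  stats::setNames(qr.coef(q, y), colnames(D))
}

pearson_r2 <- function(pred, obs) {
  if (length(obs) < 2 || stats::sd(obs) == 0 || stats::sd(pred) == 0) {
    return(NA_real_)
  }
  stats::cor(pred, obs)^2
}

#' Fit a linear multi-CpG age model by ordinary least squares
#'
#' Regresses chronological age on the beta-values of the given probes with an
#' intercept. Samples missing the age or any probe are excluded and listed in
#' the report.
#'
#' @param data a [beta_matrix()] with ages attached (see [join_metadata()]).
#' @param probes character vector of probe IDs to use as predictors.
#' @return a `swabage_fit` whose `$model` is an [age_model()]; diagnostics are
#'   training-set MAD (years) and squared Pearson correlation.
#' @export
fit_age_model <- function(data, probes) {
  sel <- select_complete(data, probes)
  n <- nrow(sel$X)
  if (n < length(probes) + 2) {
    stop_compute(sprintf("need at least %d complete samples, got %d",
                         length(probes) + 2, n))
  }
  D <- cbind("(Intercept)" = 1, sel$X)
  cf <- ls_solve(D, sel$samples$age_years)
  model <- age_model(cf[1], cf[-1], name = "fitted age model")
  pred <- as.numeric(predict(model, sel$X))
  swabage_fit(model, n,
              residual_mad = mean(abs(pred - sel$samples$age_years)),
              r2 = pearson_r2(pred, sel$samples$age_years),
              excluded = sel$excluded)
}

#' Fit a one-CpG age model (regression of beta on age, inverted)
#'
#' Fits the simple regression `beta = beta0 + slope * age` and stores it
#' inverted for prediction, `age = (beta - beta0) / slope`. This is the
#' fitting direction implied by the published one-CpG formula.
#'
#' @param data a [beta_matrix()] with ages attached.
#' @param probe the probe ID.
#' @return a `swabage_fit` whose `$model` is a [one_cpg_model()].
#' @export
fit_one_cpg_model <- function(data, probe) {
  sel <- select_complete(data, probe)
  n <- nrow(sel$X)
  if (n < 3) stop_compute("need at least 3 complete samples, got ", n)
  age <- sel$samples$age_years
  if (stats::sd(age) == 0) stop_compute("age variance is zero")
  cf <- ls_solve(cbind("(Intercept)" = 1, age = age), sel$X[, 1])
  if (abs(cf["age"]) < 1e-12) {
    stop_compute("fitted slope is zero; the regression line is not invertible")
  }
  model <- one_cpg_model(probe, beta0 = cf[1], slope = cf[2],
                         name = "fitted 1-CpG model")
  pred <- as.numeric(predict(model, sel$X))
  swabage_fit(model, n, residual_mad = mean(abs(pred - age)),
              r2 = pearson_r2(pred, age), excluded = sel$excluded)
}

#' Calibrate a two-CpG cell signature against counted cell fractions
#'
#' Regresses the cytologically counted percentage of epithelial cells
#' independently on each marker beta-value and combines the two calibration
#' lines with the given weights (default 1/2, 1/2) into a [cell_signature()].
#'
#' @param data a [beta_matrix()] carrying counted fractions in the label
#'   column given by `counted_col` (attach cytology via [join_metadata()]).
#' @param probe_delta,probe_epsilon marker probe IDs.
#' @param counted_col name of the label column with counted percentages.
#' @param weights two weights summing to 1.
#' @return a `swabage_fit` whose `$model` is a [cell_signature()]; `$r2` is
#'   the combined signature-vs-counts squared correlation, with per-CpG
#'   values in `$r2_delta` and `$r2_epsilon`, and `$residual_mad` the mean
#'   absolute error in percentage points.
#' @export
calibrate_cell_signature <- function(data, probe_delta, probe_epsilon,
                                     counted_col = "pct_epithelial_counted",
                                     weights = c(0.5, 0.5)) {
  if (!counted_col %in% names(data$samples)) {
    stop_validation("no '", counted_col, "' column; attach cytology first")
  }
  sel <- select_complete(data, c(probe_delta, probe_epsilon),
                         need_age = FALSE, extra_cols = counted_col)
  n <- nrow(sel$X)
  if (n < 3) stop_compute("need at least 3 calibration samples, got ", n)
  counted <- sel$samples[[counted_col]]
  if (stats::sd(counted) == 0) {
    stop_compute("counted fractions have zero variance")
  }
  fit1 <- function(x) {
    cf <- ls_solve(cbind("(Intercept)" = 1, beta = x), counted)
    c(slope = unname(cf["beta"]), intercept = unname(cf["(Intercept)"]))
  }
  cal_d <- fit1(sel$X[, 1])
  cal_e <- fit1(sel$X[, 2])
  model <- cell_signature(probe_delta, probe_epsilon, cal_d, cal_e,
                          weights = weights, name = "fitted cell signature")
  pred <- as.numeric(predict(model, sel$X))
  swabage_fit(model, n, residual_mad = mean(abs(pred - counted)),
              r2 = pearson_r2(pred, counted), excluded = sel$excluded,
              extra = list(
                r2_delta = pearson_r2(cal_d["slope"] * sel$X[, 1], counted),
                r2_epsilon = pearson_r2(cal_e["slope"] * sel$X[, 2], counted)))
}

#' Estimate the epithelial age model inside a mixture (two-stage plug-in)
#'
#' Treats the blood age model and the cell signature as fixed, exactly as in
#' the published two-stage procedure. For each sample with estimated percent
#' epithelial cells `B_i` (clamped signature output) and weight
#' `w_i = B_i/100`, the leukocyte contribution is subtracted,
#' `r_i = age_i - (1 - w_i) * blood(betas_i)`, and the epithelial
#' coefficients `c` are obtained by least squares of `r_i` on the scaled
#' design `w_i * (1, beta_i)` with no free intercept (the epithelial
#' intercept is the coefficient of the `w_i` column). Near-zero `w_i` rows
#' are retained; they carry essentially no information but keep the
#' procedure threshold-free.
#'
#' @param data a [beta_matrix()] with ages attached; must contain the age
#'   probes and the signature's marker probes.
#' @param blood the fixed leukocyte [age_model()].
#' @param signature the fixed [cell_signature()].
#' @param probes age-probe IDs for the epithelial model (defaults to the
#'   blood model's probes).
#' @return a `swabage_fit` whose `$model` is a [mixture_age_model()];
#'   diagnostics are training MAD and R^2 of the full mixture prediction.
#' @export
fit_epithelial_age_model <- function(data, blood, signature,
                                     probes = names(blood$coefficients)) {
  stopifnot(inherits(blood, "age_model"), inherits(signature, "cell_signature"))
  sel <- select_complete(
    data, c(probes, signature$probe_delta, signature$probe_epsilon))
  n <- nrow(sel$X)
  if (n < length(probes) + 2) {
    stop_compute(sprintf("need at least %d complete samples, got %d",
                         length(probes) + 2, n))
  }
  frac <- as.numeric(predict(signature, sel$X))
  w <- frac / 100
  if (all(w == 0)) {
    stop_compute("all estimated epithelial fractions are zero; ",
                 "the epithelial component is unidentifiable")
  }
  age <- sel$samples$age_years
  blood_pred <- as.numeric(predict(blood, sel$X))
  r <- age - (1 - w) * blood_pred
  D <- w * cbind("(Intercept)" = 1, sel$X[, probes, drop = FALSE])
  cf <- ls_solve(D, r)
  epithelial <- age_model(cf[1], cf[-1], name = "fitted epithelial sub-model")
  model <- mixture_age_model(blood, epithelial, signature,
                             name = "fitted mixture age model")
  pred <- suppressWarnings(predict(model, sel$X)$age)
  swabage_fit(model, n, residual_mad = mean(abs(pred - age)),
              r2 = pearson_r2(pred, age), excluded = sel$excluded)
}
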