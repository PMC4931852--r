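# Frozen model classes and their predict methods.
#
# All predictors operate on beta-values (fractions in [0,1]) and return ages
# in years (never clamped; a negative prediction signals mis-calibration and
# is reported as-is) or percent epithelial cells (clamped into [0,100], with
# the raw value retained for diagnostics).

# coerce prediction input to a samples x probes matrix
as_profile_matrix <- function(newdata, probes) {
  if (inherits(newdata, "beta_matrix")) return(probe_values(newdata, probes))
  if (is.numeric(newdata) && is.null(dim(newdata))) {
    if (is.null(names(newdata))) {
      stop_validation("a numeric profile must be named by probe ID")
    }
    newdata <- matrix(newdata, nrow = 1,
                      dimnames = list("sample", names(newdata)))
  }
  newdata <- as.matrix(newdata)
  if (is.null(rownames(newdata))) {
    rownames(newdata) <- paste0("sample", seq_len(nrow(newdata)))
  }
  out <- matrix(NA_real_, nrow(newdata), length(probes),
                dimnames = list(rownames(newdata), probes))
  hit <- intersect(probes, colnames(newdata))
  out[, hit] <- newdata[, hit]
  out
}

missing_reasons <- function(mat) {
  apply(mat, 1, function(r) {
    miss <- colnames(mat)[is.na(r)]
    if (!length(miss)) "ok"
    else paste0("missing beta at ", paste(miss, collapse = ", "))
  })
}

#' Linear multi-CpG age model
#'
#' An affine map from beta-values to predicted age in years:
#' `age = intercept + sum(coefficients * beta)`.
#'
#' @param intercept intercept in years.
#' @param coefficients named numeric vector of per-probe coefficients in
#'   years per beta-unit; names are probe IDs.
#' @param name model name.
#' @param notes optional character notes (e.g. coefficient provenance).
#' @return object of class `age_model`.
#' @export
age_model <- function(intercept, coefficients, name = "age model",
                      notes = NULL) {
  if (!length(coefficients) || is.null(names(coefficients)) ||
        any(!nzchar(names(coefficients)))) {
    stop_validation("'coefficients' must be a non-empty named vector")
  }
  if (!all(is.finite(c(intercept, coefficients)))) {
    stop_validation("age model coefficients must be finite")
  }
  structure(list(name = name, intercept = as.numeric(intercept),
                 coefficients = coefficients, notes = notes),
            class = "age_model")
}

#' @export
coef.age_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
print.age_model <- function(x, ...) {
  terms <- sprintf("%+.6g b(%s)", x$coefficients, names(x$coefficients))
  cat(sprintf("%s:\n  predicted age [y] = %.6g %s\n",
              x$name, x$intercept, paste(terms, collapse = " ")))
  if (!is.null(x$notes)) cat("  note:", x$notes, "\n")
  invisible(x)
}

#' Predict age with a linear multi-CpG model
#'
#' @param object an [age_model()].
#' @param newdata a [beta_matrix()], a samples x probes matrix/data frame, or
#'   a single named numeric profile.
#' @param ... unused.
#' @return named numeric vector of predicted ages in years. Samples missing a
#'   required beta-value get `NA` with the reason recorded in
#'   `attr(, "reason")`.
#' @examples
#' m <- published_models()$blood3
#' predict(m, c(cg02228185 = 0, cg25809905 = 0, cg17861230_upstream = 0))
#' @export
predict.age_model <- function(object, newdata, ...) {
  mat <- as_profile_matrix(newdata, names(object$coefficients))
  pred <- drop(object$intercept + mat %*% object$coefficients)
  pred <- stats::setNames(as.numeric(pred), rownames(mat))
  attr(pred, "reason") <- missing_reasons(mat)
  pred
}

#' One-CpG age model (inverted regression line)
#'
#' Stores the regression line of beta on age, `beta = beta0 + slope * age`,
#' and predicts by inversion: `age = (beta - beta0) / slope`.
#'
#' @param probe_id the CpG probe ID.
#' @param beta0 beta-value intercept (dimensionless).
#' @param slope beta-units per year; must be non-zero.
#' @param name model name.
#' @return object of class `one_cpg_model`.
#' @export
one_cpg_model <- function(probe_id, beta0, slope, name = "1-CpG model") {
  if (!is.finite(slope) || slope == 0) {
    stop_validation("one-CpG model slope must be non-zero")
  }
  structure(list(name = name, probe_id = probe_id,
                 beta0 = as.numeric(beta0), slope = as.numeric(slope)),
            class = "one_cpg_model")
}

#' @export
coef.one_cpg_model <- function(object, ...) {
  c(beta0 = object$beta0, slope = object$slope)
}

#' @export
print.one_cpg_model <- function(x, ...) {
  cat(sprintf("%s:\n  predicted age [y] = (b(%s) - %.6g) / %.6g\n",
              x$name, x$probe_id, x$beta0, x$slope))
  invisible(x)
}

#' @rdname one_cpg_model
#' @param object a `one_cpg_model`.
#' @param newdata as for [predict.age_model()].
#' @param ... unused.
#' @export
predict.one_cpg_model <- function(object, newdata, ...) {
  mat <- as_profile_matrix(newdata, object$probe_id)
  pred <- stats::setNames((mat[, 1] - object$beta0) / object$slope,
                          rownames(mat))
  attr(pred, "reason") <- missing_reasons(mat)
  pred
}

#' Two-CpG cell signature (percent buccal epithelial cells)
#'
#' Combines two per-CpG linear calibrations, each mapping a beta-value to a
#' percentage of epithelial cells, by a weighted average (default equal
#' weights). Predictions are clamped into \[0,100\] -- the signature output is
#' a physical cell fraction -- with the raw, pre-clamp value retained.
#'
#' @param probe_delta,probe_epsilon probe IDs of the two marker CpGs.
#' @param cal_delta,cal_epsilon numeric `c(slope, intercept)` calibrations
#'   mapping each beta-value to percent epithelial cells.
#' @param weights two non-negative weights summing to 1.
#' @param name model name.
#' @param notes optional provenance notes.
#' @return object of class `cell_signature`.
#' @export
cell_signature <- function(probe_delta, probe_epsilon, cal_delta, cal_epsilon,
                           weights = c(0.5, 0.5), name = "cell signature",
                           notes = NULL) {
  if (length(weights) != 2 || abs(sum(weights) - 1) > 1e-12) {
    stop_validation("signature weights must be two values summing to 1")
  }
  if (!all(is.finite(c(cal_delta, cal_epsilon)))) {
    stop_validation("signature calibrations must be finite")
  }
  structure(list(name = name,
                 probe_delta = probe_delta, probe_epsilon = probe_epsilon,
                 cal_delta = c(slope = unname(cal_delta[1]),
                               intercept = unname(cal_delta[2])),
                 cal_epsilon = c(slope = unname(cal_epsilon[1]),
                                 intercept = unname(cal_epsilon[2])),
                 weights = weights, notes = notes),
            class = "cell_signature")
}

#' @export
print.cell_signature <- function(x, ...) {
  cat(sprintf(
    "%s:\n  %% epithelial cells = %.3g (%.6g b(%s) %+.6g) + %.3g (%.6g b(%s) %+.6g)\n",
    x$name, x$weights[1], x$cal_delta["slope"], x$probe_delta,
    x$cal_delta["intercept"], x$weights[2], x$cal_epsilon["slope"],
    x$probe_epsilon, x$cal_epsilon["intercept"]))
  invisible(x)
}

#' Predict the percentage of buccal epithelial cells
#'
#' @param object a [cell_signature()].
#' @param newdata as for [predict.age_model()].
#' @param ... unused.
#' @return named numeric vector of percentages clamped into \[0,100\];
#'   `attr(, "raw")` carries the pre-clamp values and `attr(, "reason")` the
#'   status per sample.
#' @examples
#' sig <- published_models()$signature
#' predict(sig, c(cg07380416 = 0, cg20837735 = 0))  # 45.23 %
#' @export
predict.cell_signature <- function(object, newdata, ...) {
  mat <- as_profile_matrix(newdata, c(object$probe_delta, object$probe_epsilon))
  raw <- object$weights[1] *
    (object$cal_delta["slope"] * mat[, 1] + object$cal_delta["intercept"]) +
    object$weights[2] *
    (object$cal_epsilon["slope"] * mat[, 2] + object$cal_epsilon["intercept"])
  raw <- stats::setNames(as.numeric(raw), rownames(mat))
  out <- pmin(pmax(raw, 0), 100)
  attr(out, "raw") <- raw
  attr(out, "reason") <- missing_reasons(mat)
  out
}

#' Mixture age model (cell composition-weighted)
#'
#' Couples a leukocyte (blood) age model and a buccal-epithelial age model
#' through a [cell_signature()]: with estimated percent epithelial cells
#' `B`, the prediction is
#' `(1 - B/100) * blood(betas) + (B/100) * epithelial(betas)`.
#'
#' @param blood,epithelial [age_model()]s over the same probe set.
#' @param signature a [cell_signature()].
#' @param name model name.
#' @param notes optional provenance notes.
#' @return object of class `mixture_age_model`.
#' @export
mixture_age_model <- function(blood, epithelial, signature,
                              name = "mixture age model", notes = NULL) {
  stopifnot(inherits(blood, "age_model"), inherits(epithelial, "age_model"),
            inherits(signature, "cell_signature"))
  if (!setequal(names(blood$coefficients), names(epithelial$coefficients))) {
    stop_validation("blood and epithelial sub-models must share one probe set")
  }
  structure(list(name = name, blood = blood, epithelial = epithelial,
                 signature = signature, notes = notes),
            class = "mixture_age_model")
}

#' @export
print.mixture_age_model <- function(x, ...) {
  cat(sprintf("%s: (1 - B/100) * [blood] + (B/100) * [epithelial]\n", x$name))
  print(x$blood); print(x$epithelial); print(x$signature)
  invisible(x)
}

#' @export
coef.mixture_age_model <- function(object, ...) {
  list(blood = coef(object$blood), epithelial = coef(object$epithelial),
       signature = c(object$signature$cal_delta, object$signature$cal_epsilon))
}

#' Predict age with a mixture model
#'
#' @param object a [mixture_age_model()].
#' @param newdata as for [predict.age_model()].
#' @param fixed_fraction optional percent epithelial cells in \[0,100\] to use
#'   for every sample instead of the signature estimate.
#' @param ... unused.
#' @return data frame with columns `age` (years) and `fraction` (the percent
#'   epithelial cells used); rownames are sample IDs. `attr(, "reason")`
#'   records per-sample status.
#' @examples
#' m <- published_models()$mix5
#' p0 <- c(cg02228185 = 0, cg25809905 = 0, cg17861230_upstream = 0)
#' predict(m, p0, fixed_fraction = 0)$age    # 38.0 (blood branch)
#' predict(m, p0, fixed_fraction = 100)$age  # 2.6 (epithelial branch)
#' @export
predict.mixture_age_model <- function(object, newdata, fixed_fraction = NULL,
                                      ...) {
  probes <- names(object$blood$coefficients)
  mat <- as_profile_matrix(newdata, probes)
  if (is.null(fixed_fraction)) {
    frac <- predict(object$signature, newdata)
    reason_sig <- attr(frac, "reason")
    frac <- as.numeric(frac)
  } else {
    if (fixed_fraction < 0 || fixed_fraction > 100) {
      stop_validation("fixed_fraction must be in [0,100]")
    }
    frac <- rep(fixed_fraction, nrow(mat))
    reason_sig <- rep("ok", nrow(mat))
  }
  blood <- as.numeric(predict(object$blood, newdata))
  epith <- as.numeric(predict(object$epithelial, newdata))
  w <- frac / 100
  age <- (1 - w) * blood + w * epith
  reason <- missing_reasons(mat)
  reason <- ifelse(reason == "ok" & reason_sig != "ok", reason_sig, reason)
  age[reason != "ok"] <- NA_real_
  frac[reason_sig != "ok"] <- NA_real_
  if (any(!is.na(age) & age < 0)) {
    warning("negative predicted age(s) reported as-is", call. = FALSE)
  }
  out <- data.frame(age = age, fraction = frac,
                    row.names = rownames(mat))
  attr(out, "reason") <- stats::setNames(reason, rownames(mat))
  out
}

#' The five frozen published predictors
#'
#' Returns the published models with their printed coefficients:
#' \describe{
#'   \item{`blood3`}{3-CpG blood model: `38.0 - 26.4 a - 23.7 b + 164.7 g`
#'     (a = cg02228185/ASPA, b = cg25809905/ITGA2B, g = PDE4C CpG upstream of
#'     cg17861230), trained on 82 blood samples.}
#'   \item{`swab3`}{3-CpG swab model, retrained on 55 buccal swabs:
#'     `32.69 - 8.42 a - 47.38 b + 183.25 g`.}
#'   \item{`swab1`}{1-CpG swab model: `(g - 0.0648) / 0.0046`.}
#'   \item{`signature`}{Buccal-Cell-Signature, percent epithelial cells:
#'     `(99.8 d + 1.92)/2 + (-98.12 e + 88.54)/2`
#'     (d = cg07380416/CD6, e = cg20837735/SERPINB5).}
#'   \item{`mix5`}{5-CpG mixture model: blood branch as `blood3`, epithelial
#'     branch `2.6 - 11.0 a - 15.6 b + 181.7 g`, weighted by the signature.}
#' }
#'
#' Where the source prints a coefficient at two precisions, the more precise
#' printing is stored (swab intercept 32.69; signature constants
#' 99.8/1.92/-98.12/88.54) and the discrepancy is noted in the model's
#' `notes` field. Coefficients are stored at printed precision, never
#' re-derived.
#'
#' @param registry a [cpg_registry()]; pass `cpg_registry(array_gamma = TRUE)`
#'   to key the gamma CpG by its on-array neighbour.
#' @return named list with elements `blood3`, `swab3`, `swab1`, `signature`,
#'   `mix5`.
#' @export
published_models <- function(registry = cpg_registry()) {
  p <- stats::setNames(registry$probe_id, registry$symbol)
  blood3 <- age_model(
    38.0, stats::setNames(c(-26.4, -23.7, 164.7), p[c("alpha", "beta", "gamma")]),
    name = "3-CpG-blood-model")
  swab3 <- age_model(
    32.69, stats::setNames(c(-8.42, -47.38, 183.25), p[c("alpha", "beta", "gamma")]),
    name = "3-CpG-swab-model",
    notes = "intercept printed as 32.69 and 32.70; higher precision adopted")
  swab1 <- one_cpg_model(p[["gamma"]], beta0 = 0.0648, slope = 0.0046,
                         name = "1-CpG-swab-model")
  signature <- cell_signature(
    p[["delta"]], p[["epsilon"]],
    cal_delta = c(99.8, 1.92), cal_epsilon = c(-98.12, 88.54),
    name = "Buccal-Cell-Signature",
    notes = "constants also printed as 1.9/-98.1/88.5; higher precision adopted")
  epithelial <- age_model(
    2.6, stats::setNames(c(-11.0, -15.6, 181.7), p[c("alpha", "beta", "gamma")]),
    name = "buccal-epithelial sub-model")
  mix5 <- mixture_age_model(blood3, epithelial, signature,
                            name = "5-CpG-swab-model")
  list(blood3 = blood3, swab3 = swab3, swab1 = swab1,
       signature = signature, mix5 = mix5)
}

# ---- flat key-value model serialization (round-trip exact) --------------

fmt17 <- function(x) sprintf("%.17g", x)

serialize_model_lines <- function(model, prefix = "") {
  if (inherits(model, "age_model")) {
    c(paste0(prefix, "type\tage_model"),
      paste0(prefix, "name\t", model$name),
      paste0(prefix, "intercept\t", fmt17(model$intercept)),
      paste0(prefix, "coef:", names(model$coefficients), "\t",
             fmt17(model$coefficients)))
  } else if (inherits(model, "one_cpg_model")) {
    c(paste0(prefix, "type\tone_cpg_model"),
      paste0(prefix, "name\t", model$name),
      paste0(prefix, "probe\t", model$probe_id),
      paste0(prefix, "beta0\t", fmt17(model$beta0)),
      paste0(prefix, "slope\t", fmt17(model$slope)))
  } else if (inherits(model, "cell_signature")) {
    c(paste0(prefix, "type\tcell_signature"),
      paste0(prefix, "name\t", model$name),
      paste0(prefix, "probe_delta\t", model$probe_delta),
      paste0(prefix, "probe_epsilon\t", model$probe_epsilon),
      paste0(prefix, "cal_delta\t", paste(fmt17(model$cal_delta), collapse = " ")),
      paste0(prefix, "cal_epsilon\t", paste(fmt17(model$cal_epsilon), collapse = " ")),
      paste0(prefix, "weights\t", paste(fmt17(model$weights), collapse = " ")))
  } else if (inherits(model, "mixture_age_model")) {
    c(paste0(prefix, "type\tmixture_age_model"),
      paste0(prefix, "name\t", model$name),
      serialize_model_lines(model$blood, paste0(prefix, "blood.")),
      serialize_model_lines(model$epithelial, paste0(prefix, "epithelial.")),
      serialize_model_lines(model$signature, paste0(prefix, "signature.")))
  } else stop_validation("cannot serialize object of class ",
                         paste(class(model), collapse = "/"))
}

#' Write / read a model as flat key-value text
#'
#' Models are stored as tab-separated `key<TAB>value` lines with numeric
#' values at full double precision, so write-then-read is exact.
#'
#' @param model an [age_model()], [one_cpg_model()], [cell_signature()] or
#'   [mixture_age_model()].
#' @param path file path.
#' @return `write_model` returns `path` invisibly; `read_model` returns the
#'   reconstructed model object.
#' @export
write_model <- function(model, path) {
  writeLines(serialize_model_lines(model), path)
  invisible(path)
}

parse_model_fields <- function(fields) {
  type <- fields[["type"]]
  num <- function(k) as.numeric(strsplit(fields[[k]], " ", fixed = TRUE)[[1]])
  if (type == "age_model") {
    ck <- grep("^coef:", names(fields), value = TRUE)
    age_model(num("intercept"),
              stats::setNames(vapply(ck, num, numeric(1)), sub("^coef:", "", ck)),
              name = fields[["name"]])
  } else if (type == "one_cpg_model") {
    one_cpg_model(fields[["probe"]], num("beta0"), num("slope"),
                  name = fields[["name"]])
  } else if (type == "cell_signature") {
    cell_signature(fields[["probe_delta"]], fields[["probe_epsilon"]],
                   num("cal_delta"), num("cal_epsilon"),
                   weights = num("weights"), name = fields[["name"]])
  } else if (type == "mixture_age_model") {
    sub_model <- function(pfx) {
      k <- grep(paste0("^", pfx, "\\."), names(fields), value = TRUE)
      f <- fields[k]
      names(f) <- sub(paste0("^", pfx, "\\."), "", k)
      parse_model_fields(f)
    }
    mixture_age_model(sub_model("blood"), sub_model("epithelial"),
                      sub_model("signature"), name = fields[["name"]])
  } else stop_validation("unknown model type in file: ", type)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\t", fixed = TRUE)
  fields <- stats::setNames(vapply(kv, `[`, character(1), 2),
                            vapply(kv, `[`, character(1), 1))
  parse_model_fields(as.list(fields))
}
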