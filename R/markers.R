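#' Screen CpGs for cell-type specificity between two tissues
#'
#' Reproduces the marker-selection procedure behind the two cell-type-specific
#' CpGs of the Buccal-Cell-Signature. For every probe shared by the two
#' tissue matrices and the age reference, three criteria are evaluated:
#' (i) a large difference in mean beta-value between the tissues, (ii) low
#' variance within each tissue (sum of the two n-1 variances), and (iii) no
#' correlation with chronological age in the reference data set
#' (`|Pearson r| < age_corr_max`; an anti-correlation is equally
#' disqualifying). Probes passing both the age veto and the low-variance
#' cutoff are ranked by absolute mean difference (descending), ties broken
#' by smaller variance sum, then lexicographic probe ID.
#'
#' @param tissue_a,tissue_b [beta_matrix()]s of the two pure tissues (e.g.
#'   buccal swabs and whole blood).
#' @param age_reference a [beta_matrix()] with chronological ages for at
#'   least 3 samples, used for the age-correlation veto.
#' @param age_corr_max veto threshold on `|r|` (default 0.05).
#' @param var_sum_quantile quantile of the variance sum (over all screened
#'   probes) used as the low-variance cutoff (default 0.10, the lowest
#'   decile); computing it over all probes keeps the candidate set monotone
#'   in `age_corr_max`.
#' @param top_k maximum number of ranked candidates to return (default all).
#' @param max_missing probes missing in more than this fraction of samples in
#'   either tissue are dropped before statistics (default 0.2).
#' @return data frame of ranked candidates (class `marker_screen`) with
#'   columns `probe_id`, `mean_a`, `mean_b`, `abs_delta_mean`, `var_a`,
#'   `var_b`, `var_sum`, `age_corr`, `passes_age_filter`,
#'   `passes_var_filter`, `rank`. The full per-probe table (vetoed probes
#'   included, `rank = NA`) is in `attr(, "screened")`. If every probe is
#'   vetoed an empty table is returned with a warning.
#' @export
screen_markers <- function(tissue_a, tissue_b, age_reference,
                           age_corr_max = 0.05, var_sum_quantile = 0.10,
                           top_k = Inf, max_missing = 0.2) {
  stopifnot(inherits(tissue_a, "beta_matrix"),
            inherits(tissue_b, "beta_matrix"),
            inherits(age_reference, "beta_matrix"))
  shared <- Reduce(intersect, list(colnames(tissue_a$betas),
                                   colnames(tissue_b$betas),
                                   colnames(age_reference$betas)))
  if (!length(shared)) stop_validation("the matrices share no probes")
  ages <- age_reference$samples$age_years
  if (sum(!is.na(ages)) < 3) {
    stop_validation("age reference needs ages for at least 3 samples")
  }
  miss_frac <- function(m) colMeans(is.na(m))
  drop <- miss_frac(tissue_a$betas[, shared, drop = FALSE]) > max_missing |
    miss_frac(tissue_b$betas[, shared, drop = FALSE]) > max_missing
  shared <- shared[!drop]
  if (!length(shared)) stop_validation("no probes left after missingness filter")

  A <- tissue_a$betas[, shared, drop = FALSE]
  B <- tissue_b$betas[, shared, drop = FALSE]
  R <- age_reference$betas[, shared, drop = FALSE]
  age_corr <- vapply(seq_along(shared), function(j) {
    ok <- !is.na(R[, j]) & !is.na(ages)
    if (sum(ok) < 3 || stats::sd(R[ok, j]) == 0) return(NA_real_)
    stats::cor(R[ok, j], ages[ok])
  }, numeric(1))

  tab <- data.frame(
    probe_id = shared,
    mean_a = colMeans(A, na.rm = TRUE),
    mean_b = colMeans(B, na.rm = TRUE),
    var_a = apply(A, 2, stats::var, na.rm = TRUE),
    var_b = apply(B, 2, stats::var, na.rm = TRUE),
    age_corr = age_corr,
    row.names = NULL, stringsAsFactors = FALSE
  )
  tab$abs_delta_mean <- abs(tab$mean_a - tab$mean_b)
  tab$var_sum <- tab$var_a + tab$var_b
  tab$passes_age_filter <- !is.na(tab$age_corr) & abs(tab$age_corr) < age_corr_max
  # the low-variance cutoff is a quantile over all screened probes, so the
  # candidate set is monotone in age_corr_max
  cutoff <- stats::quantile(tab$var_sum, var_sum_quantile, names = FALSE,
                            na.rm = TRUE)
  tab$passes_var_filter <- !is.na(cutoff) & !is.na(tab$var_sum) &
    tab$var_sum <= cutoff
  retained <- tab$passes_age_filter & tab$passes_var_filter
  tab$rank <- NA_integer_
  if (any(retained)) {
    idx <- which(retained)
    ord <- idx[order(-tab$abs_delta_mean[idx], tab$var_sum[idx],
                     tab$probe_id[idx])]
    tab$rank[ord] <- seq_along(ord)
  } else {
    warning("all probes vetoed; returning an empty candidate list",
            call. = FALSE)
  }
  tab <- tab[, c("probe_id", "mean_a", "mean_b", "abs_delta_mean",
                 "var_a", "var_b", "var_sum", "age_corr",
                 "passes_age_filter", "passes_var_filter", "rank")]
  out <- tab[!is.na(tab$rank), , drop = FALSE]
  out <- out[order(out$rank), , drop = FALSE]
  if (is.finite(top_k)) out <- out[seq_len(min(top_k, nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "screened") <- tab
  attr(out, "var_sum_cutoff") <- cutoff
  class(out) <- c("marker_screen", "data.frame")
  out
}

#' @export
print.marker_screen <- function(x, ...) {
  cat(sprintf("marker screen: %d candidate(s) of %d probes screened\n",
              nrow(x), nrow(attr(x, "screened"))))
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  invisible(x)
}

#' Characterize candidate markers across data sets
#'
#' Per candidate probe and data set, the mean and standard deviation of the
#' beta-values -- the cross-tissue portrait used to confirm that a marker is
#' stably hypo-/hypermethylated in each cell type and intermediate in mixed
#' specimens such as saliva.
#'
#' @param probes character vector of probe IDs (or a [screen_markers()]
#'   result, whose `probe_id` column is used).
#' @param datasets named list of [beta_matrix()]s.
#' @return data frame with columns `probe_id`, `dataset`, `mean`, `sd`, `n`;
#'   probes absent from a data set yield `NA` entries, not failures.
#' @export
characterize_markers <- function(probes, datasets) {
  if (inherits(probes, "data.frame")) probes <- probes$probe_id
  if (is.null(names(datasets)) || any(!nzchar(names(datasets)))) {
    stop_validation("'datasets' must be a named list")
  }
  rows <- lapply(names(datasets), function(ds) {
    m <- probe_values(datasets[[ds]], probes)
    data.frame(probe_id = probes, dataset = ds,
               mean = colMeans(m, na.rm = TRUE),
               sd = apply(m, 2, stats::sd, na.rm = TRUE),
               n = colSums(!is.na(m)),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$mean[out$n == 0] <- NA_real_
  out$sd[out$n == 0] <- NA_real_
  out
}
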