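# Shared fixtures and independent oracles, built in code at test time.

# probe IDs of the frozen registry, in alpha..epsilon order
reg_probes <- function() {
  r <- cpg_registry()
  stats::setNames(r$probe_id, r$symbol)
}

# small random beta matrix with optional ages
random_beta_matrix <- function(n, probes, seed, with_ages = FALSE,
                               age_range = c(1, 85)) {
  set.seed(seed)
  b <- matrix(runif(n * length(probes)), n,
              dimnames = list(sprintf("S%02d", seq_len(n)), probes))
  smp <- data.frame(sample_id = rownames(b),
                    age_years = if (with_ages)
                      runif(n, age_range[1], age_range[2]) else NA_real_,
                    stringsAsFactors = FALSE)
  beta_matrix(b, smp)
}

# write a samples-as-rows beta CSV and return its path
write_beta_csv <- function(values, path = tempfile(fileext = ".csv"),
                           sep = ",") {
  header <- paste(c("sample_id", colnames(values)), collapse = sep)
  rows <- vapply(seq_len(nrow(values)), function(i) {
    paste(c(rownames(values)[i],
            ifelse(is.na(values[i, ]), "",
                   format(values[i, ], digits = 15, trim = TRUE))),
          collapse = sep)
  }, character(1))
  writeLines(c(header, rows), path)
  path
}

# independent normal-equations least-squares oracle
ne_oracle <- function(D, y) drop(solve(crossprod(D), crossprod(D, y)))

# independent brute-force re-implementation of the three marker-screen
# criteria (means/variance filter/age veto, then the ranking rule)
oracle_screen <- function(A, B, R, ages, age_corr_max = 0.05,
                          var_sum_quantile = 0.10) {
  probes <- intersect(intersect(colnames(A), colnames(B)), colnames(R))
  stats <- lapply(probes, function(p) {
    r <- suppressWarnings(stats::cor(R[, p], ages))
    list(probe = p,
         dm = abs(mean(A[, p]) - mean(B[, p])),
         vs = stats::var(A[, p]) + stats::var(B[, p]),
         r = r)
  })
  dm <- vapply(stats, `[[`, numeric(1), "dm")
  vs <- vapply(stats, `[[`, numeric(1), "vs")
  r <- vapply(stats, `[[`, numeric(1), "r")
  pass_age <- !is.na(r) & abs(r) < age_corr_max
  cutoff <- stats::quantile(vs, var_sum_quantile, names = FALSE)
  keep <- pass_age & vs <= cutoff
  kp <- probes[keep]
  kp[order(-dm[keep], vs[keep], kp)]
}

# per-sample absolute errors of a predictor on a cohort
abs_errors <- function(pred, cohort) {
  abs(pred - cohort$samples$age_years)
}
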