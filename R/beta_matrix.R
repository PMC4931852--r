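#' Construct a beta-value matrix with per-sample metadata
#'
#' The central data container: a samples x probes matrix of DNA methylation
#' beta-values (fractions in \[0,1\], `NA` for missing measurements) plus a
#' per-sample metadata table (chronological age in years and arbitrary
#' label columns such as cohort, sex or counted cell fractions).
#'
#' @param betas numeric matrix, samples in rows, probes in columns; rownames
#'   are sample IDs and colnames are probe IDs. Values in \[0,1\] or `NA`.
#' @param samples optional data frame of per-sample metadata with a
#'   `sample_id` column matching the rownames of `betas`; an `age_years`
#'   column, if present, must be non-negative. Defaults to a skeleton with
#'   missing ages.
#' @return An object of class `beta_matrix`.
#' @seealso [read_beta_matrix()], [join_metadata()]
#' @export
beta_matrix <- function(betas, samples = NULL) {
  betas <- as.matrix(betas)
  storage.mode(betas) <- "double"
  if (is.null(rownames(betas)) || is.null(colnames(betas))) {
    stop_validation("'betas' needs sample IDs as rownames and probe IDs as colnames")
  }
  if (anyDuplicated(rownames(betas))) {
    stop_validation("duplicate sample ID(s): ",
                    paste(unique(rownames(betas)[duplicated(rownames(betas))]),
                          collapse = ", "))
  }
  if (anyDuplicated(colnames(betas))) {
    stop_validation("duplicate probe ID(s)")
  }
  bad <- which(!is.na(betas) & (betas < 0 | betas > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    v <- betas[bad[1, , drop = FALSE]]
    hint <- if (v > 1 && v <= 100)
      " (values in (1,100] look percent-scaled; use percent = TRUE)" else ""
    stop_validation(sprintf(
      "beta-value %.4g outside [0,1] at sample '%s', probe '%s'%s",
      v, rownames(betas)[bad[1, 1]], colnames(betas)[bad[1, 2]], hint))
  }
  if (is.null(samples)) {
    samples <- data.frame(sample_id = rownames(betas),
                          age_years = NA_real_,
                          stringsAsFactors = FALSE)
  }
  if (!"sample_id" %in% names(samples)) {
    stop_validation("'samples' must contain a sample_id column")
  }
  samples$sample_id <- as.character(samples$sample_id)
  if (!identical(samples$sample_id, rownames(betas))) {
    m <- match(rownames(betas), samples$sample_id)
    if (anyNA(m)) stop_validation("'samples' does not cover all sample IDs")
    samples <- samples[m, , drop = FALSE]
  }
  if (!"age_years" %in% names(samples)) samples$age_years <- NA_real_
  if (any(!is.na(samples$age_years) & samples$age_years < 0)) {
    stop_validation("negative age_years in sample metadata")
  }
  rownames(samples) <- NULL
  structure(list(betas = betas, samples = samples), class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d samples x %d probes\n",
              nrow(x$betas), ncol(x$betas)))
  n_age <- sum(!is.na(x$samples$age_years))
  cat(sprintf("  ages available for %d sample(s); metadata columns: %s\n",
              n_age, paste(setdiff(names(x$samples), "sample_id"),
                           collapse = ", ")))
  if (anyNA(x$betas)) {
    cat(sprintf("  %d missing beta-value(s)\n", sum(is.na(x$betas))))
  }
  invisible(x)
}

#' @export
dim.beta_matrix <- function(x) dim(x$betas)

# Subset a beta_matrix by sample and/or probe
#' @export
`[.beta_matrix` <- function(x, i, j, ...) {
  b <- x$betas[i, j, drop = FALSE]
  s <- x$samples[match(rownames(b), x$samples$sample_id), , drop = FALSE]
  beta_matrix(b, s)
}

n_samples <- function(x) nrow(x$betas)

# ---- delimited text I/O ------------------------------------------------

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  counts <- vapply(c("\t", ",", ";"),
                   function(s) lengths(regmatches(header, gregexpr(s, header, fixed = TRUE))),
                   integer(1))
  if (all(counts == 0)) stop_validation(
    "could not detect a delimiter (tab, comma or semicolon) in ", path)
  c("\t", ",", ";")[which.max(counts)]
}

read_delim_table <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- detect_sep(path)
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "", na.strings = c("", "NA"))
}

#' Read a beta-value matrix from delimited text
#'
#' Reads a CSV/TSV table (delimiter auto-detected among tab, comma and
#' semicolon; decimal point only) whose first column holds sample IDs (or
#' probe IDs, with `orientation = "probes_as_rows"`) and whose header holds
#' the other dimension. Values must be fractions in \[0,1\]; empty cells
#' become missing values. Percent-scale exports (0-100, common for
#' pyrosequencing software) are only accepted behind `percent = TRUE`, which
#' divides by 100 -- out-of-range values otherwise produce an error naming
#' the offending cell, with a hint when the file looks percent-scaled.
#'
#' @param path file path.
#' @param orientation `"samples_as_rows"` (default) or `"probes_as_rows"`.
#' @param percent if `TRUE`, values are divided by 100 before validation.
#' @param sep optional delimiter, overriding auto-detection.
#' @return A [beta_matrix()] (metadata skeleton only; see [join_metadata()]).
#' @export
read_beta_matrix <- function(path,
                             orientation = c("samples_as_rows", "probes_as_rows"),
                             percent = FALSE, sep = NULL) {
  orientation <- match.arg(orientation)
  tab <- read_delim_table(path, sep)
  if (ncol(tab) < 2) stop_validation("no data columns found in ", path)
  ids <- as.character(tab[[1]])
  num <- as.matrix(tab[, -1, drop = FALSE])
  if (is.character(num)) {
    parsed <- suppressWarnings(array(as.numeric(num), dim = dim(num),
                                     dimnames = dimnames(num)))
    bad <- !is.na(num) & is.na(parsed)
    if (any(bad)) {
      idx <- which(bad, arr.ind = TRUE)[1, ]
      stop_validation(sprintf("non-numeric cell '%s' at row %d, column '%s'",
                              num[idx[1], idx[2]], idx[1],
                              colnames(num)[idx[2]]))
    }
    num <- parsed
  }
  storage.mode(num) <- "double"
  rownames(num) <- ids
  if (percent) num <- num / 100
  if (orientation == "probes_as_rows") num <- t(num)
  beta_matrix(num)
}

#' Write a beta-value matrix to delimited text
#'
#' Writes samples as rows with a `sample_id` first column at full double
#' precision, so that write-then-read reproduces the matrix.
#'
#' @param x a [beta_matrix()].
#' @param path output file path.
#' @param sep field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "beta_matrix"))
  chr <- format(x$betas, digits = 15, trim = TRUE, scientific = FALSE)
  chr[is.na(x$betas)] <- ""
  out <- cbind(sample_id = rownames(x$betas), chr)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a sample sheet
#'
#' A sample sheet is a delimited table with a mandatory `sample_id` column,
#' an optional `age` (or `age_years`) column of non-negative ages in years,
#' and arbitrary additional label columns (cohort, sex, smoking, ...).
#'
#' @param path file path.
#' @param sep optional delimiter, overriding auto-detection.
#' @return data frame with columns `sample_id`, `age_years` (NA when the file
#'   has no age column) and any label columns.
#' @export
read_sample_sheet <- function(path, sep = NULL) {
  tab <- read_delim_table(path, sep)
  if (!"sample_id" %in% names(tab)) {
    stop_validation("sample sheet lacks a 'sample_id' column: ", path)
  }
  tab$sample_id <- as.character(tab$sample_id)
  age_col <- intersect(c("age_years", "age"), names(tab))[1]
  if (!is.na(age_col)) {
    age <- suppressWarnings(as.numeric(tab[[age_col]]))
    if (any(!is.na(tab[[age_col]]) & is.na(age))) {
      stop_validation("non-numeric age in sample sheet")
    }
    if (any(!is.na(age) & age < 0)) {
      stop_validation("negative age in sample sheet: ",
                      paste(age[!is.na(age) & age < 0], collapse = ", "))
    }
    tab[[age_col]] <- NULL
    tab$age_years <- age
  } else {
    tab$age_years <- NA_real_
  }
  tab[, c("sample_id", "age_years",
          setdiff(names(tab), c("sample_id", "age_years"))), drop = FALSE]
}

#' Read a cytology table
#'
#' Counted cell compositions from stained smears: columns `sample_id`,
#' `pct_epithelial` (percent of buccal epithelial cells, in \[0,100\]) and
#' optionally `n_cells_counted`.
#'
#' @param path file path.
#' @param sep optional delimiter, overriding auto-detection.
#' @return data frame with columns `sample_id`, `pct_epithelial`,
#'   `n_cells_counted`.
#' @export
read_cytology <- function(path, sep = NULL) {
  tab <- read_delim_table(path, sep)
  need <- c("sample_id", "pct_epithelial")
  if (!all(need %in% names(tab))) {
    stop_validation("cytology table needs columns: ", paste(need, collapse = ", "))
  }
  tab$sample_id <- as.character(tab$sample_id)
  tab$pct_epithelial <- as.numeric(tab$pct_epithelial)
  if (any(is.na(tab$pct_epithelial) | tab$pct_epithelial < 0 |
            tab$pct_epithelial > 100)) {
    stop_validation("pct_epithelial must be in [0,100]")
  }
  if (!"n_cells_counted" %in% names(tab)) tab$n_cells_counted <- NA_integer_
  tab[, c("sample_id", "pct_epithelial", "n_cells_counted")]
}

#' Attach sample-sheet and cytology metadata to a beta matrix
#'
#' Joins metadata by `sample_id`. Sheet entries without a matching sample are
#' reported as warnings, never failures. Counted epithelial fractions are
#' attached as the label column `pct_epithelial_counted`. The join is
#' idempotent: applying the same sheet twice equals applying it once.
#'
#' @param x a [beta_matrix()].
#' @param sheet optional data frame as returned by [read_sample_sheet()].
#' @param cytology optional data frame as returned by [read_cytology()].
#' @return the annotated [beta_matrix()].
#' @export
join_metadata <- function(x, sheet = NULL, cytology = NULL) {
  stopifnot(inherits(x, "beta_matrix"))
  smp <- x$samples
  if (!is.null(sheet) && nrow(sheet)) {
    if (!"sample_id" %in% names(sheet)) {
      stop_validation("sheet lacks a 'sample_id' column")
    }
    unmatched <- setdiff(sheet$sample_id, smp$sample_id)
    if (length(unmatched)) {
      warning(sprintf("%d sheet entr%s without a matching sample: %s",
                      length(unmatched),
                      if (length(unmatched) == 1) "y" else "ies",
                      paste(utils::head(unmatched, 5), collapse = ", ")),
              call. = FALSE)
    }
    m <- match(smp$sample_id, sheet$sample_id)
    for (col in setdiff(names(sheet), "sample_id")) {
      val <- sheet[[col]][m]
      if (col %in% names(smp)) {
        hit <- !is.na(m)
        smp[[col]][hit] <- val[hit]
      } else {
        smp[[col]] <- val
      }
    }
    if (any(!is.na(smp$age_years) & smp$age_years < 0)) {
      stop_validation("negative age after join")
    }
  }
  if (!is.null(cytology) && nrow(cytology)) {
    m <- match(smp$sample_id, cytology$sample_id)
    val <- cytology$pct_epithelial[m]
    if ("pct_epithelial_counted" %in% names(smp)) {
      hit <- !is.na(m)
      smp$pct_epithelial_counted[hit] <- val[hit]
    } else {
      smp$pct_epithelial_counted <- val
    }
  }
  x$samples <- smp
  x
}

# beta values for selected probes as a samples x probes matrix; probes that
# are entirely absent from the matrix come back as NA columns
probe_values <- function(x, probes) {
  out <- matrix(NA_real_, nrow = nrow(x$betas), ncol = length(probes),
                dimnames = list(rownames(x$betas), probes))
  hit <- intersect(probes, colnames(x$betas))
  out[, hit] <- x$betas[, hit]
  out
}
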