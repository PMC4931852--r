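#' CpG registry: the five probes used by the published models
#'
#' Binds the five model symbols to Illumina-style probe IDs and gene names:
#' alpha (ASPA, cg02228185), beta (ITGA2B, cg25809905), gamma (PDE4C, a CpG
#' upstream of cg17861230 assayed by pyrosequencing and not represented on
#' Illumina arrays), delta (CD6, cg07380416) and epsilon (SERPINB5,
#' cg20837735). The two last probes are the cell-type-specific markers of the
#' Buccal-Cell-Signature; the first three are age-associated.
#'
#' @param array_gamma if `TRUE`, the gamma entry uses the array alias
#'   `"cg17861230"` (the neighbouring on-array CpG) instead of the assayed
#'   upstream site `"cg17861230_upstream"`. Use this when working with
#'   Illumina array matrices.
#' @param overrides optional named character vector mapping symbols
#'   (`"alpha"`, ..., `"epsilon"`) to replacement probe IDs.
#' @param config optional path to a YAML file with a top-level `probe_ids`
#'   mapping of symbols to probe IDs (requires the `yaml` package).
#' @return A data frame with columns `symbol`, `probe_id`, `gene`; exactly
#'   five rows, unique symbols and probe IDs.
#' @examples
#' cpg_registry()
#' cpg_registry(array_gamma = TRUE)$probe_id
#' @export
cpg_registry <- function(array_gamma = FALSE, overrides = NULL,
                         config = NULL) {
  reg <- data.frame(
    symbol   = c("alpha", "beta", "gamma", "delta", "epsilon"),
    probe_id = c("cg02228185", "cg25809905",
                 if (array_gamma) "cg17861230" else "cg17861230_upstream",
                 "cg07380416", "cg20837735"),
    gene     = c("ASPA", "ITGA2B", "PDE4C", "CD6", "SERPINB5"),
    stringsAsFactors = FALSE
  )
  if (!is.null(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_validation("reading a registry config requires the 'yaml' package")
    }
    cfg <- yaml::read_yaml(config)
    if (!is.null(cfg$probe_ids)) {
      overrides <- c(unlist(cfg$probe_ids), overrides)
      overrides <- overrides[!duplicated(names(overrides))]
    }
  }
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), reg$symbol)
    if (length(bad)) {
      stop_validation("unknown registry symbol(s): ", paste(bad, collapse = ", "))
    }
    reg$probe_id[match(names(overrides), reg$symbol)] <-
      unname(as.character(overrides))
  }
  if (anyDuplicated(reg$probe_id)) {
    stop_validation("registry probe IDs must be unique")
  }
  # the epsilon probe is printed once without its "cg" prefix in the source
  # literature; the prefixed form is canonical here
  attr(reg, "gamma_alias") <- "cg17861230"
  reg
}
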