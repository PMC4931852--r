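# Synthetic cohorts with the two-cell-type mixture structure the method
# assumes: buccal epithelial cells and leukocytes with opposing methylation
# at the marker CpGs, tissue-specific linear age trajectories at the age
# CpGs, compositional mixing, and additive measurement noise on the beta
# scale.

# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Describe one cell type's methylation profile
#'
#' A cell type is characterized by constant baselines at cell-type marker
#' CpGs and linear age trajectories `beta(age) = intercept + slope * age` at
#' age-associated CpGs. A per-probe biological standard deviation adds
#' inter-individual variation beyond measurement noise (random CpGs vary
#' between donors; good cell-type markers are chosen for stability, so
#' marker probes default to 0).
#'
#' @param name cell type name.
#' @param marker_baselines named numeric vector of constant beta baselines.
#' @param age_cpg_params data frame with columns `probe_id`, `intercept`,
#'   `slope` (beta-units per year).
#' @param biological_sd single value or named vector of per-probe
#'   inter-individual standard deviations (beta-units).
#' @return object of class `cell_type_spec`.
#' @export
cell_type_spec <- function(name, marker_baselines = numeric(0),
                           age_cpg_params = NULL, biological_sd = 0) {
  tab <- data.frame(probe_id = character(0), intercept = numeric(0),
                    slope = numeric(0), stringsAsFactors = FALSE)
  if (length(marker_baselines)) {
    if (is.null(names(marker_baselines))) {
      stop_validation("'marker_baselines' must be named by probe ID")
    }
    if (any(marker_baselines < 0 | marker_baselines > 1)) {
      stop_validation("marker baselines must be beta-values in [0,1]")
    }
    tab <- rbind(tab, data.frame(probe_id = names(marker_baselines),
                                 intercept = unname(marker_baselines),
                                 slope = 0, stringsAsFactors = FALSE))
  }
  if (!is.null(age_cpg_params)) {
    stopifnot(all(c("probe_id", "intercept", "slope") %in% names(age_cpg_params)))
    tab <- rbind(tab, age_cpg_params[, c("probe_id", "intercept", "slope")])
  }
  if (anyDuplicated(tab$probe_id)) stop_validation("duplicate probe IDs in spec")
  if (!all(is.finite(tab$intercept)) || !all(is.finite(tab$slope))) {
    stop_validation("cell type parameters must be finite")
  }
  bio <- rep(0, nrow(tab))
  if (length(biological_sd) == 1 && is.null(names(biological_sd))) {
    bio <- rep(biological_sd, nrow(tab))
  } else if (length(biological_sd)) {
    m <- match(tab$probe_id, names(biological_sd))
    bio[!is.na(m)] <- biological_sd[m[!is.na(m)]]
  }
  tab$bio_sd <- bio
  structure(list(name = name, params = tab), class = "cell_type_spec")
}

#' @export
print.cell_type_spec <- function(x, ...) {
  cat(sprintf("cell_type_spec '%s' (%d probes, %d age-linear)\n",
              x$name, nrow(x$params), sum(x$params$slope != 0)))
  invisible(x)
}

# beta means of one cell type at given ages: ages x probes matrix
spec_means <- function(spec, ages) {
  outer(ages, spec$params$slope) +
    matrix(spec$params$intercept, length(ages), nrow(spec$params),
           byrow = TRUE, dimnames = list(NULL, spec$params$probe_id))
}

#' Cell-type specifications consistent with the frozen published models
#'
#' Constructs a leukocyte and a buccal-epithelial [cell_type_spec()] whose
#' age trajectories are solved in closed form from the frozen model
#' coefficients so that, at zero noise, (1) the 3-CpG blood model is exact on
#' pure leukocytes, (2) the epithelial sub-model of the 5-CpG mixture is
#' exact on pure epithelial cells, and (3) the printed mixture model is exact
#' at every intermediate composition (the cross condition
#' `blood(epithelial betas) + epithelial(leukocyte betas) = 2 * age`).
#' Marker baselines follow the hypo-/hypermethylation pattern of the two
#' published cell-type CpGs: CD6-like probe 0.02 (leukocytes) vs 0.95
#' (epithelium), SERPINB5-like probe 0.92 vs 0.05.
#'
#' The free curve parameters (leukocyte ASPA/ITGA2B trajectories and the
#' epithelial PDE4C trajectory) are fixed at realistic values: beta mid-range
#' over ages 1-85 and slopes of order 1e-3 per year, with the PDE4C slope
#' near the published swab regression slope of 0.0046/y.
#'
#' @param n_decoys number of decoy probes (age-independent, means shared by
#'   both cell types, inter-individual sd `decoy_bio_sd`) to append; decoys
#'   make the spec suitable for marker-screen experiments.
#' @param decoy_seed seed for the decoy means (kept separate from cohort
#'   seeds so several cohorts can share one decoy panel).
#' @param decoy_bio_sd biological standard deviation of decoy probes.
#' @param registry a [cpg_registry()] supplying the probe IDs.
#' @return list with elements `leuko` and `epi`.
#' @export
paperlike_cell_specs <- function(n_decoys = 0, decoy_seed = 1L,
                                 decoy_bio_sd = 0.05,
                                 registry = cpg_registry()) {
  models <- published_models(registry)
  bl <- coef(models$blood3)
  ep <- coef(models$mix5$epithelial)
  probes <- names(models$blood3$coefficients)   # alpha, beta, gamma order
  # free parameters, chosen once for realism (see package vignette): beta
  # mid-range over ages 1-85, slopes O(1e-3)/y, and leukocyte slopes steep
  # enough that the cross-tissue prediction divergence grows with age (the
  # regime in which composition adjustment matters most in older donors)
  aL <- c(0.85, -0.005); bL <- c(0.65, -0.0035); aE <- c(0.75, -0.006)
  # leukocyte gamma curve from exactness of the blood model on leukocytes
  gL <- c(-(bl[1] + bl[2] * aL[1] + bl[3] * bL[1]) / bl[4],
          (1 - bl[2] * aL[2] - bl[3] * bL[2]) / bl[4])
  # cross condition: blood(epi curves) must equal 2*age - epi(leuko curves)
  h <- c(ep[1] + ep[2] * aL[1] + ep[3] * bL[1] + ep[4] * gL[1],
         ep[2] * aL[2] + ep[3] * bL[2] + ep[4] * gL[2])
  g <- c(-h[1], 2 - h[2])
  # epithelial ITGA2B and PDE4C curves solved from (a) exactness of the
  # epithelial sub-model on pure epithelium and (b) the cross condition
  A <- rbind(c(ep[3], ep[4]), c(bl[3], bl[4]))
  ic <- solve(A, c(-(ep[1] + ep[2] * aE[1]), g[1] - bl[1] - bl[2] * aE[1]))
  sl <- solve(A, c(1 - ep[2] * aE[2], g[2] - bl[2] * aE[2]))
  bE <- c(ic[1], sl[1]); gE <- c(ic[2], sl[2])

  d <- registry$probe_id[registry$symbol == "delta"]
  e <- registry$probe_id[registry$symbol == "epsilon"]
  curves <- function(a, b, g) {
    data.frame(probe_id = probes, intercept = c(a[1], b[1], g[1]),
               slope = c(a[2], b[2], g[2]), stringsAsFactors = FALSE)
  }
  mk_l <- stats::setNames(c(0.02, 0.92), c(d, e))
  mk_e <- stats::setNames(c(0.95, 0.05), c(d, e))
  if (n_decoys > 0) {
    dec <- with_seed(decoy_seed,
                     stats::setNames(stats::runif(n_decoys, 0.05, 0.95),
                                     sprintf("decoy_%03d", seq_len(n_decoys))))
    mk_l <- c(mk_l, dec)
    mk_e <- c(mk_e, dec)
  }
  bio <- stats::setNames(rep(decoy_bio_sd, max(n_decoys, 0)),
                         names(mk_l)[-(1:2)])
  list(
    leuko = cell_type_spec("leukocytes", mk_l, curves(aL, bL, gL),
                           biological_sd = bio),
    epi = cell_type_spec("buccal epithelial cells", mk_e, curves(aE, bE, gE),
                         biological_sd = bio)
  )
}

#' Cohort simulation settings
#'
#' Defaults reflect the published study conditions: 55 donors, ages uniform
#' on 1-85 years, epithelial fractions uniform on 24-91 percent, additive
#' measurement noise of 0.02 beta-units.
#'
#' @param n_samples number of samples.
#' @param age_range `c(min, max)` chronological age span in years.
#' @param fraction_range `c(min, max)` percent epithelial cells.
#' @param noise_sd measurement noise standard deviation (beta-units).
#' @param n_decoy_probes decoy probes to add to this cohort (drawn from the
#'   cohort seed; use [paperlike_cell_specs()]'s `n_decoys` when several
#'   cohorts must share one decoy panel).
#' @param seed mandatory integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 55, age_range = c(1, 85),
                        fraction_range = c(24, 91), noise_sd = 0.02,
                        n_decoy_probes = 0, seed) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop_validation("a seed is required for cohort generation")
  }
  if (any(fraction_range < 0) || any(fraction_range > 100) ||
        fraction_range[1] > fraction_range[2]) {
    stop_validation("fraction_range must be within [0,100] and ordered")
  }
  if (noise_sd < 0) stop_validation("noise_sd must be non-negative")
  if (n_samples < 1) stop_validation("n_samples must be positive")
  structure(list(n_samples = as.integer(n_samples), age_range = age_range,
                 fraction_range = fraction_range, noise_sd = noise_sd,
                 n_decoy_probes = as.integer(n_decoy_probes),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# mixing coordinate for marker probes: position between the pure baselines at
# which the frozen signature reads back the latent fraction exactly
signature_inversion <- function(leuko, epi, signature) {
  probes <- c(signature$probe_delta, signature$probe_epsilon)
  if (!all(probes %in% leuko$params$probe_id) ||
        !all(probes %in% epi$params$probe_id)) {
    return(NULL)
  }
  base <- function(spec) {
    stats::setNames(spec$params$intercept, spec$params$probe_id)[probes]
  }
  s0 <- as.numeric(predict(signature, base(leuko)))
  s1 <- as.numeric(predict(signature, base(epi)))
  if (!is.finite(s0) || !is.finite(s1) || abs(s1 - s0) < 1e-8) return(NULL)
  c(s0 = s0, s1 = s1)
}

#' Generate a synthetic mixed-cell cohort
#'
#' Draws ages and latent epithelial fractions uniformly, then emits
#' beta-values as mixtures of the two cell-type profiles plus noise, clipped
#' to \[0,1\]. Age-associated probes (non-zero slope in either cell type) are
#' mixed with weight `fraction/100`, which makes the 5-CpG mixture model
#' exact at zero noise under [paperlike_cell_specs()]. Cell-type marker
#' probes (zero slope) are mixed, when `marker_mixing = "signature_consistent"`
#' and the frozen signature's probes are present, at the interpolation
#' coordinate where the frozen Buccal-Cell-Signature reads back the latent
#' fraction exactly -- the published calibration does not pass through
#' (0 %, 100 %), so this coordinate differs slightly from `fraction/100`;
#' with `"proportional"` every probe is mixed with `fraction/100`.
#'
#' @param leuko,epi [cell_type_spec()]s sharing one probe set.
#' @param spec a [cohort_spec()].
#' @param marker_mixing `"signature_consistent"` (default) or
#'   `"proportional"`.
#' @param noise_model `"gaussian"` (additive, then clipped; default) or
#'   `"beta"` (moment-matched Beta draws, bounded by construction).
#' @param clip_tol construction fails if a noise-free mean beta lies outside
#'   \[0,1\] by more than this tolerance.
#' @return a [beta_matrix()] with `age_years` and the label `true_fraction`
#'   (percent epithelial) filled in; `attr(, "n_clipped")` counts clipped
#'   values.
#' @export
generate_cohort <- function(leuko, epi, spec,
                            marker_mixing = c("signature_consistent",
                                              "proportional"),
                            noise_model = c("gaussian", "beta"),
                            clip_tol = 0.02) {
  stopifnot(inherits(leuko, "cell_type_spec"), inherits(epi, "cell_type_spec"),
            inherits(spec, "cohort_spec"))
  marker_mixing <- match.arg(marker_mixing)
  noise_model <- match.arg(noise_model)
  if (!setequal(leuko$params$probe_id, epi$params$probe_id)) {
    stop_validation("the two cell types must describe the same probes")
  }
  epi$params <- epi$params[match(leuko$params$probe_id, epi$params$probe_id), ]

  inv <- NULL
  if (marker_mixing == "signature_consistent") {
    inv <- signature_inversion(leuko, epi, published_models()$signature)
  }

  with_seed(spec$seed, {
    if (spec$n_decoy_probes > 0) {
      dec <- stats::setNames(
        stats::runif(spec$n_decoy_probes, 0.05, 0.95),
        sprintf("cohort_decoy_%03d", seq_len(spec$n_decoy_probes)))
      add <- data.frame(probe_id = names(dec), intercept = unname(dec),
                        slope = 0, bio_sd = 0.05, stringsAsFactors = FALSE)
      leuko$params <- rbind(leuko$params, add)
      epi$params <- rbind(epi$params, add)
    }
    n <- spec$n_samples
    ages <- stats::runif(n, spec$age_range[1], spec$age_range[2])
    frac <- stats::runif(n, spec$fraction_range[1], spec$fraction_range[2])
    w <- frac / 100
    u <- if (is.null(inv)) w else (frac - inv["s0"]) / (inv["s1"] - inv["s0"])

    ML <- spec_means(leuko, ages)
    ME <- spec_means(epi, ages)
    is_age_probe <- leuko$params$slope != 0 | epi$params$slope != 0
    mix_w <- matrix(rep(ifelse(is_age_probe, 1, 0), each = n), n) * w +
      matrix(rep(ifelse(is_age_probe, 0, 1), each = n), n) * u
    mu <- (1 - mix_w) * ML + mix_w * ME

    # construction-time range check on noise-free means
    lo <- min(mu); hi <- max(mu)
    if (lo < -clip_tol || hi > 1 + clip_tol) {
      hint <- if (!is.null(inv))
        paste0("; fractions outside the signature's representable span ",
               "need marker_mixing = \"proportional\"") else ""
      stop_validation(sprintf(
        "cell type specs imply mean beta outside [0,1] (range %.3f..%.3f)%s",
        lo, hi, hint))
    }

    bio_sd <- pmax(leuko$params$bio_sd, epi$params$bio_sd)
    if (any(bio_sd > 0)) {
      mu <- mu + matrix(stats::rnorm(length(mu)), nrow(mu)) *
        matrix(rep(bio_sd, each = n), n)
    }
    if (noise_model == "gaussian") {
      x <- mu + stats::rnorm(length(mu), 0, spec$noise_sd)
    } else {
      x <- draw_beta_noise(mu, spec$noise_sd)
    }
    n_clipped <- sum(x < 0 | x > 1)
    x <- pmin(pmax(x, 0), 1)
    dimnames(x) <- list(sprintf("S%03d", seq_len(n)), leuko$params$probe_id)

    out <- beta_matrix(x, data.frame(sample_id = rownames(x),
                                     age_years = ages,
                                     true_fraction = frac,
                                     stringsAsFactors = FALSE))
    attr(out, "n_clipped") <- n_clipped
    out
  })
}

# moment-matched Beta noise; falls back to clipped Gaussian where the Beta
# parametrization is undefined (mean at the boundary or variance too large)
draw_beta_noise <- function(mu, sd) {
  x <- mu + stats::rnorm(length(mu), 0, sd)
  if (sd == 0) return(mu)
  ok <- mu > 0 & mu < 1 & sd^2 < mu * (1 - mu)
  phi <- mu[ok] * (1 - mu[ok]) / sd^2 - 1
  x[ok] <- stats::rbeta(sum(ok), mu[ok] * phi, (1 - mu[ok]) * phi)
  x
}

#' Generate a synthetic cytology-calibration set
#'
#' Emulates the small counted-smear calibration experiment: paired
#' beta-profiles and counted percent epithelial cells. The default counted
#' span (37-88 percent epithelial) mirrors leukocyte proportions between 12
#' and 63 percent.
#'
#' @param leuko,epi [cell_type_spec()]s.
#' @param n number of calibration samples (default 11).
#' @param noise_sd beta measurement noise.
#' @param seed mandatory seed.
#' @param fraction_range counted percent-epithelial span.
#' @param counting_sd optional counting noise (percentage points) added to
#'   the recorded counts.
#' @param n_cells_counted nominal cells counted per smear (metadata only).
#' @return list with `data` (a [beta_matrix()] with the label
#'   `pct_epithelial_counted` attached) and `cytology` (a data frame as from
#'   [read_cytology()]).
#' @export
generate_calibration_set <- function(leuko, epi, n = 11, noise_sd = 0.02,
                                     seed, fraction_range = c(37, 88),
                                     counting_sd = 0, n_cells_counted = 328) {
  spec <- cohort_spec(n_samples = n, fraction_range = fraction_range,
                      noise_sd = noise_sd, seed = seed)
  cohort <- generate_cohort(leuko, epi, spec)
  counted <- cohort$samples$true_fraction
  if (counting_sd > 0) {
    counted <- with_seed(spec$seed + 1L,
                         counted + stats::rnorm(n, 0, counting_sd))
    counted <- pmin(pmax(counted, 0), 100)
  }
  cyt <- data.frame(sample_id = cohort$samples$sample_id,
                    pct_epithelial = counted,
                    n_cells_counted = n_cells_counted,
                    stringsAsFactors = FALSE)
  list(data = join_metadata(cohort, cytology = cyt), cytology = cyt)
}
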