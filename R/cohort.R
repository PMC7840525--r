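# Synthetic white-matter cohort with known ground truth.
#
# Stands in for ex vivo EM-derived volume-fraction data (mouse models spanning
# hypo- to hyper-myelination): each sample is a packed population of
# myelinated axons, aggregated to MVF/AVF/EVF, with biomarkers generated under
# the linear law M = (MVF - beta)/alpha so that every downstream calibration
# and evaluation stage is testable without external data. Noise-free by
# default, matching the simulation scenario the evaluation emulates.

#' Configuration for a synthetic white-matter cohort
#'
#' The microscopic g-ratio law is hierarchical: each sample draws a mean
#' microscopic g from a Beta distribution rescaled to `g_range`, and its axons
#' draw their g around that mean from a Beta with concentration
#' `g_concentration` (rescaled to the same range). This makes the cohort span
#' hypo- to hyper-myelination across samples while keeping the within-sample
#' g dispersion small, as in real fibre populations.
#'
#' @param n_samples number of tissue samples (default 200).
#' @param seed integer seed; mandatory, drives all randomness.
#' @param axons_per_sample axons simulated per sample (default 500).
#' @param radius_shape,radius_scale Gamma law for inner radii in um
#'   (default shape 5, scale 0.1: mean 0.5 um).
#' @param g_range support of the microscopic g law (default `c(0.5, 0.95)`).
#' @param g_shape1,g_shape2 Beta shapes of the sample-mean g law (default 5, 5).
#' @param g_concentration within-sample Beta concentration (default 60; larger
#'   means tighter per-sample g dispersion).
#' @param fvf_range fibre-volume-fraction range, drawn uniformly per sample
#'   (default `c(0.55, 0.85)`).
#' @param demyelination_factors myelin-thickness retention factors d in
#'   \[0, 1\]; each sample is assigned an arm cyclically. `d = 1` leaves the
#'   population untouched, `d = 0` strips all myelin. Default `1` (no
#'   demyelination arm).
#' @param biomarker_specs data frame with columns `kind`, `alpha`, `beta`,
#'   `noise_sd` describing the linear biomarkers to generate; defaults to
#'   three noise-free markers loosely emulating MWF-, BPF- and MTV-like
#'   sensitivities (see [default_biomarker_specs()]).
#' @param unmyelinated_fraction fraction of axons with no myelin (RO = RI);
#'   default 0 (ground truth counts myelinated axons only).
#' @param rho_mw myelin-water share of the myelin compartment used for the
#'   optional voxel-composition split (default 0.5).
#' @param fixed_radius if non-NULL, all inner radii are set to this value (um)
#'   instead of being drawn from the Gamma law; useful for degenerate test
#'   configurations.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 200,
                          seed,
                          axons_per_sample = 500,
                          radius_shape = 5, radius_scale = 0.1,
                          g_range = c(0.5, 0.95),
                          g_shape1 = 5, g_shape2 = 5,
                          g_concentration = 60,
                          fvf_range = c(0.55, 0.85),
                          demyelination_factors = 1,
                          biomarker_specs = default_biomarker_specs(),
                          unmyelinated_fraction = 0,
                          rho_mw = 0.5,
                          fixed_radius = NULL) {
  if (missing(seed) || length(seed) != 1L || !is.finite(seed))
    stop("an integer seed is mandatory", call. = FALSE)
  stopifnot(n_samples >= 1, axons_per_sample >= 1,
            radius_shape > 0, radius_scale > 0,
            length(g_range) == 2L, g_range[1] > 0, g_range[2] <= 1,
            g_range[1] <= g_range[2],
            g_shape1 > 0, g_shape2 > 0, g_concentration > 0,
            length(fvf_range) == 2L, fvf_range[1] > 0, fvf_range[2] <= 1,
            fvf_range[1] <= fvf_range[2],
            all(demyelination_factors >= 0 & demyelination_factors <= 1),
            unmyelinated_fraction >= 0, unmyelinated_fraction < 1,
            rho_mw >= 0, rho_mw <= 1)
  specs <- validate_biomarker_specs(biomarker_specs)
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed),
                 axons_per_sample = as.integer(axons_per_sample),
                 radius_shape = radius_shape, radius_scale = radius_scale,
                 g_range = g_range, g_shape1 = g_shape1, g_shape2 = g_shape2,
                 g_concentration = g_concentration, fvf_range = fvf_range,
                 demyelination_factors = demyelination_factors,
                 biomarker_specs = specs,
                 unmyelinated_fraction = unmyelinated_fraction,
                 rho_mw = rho_mw, fixed_radius = fixed_radius),
            class = "cohort_config")
}

#' Default linear biomarker specifications
#'
#' Slope/offset pairs are configuration, not literature facts: they emulate a
#' high-sensitivity MWF-like marker, a BPF-like marker with a non-trivial
#' offset, and an MTV-like marker, all noise-free.
#'
#' @return data frame with columns `kind`, `alpha`, `beta`, `noise_sd`.
#' @export
default_biomarker_specs <- function() {
  data.frame(kind = c("MWF", "BPF", "MTV"),
             alpha = c(1.6, 0.8, 1.2),
             beta = c(0.01, 0.05, 0.02),
             noise_sd = c(0, 0, 0),
             stringsAsFactors = FALSE)
}

validate_biomarker_specs <- function(specs) {
  specs <- as.data.frame(specs, stringsAsFactors = FALSE)
  need <- c("kind", "alpha", "beta")
  if (!all(need %in% names(specs)))
    stop("biomarker_specs needs columns kind, alpha, beta", call. = FALSE)
  if (is.null(specs$noise_sd)) specs$noise_sd <- 0
  if (any(specs$alpha == 0) || any(!is.finite(specs$alpha)))
    stop("biomarker slopes must be non-zero and finite", call. = FALSE)
  if (any(specs$noise_sd < 0))
    stop("noise_sd must be >= 0", call. = FALSE)
  if (anyDuplicated(specs$kind))
    stop("biomarker kinds must be unique", call. = FALSE)
  specs
}

# Beta draw rescaled to [lo, hi]; a zero-width range is a point mass.
rbeta_scaled <- function(n, shape1, shape2, lo, hi) {
  if (lo == hi) return(rep_len(lo, n))
  lo + (hi - lo) * stats::rbeta(n, shape1, shape2)
}

# Beta with given mean (on [lo, hi] scale) and concentration kappa.
rbeta_mean_conc <- function(n, mu, kappa, lo, hi) {
  if (lo == hi) return(rep_len(lo, n))
  mu01 <- (mu - lo) / (hi - lo)
  stopifnot(mu01 > 0, mu01 < 1)
  lo + (hi - lo) * stats::rbeta(n, mu01 * kappa, (1 - mu01) * kappa)
}

#' Draw one axon population from a cohort configuration
#'
#' Draws `axons_per_sample` inner radii from the configured Gamma law and
#' per-axon microscopic g-ratios from the hierarchical Beta law (sample-level
#' mean, then within-sample dispersion), sets `RO = RI / g`, and draws the
#' sample's packing fraction uniformly from `fvf_range`. If
#' `unmyelinated_fraction > 0`, that share of axons gets `RO = RI` (g = 1).
#' Deterministic given the RNG state; callers control seeding.
#'
#' @param config a [cohort_config()].
#' @return an [axon_population()].
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$axons_per_sample
  if (is.null(config$fixed_radius)) {
    ri <- stats::rgamma(n, shape = config$radius_shape, scale = config$radius_scale)
    ri <- pmax(ri, 1e-6)   # guard against underflow to 0 at tiny shape values
  } else {
    ri <- rep_len(config$fixed_radius, n)
  }
  mu_g <- rbeta_scaled(1, config$g_shape1, config$g_shape2,
                       config$g_range[1], config$g_range[2])
  g <- rbeta_mean_conc(n, mu_g, config$g_concentration,
                       config$g_range[1], config$g_range[2])
  if (any(g <= 0 | g > 1))
    stop("configured g law produced values outside (0, 1]", call. = FALSE)
  if (config$unmyelinated_fraction > 0) {
    n_un <- round(config$unmyelinated_fraction * n)
    if (n_un > 0) g[seq_len(n_un)] <- 1
  }
  fvf <- stats::runif(1, config$fvf_range[1], config$fvf_range[2])
  axon_population(ri, ri / g, fvf)
}

#' Thin the myelin sheaths of a population
#'
#' Models demyelination as a proportional loss of sheath thickness: each
#' axon's outer radius becomes `RO' = RI + d * (RO - RI)` while the axon
#' itself (RI) is untouched. `d = 1` is the identity, `d = 0` removes all
#' myelin; the microscopic (and hence aggregate) g-ratio rises as d falls.
#'
#' @param pop an [axon_population()].
#' @param d myelin retention factor in \[0, 1\].
#' @return a new [axon_population()].
#' @export
apply_demyelination <- function(pop, d) {
  stopifnot(inherits(pop, "axon_population"))
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d < 0 || d > 1)
    stop("d must be a single value in [0, 1]", call. = FALSE)
  axon_population(pop$inner_radius,
                  pop$inner_radius + d * (pop$outer_radius - pop$inner_radius),
                  pop$fvf)
}

#' Generate biomarker values for a known MVF under the linear law
#'
#' Inverts the calibration law: `M = (MVF - beta)/alpha`, plus additive
#' Gaussian noise with standard deviation `noise_sd`. With zero noise,
#' applying the matching linear model to M returns MVF exactly. A spec whose
#' offset exceeds the MVF (so the noise-free M would be negative) is a
#' configuration error.
#'
#' @param mvf myelin volume fraction(s).
#' @param specs biomarker spec data frame (`kind`, `alpha`, `beta`,
#'   `noise_sd`).
#' @return named list mapping kind to the numeric vector of biomarker values.
#' @export
generate_biomarkers <- function(mvf, specs = default_biomarker_specs()) {
  specs <- validate_biomarker_specs(specs)
  out <- list()
  for (i in seq_len(nrow(specs))) {
    m <- (mvf - specs$beta[i]) / specs$alpha[i]
    if (specs$noise_sd[i] == 0 && any(m < 0, na.rm = TRUE))
      stop(sprintf("biomarker %s: offset %.3g exceeds some MVF values (negative noise-free M)",
                   specs$kind[i], specs$beta[i]), call. = FALSE)
    if (specs$noise_sd[i] > 0)
      m <- m + stats::rnorm(length(m), 0, specs$noise_sd[i])
    out[[specs$kind[i]]] <- m
  }
  out
}

#' Build a ground-truth cohort table
#'
#' Runs the full generative chain for each sample: draw an axon population,
#' optionally thin its myelin (samples are assigned to the configured
#' demyelination arms cyclically), aggregate to volume fractions, derive the
#' true aggregate g-ratio and axon water fraction, and generate biomarkers
#' under the linear law. All randomness is governed by `config$seed`; the same
#' configuration reproduces the cohort bit for bit.
#'
#' @param config a [cohort_config()].
#' @return A tidy data frame of class `gratio_cohort` with one row per sample:
#'   `sample_id`, `arm` (demyelination factor), `mvf`, `avf`, `evf`, `awf`,
#'   `g_true`, and one column per biomarker kind (lower-cased). The
#'   configuration is attached as attribute `config`.
#' @examples
#' coh <- build_cohort(cohort_config(n_samples = 20, seed = 1))
#' summary(coh$g_true)
#' @export
build_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  n <- config$n_samples
  arms <- rep_len(config$demyelination_factors, n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pop <- generate_population(config)
    if (arms[i] < 1) pop <- apply_demyelination(pop, arms[i])
    agg <- aggregate_from_population(pop)
    rows[[i]] <- data.frame(sample_id = i, arm = arms[i],
                            mvf = agg$fractions$mvf, avf = agg$fractions$avf,
                            evf = agg$fractions$evf, awf = agg$awf,
                            g_true = agg$g_aggregate)
  }
  coh <- do.call(rbind, rows)
  bm <- generate_biomarkers(coh$mvf, config$biomarker_specs)
  for (kind in names(bm)) coh[[tolower(kind)]] <- bm[[kind]]
  attr(coh, "config") <- config
  class(coh) <- c("gratio_cohort", "data.frame")
  coh
}

# Save/restore the global RNG state so cohort generation is hermetic.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Optional voxel-composition split for a cohort sample
#'
#' Distributes a sample's volume fractions over the four-pool proton model:
#' the myelin compartment splits into myelin water (`rho_mw * MVF`) and
#' myelin-bound macromolecules (`(1 - rho_mw) * MVF`); axonal and
#' extracellular compartments are water; the non-myelin bound pool and CSF
#' default to zero. With `f_bnm = 0` the bound pool is entirely myelin, the
#' assumption under which AVF = (1 - MVF) * AWF is exact.
#'
#' @param fractions a [wm_fractions()].
#' @param rho_mw myelin-water share of the myelin compartment (default 0.5).
#' @param f_bnm non-myelin bound fraction (default 0); carved out of the
#'   extracellular water pool.
#' @return a [voxel_composition()].
#' @export
composition_from_fractions <- function(fractions, rho_mw = 0.5, f_bnm = 0) {
  stopifnot(inherits(fractions, "wm_fractions"))
  if (f_bnm > fractions$evf)
    stop("f_bnm cannot exceed the extracellular fraction", call. = FALSE)
  voxel_composition(f_mw = rho_mw * fractions$mvf,
                    f_aw = fractions$avf,
                    f_ew = fractions$evf - f_bnm,
                    f_csf = 0,
                    f_bm = (1 - rho_mw) * fractions$mvf,
                    f_bnm = f_bnm)
}

#' Write / read a cohort as CSV
#'
#' The CSV holds the tidy per-sample table; the configuration (including the
#' seed) is echoed to a JSON sidecar `<path>.config.json` so a cohort on disk
#' is fully reproducible.
#'
#' @param cohort a `gratio_cohort` data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "gratio_cohort"))
  utils::write.csv(cohort, path, row.names = FALSE)
  cfg <- attr(cohort, "config")
  if (!is.null(cfg)) {
    jsonlite::write_json(unclass(cfg), paste0(path, ".config.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  coh <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(coh) <- c("gratio_cohort", "data.frame")
  coh
}
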