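# Independent oracles used across the suite. These deliberately avoid the
# package's own closed forms: aggregation is done by direct summation over
# axons, and the g-referenced calibration is solved by a bounded 1-D
# minimiser of the objective it is defined by.

# Direct-summation aggregation of an axon population (areas as r^2, pi
# cancelling), independent of aggregate_from_population().
oracle_aggregate <- function(ri, ro, fvf) {
  s_i <- sum(ri^2)
  s_o <- sum(ro^2)
  mvf <- fvf * (s_o - s_i) / s_o
  avf <- fvf * s_i / s_o
  list(mvf = mvf, avf = avf, evf = 1 - fvf,
       g_aggregate = sqrt(avf / (avf + mvf)),
       g_area_weighted = sum(ro^2 * (ri / ro)) / s_o)
}

# Brute-force g-referenced single-point calibration: minimise
# |g(alpha_eff) - g_ref| over alpha_eff in (0, 10] with the ROI-mean
# quantities, mirroring the defining objective rather than its inversion.
oracle_spc_gratio_alpha <- function(m_bar, awf_bar, g_ref) {
  g_of <- function(a) {
    mvf <- a * m_bar
    avf <- (1 - mvf) * awf_bar
    sqrt(avf / (avf + mvf))
  }
  obj <- function(a) {
    if (a * m_bar >= 1) return(10 + a * m_bar)  # sloped penalty outside domain
    abs(g_of(a) - g_ref)
  }
  coarse <- stats::optimize(obj, interval = c(1e-9, 10), tol = 1e-10)$minimum
  # optimize() stalls around sqrt-machine precision on the V-shaped
  # objective; polish the minimiser by solving g(a) = g_ref, whose root is
  # the same point (g is strictly monotone in a)
  lo <- max(1e-12, coarse - 0.01)
  hi <- min(0.999999 / m_bar, coarse + 0.01)
  stats::uniroot(function(a) g_of(a) - g_ref, c(lo, hi),
                 tol = 1e-13, extendInt = "yes")$root
}

# Small deterministic cohort used by several files.
tiny_cohort <- function(n = 40, seed = 42, specs = NULL) {
  cfg <- if (is.null(specs)) cohort_config(n_samples = n, seed = seed)
  else cohort_config(n_samples = n, seed = seed, biomarker_specs = specs)
  build_cohort(cfg)
}

# Arrange per-sample scalars from a cohort on a 3-D grid as voxel maps.
cohort_to_maps <- function(cohort, column, shape = NULL) {
  n <- nrow(cohort)
  if (is.null(shape)) shape <- c(n, 1L, 1L)
  stopifnot(prod(shape) == n)
  voxel_map(array(cohort[[column]], dim = shape), kind = column)
}
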