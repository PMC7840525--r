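# ---- domain types -----------------------------------------------------------

#' Axon population: per-axon inner/outer radii plus a packing fraction
#'
#' Represents the myelinated-fibre content of one voxel or tissue sample as an
#' ordered collection of axons with circular cross-sections. Each axon has an
#' inner (axonal) radius `RI` and an outer (axon + myelin sheath) radius `RO`,
#' both in micrometres; the microscopic g-ratio of axon i is `RI[i]/RO[i]`.
#' `fvf` is the fibre volume fraction of the sample (axons + myelin), i.e.
#' MVF + AVF.
#'
#' @param inner_radius numeric vector of inner radii (um), all > 0.
#' @param outer_radius numeric vector of outer radii (um), `outer >= inner`
#'   elementwise.
#' @param fvf fibre volume fraction in (0, 1].
#' @return An object of class `axon_population`.
#' @examples
#' pop <- axon_population(c(0.6, 0.3), c(1.0, 0.5), fvf = 1)
#' aggregate_from_population(pop)
#' @export
axon_population <- function(inner_radius, outer_radius, fvf) {
  inner_radius <- as.numeric(inner_radius)
  outer_radius <- as.numeric(outer_radius)
  if (length(inner_radius) == 0L)
    stop("axon population must be non-empty", call. = FALSE)
  if (length(outer_radius) != length(inner_radius))
    stop("inner and outer radius vectors must have equal length", call. = FALSE)
  if (any(!is.finite(inner_radius)) || any(!is.finite(outer_radius)))
    stop("radii must be finite", call. = FALSE)
  if (any(inner_radius <= 0))
    stop("inner radii must be > 0", call. = FALSE)
  if (any(outer_radius < inner_radius))
    stop("outer radii must be >= inner radii", call. = FALSE)
  if (!is.numeric(fvf) || length(fvf) != 1L || fvf <= 0 || fvf > 1)
    stop("fvf must be a single value in (0, 1]", call. = FALSE)
  structure(list(inner_radius = inner_radius,
                 outer_radius = outer_radius,
                 fvf = fvf),
            class = "axon_population")
}

#' @export
print.axon_population <- function(x, ...) {
  g <- x$inner_radius / x$outer_radius
  cat(sprintf("<axon_population> %d axons, FVF = %.3f, microscopic g in [%.3f, %.3f]\n",
              length(x$inner_radius), x$fvf, min(g), max(g)))
  invisible(x)
}

#' White-matter volume fractions (MVF, AVF, EVF)
#'
#' The three-compartment white-matter bookkeeping: myelin (MVF), axonal (AVF)
#' and extracellular (EVF) volume fractions, which must sum to one.
#'
#' @param mvf,avf,evf fractions in \[0, 1\] summing to 1 (tolerance 1e-9).
#' @return An object of class `wm_fractions` (a named list).
#' @export
wm_fractions <- function(mvf, avf, evf) {
  v <- c(mvf = mvf, avf = avf, evf = evf)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
    stop("volume fractions must be finite and in [0, 1]", call. = FALSE)
  if (abs(sum(v) - 1) > 1e-9)
    stop(sprintf("MVF + AVF + EVF must equal 1 (got %.12f)", sum(v)),
         call. = FALSE)
  structure(list(mvf = mvf, avf = avf, evf = evf), class = "wm_fractions")
}

#' Four-pool voxel composition (water and bound-proton sub-fractions)
#'
#' Every voxel is described by its aqueous (`fW`) and macromolecule-bound
#' (`fB`) proton content with fW + fB = 1. The aqueous pool splits into myelin
#' water (`f_mw`), intra-axonal (`f_aw`), extracellular (`f_ew`) water and CSF
#' (`f_csf`); the bound pool into myelin (`f_bm`) and non-myelin (`f_bnm`)
#' macromolecules.
#'
#' @param f_mw,f_aw,f_ew,f_csf aqueous sub-fractions, each >= 0.
#' @param f_bm,f_bnm bound sub-fractions, each >= 0.
#' @return An object of class `voxel_composition`.
#' @seealso [biomarkers_from_composition()]
#' @export
voxel_composition <- function(f_mw, f_aw, f_ew, f_csf = 0, f_bm = 0, f_bnm = 0) {
  v <- c(f_mw = f_mw, f_aw = f_aw, f_ew = f_ew, f_csf = f_csf,
         f_bm = f_bm, f_bnm = f_bnm)
  if (any(!is.finite(v)) || any(v < 0))
    stop("all sub-fractions must be finite and >= 0", call. = FALSE)
  f_w <- f_mw + f_aw + f_ew + f_csf
  f_b <- f_bm + f_bnm
  if (abs(f_w + f_b - 1) > 1e-9)
    stop(sprintf("fW + fB must equal 1 (got %.12f)", f_w + f_b), call. = FALSE)
  structure(list(f_mw = f_mw, f_aw = f_aw, f_ew = f_ew, f_csf = f_csf,
                 f_bm = f_bm, f_bnm = f_bnm, f_w = f_w, f_b = f_b),
            class = "voxel_composition")
}

# ---- closed-form operations -------------------------------------------------

#' Aggregate g-ratio from volume fractions
#'
#' The voxel-level (aggregate) g-ratio computed from the myelin and axonal
#' volume fractions: `g = sqrt(1 - MVF/(MVF + AVF)) = sqrt(AVF/(AVF + MVF))`.
#' Under circular cross-sections this equals the fibre-area-weighted mean of
#' the microscopic g-ratios when all axons share the same g, and it is
#' invariant to a common rescaling of MVF and AVF (independence of the fibre
#' volume fraction).
#'
#' Vectorised over `mvf` and `avf` (recycled). Voxels with MVF + AVF = 0 carry
#' no fibre signal; the g-ratio is undefined there and `NA` is returned (and
#' propagated downstream) rather than 0 or 1. `NA` inputs yield `NA`.
#'
#' @param mvf myelin volume fraction(s), >= 0.
#' @param avf axonal volume fraction(s), >= 0, with `mvf + avf <= 1`.
#' @return numeric vector of g-ratios in \[0, 1\], `NA` where undefined.
#' @examples
#' g_from_volume_fractions(0.5, 0.5)   # sqrt(0.5)
#' g_from_volume_fractions(0, 0.5)     # 1: unmyelinated limit
#' @export
g_from_volume_fractions <- function(mvf, avf) {
  n <- max(length(mvf), length(avf))
  mvf <- rep_len(as.numeric(mvf), n)
  avf <- rep_len(as.numeric(avf), n)
  ok <- !is.na(mvf) & !is.na(avf)
  if (any(mvf[ok] < 0) || any(avf[ok] < 0))
    stop("volume fractions must be >= 0", call. = FALSE)
  if (any(mvf[ok] + avf[ok] > 1 + 1e-9))
    stop("MVF + AVF must be <= 1", call. = FALSE)
  tot <- mvf + avf
  g <- rep_len(NA_real_, n)
  def <- ok & tot > 0
  g[def] <- sqrt(avf[def] / tot[def])
  g
}

#' Axonal volume fraction from axon water fraction
#'
#' Rescales the diffusion-derived axon water fraction (AWF) to the axonal
#' volume fraction, accounting for the MR-invisible myelin compartment:
#' `AVF = (1 - MVF) * AWF`.
#'
#' @param awf axon water fraction(s) in \[0, 1\].
#' @param mvf myelin volume fraction(s) in \[0, 1\].
#' @return numeric vector of AVF values; `AVF + MVF <= 1` always holds.
#' @export
avf_from_awf <- function(awf, mvf) {
  n <- max(length(awf), length(mvf))
  awf <- rep_len(as.numeric(awf), n)
  mvf <- rep_len(as.numeric(mvf), n)
  ok <- !is.na(awf) & !is.na(mvf)
  if (any(awf[ok] < 0 | awf[ok] > 1))
    stop("AWF must be in [0, 1]", call. = FALSE)
  if (any(mvf[ok] < 0 | mvf[ok] > 1))
    stop("MVF must be in [0, 1]", call. = FALSE)
  (1 - mvf) * awf
}

#' Axon water fraction from NODDI signal fractions
#'
#' Converts the NODDI intra-neurite (stick) signal fraction `nu` and isotropic
#' (free-water) signal fraction `nu0` to the axon water fraction:
#' `AWF = nu * (1 - nu0)`. For two-compartment models without an isotropic
#' pool, set `nu0 = 0` and AWF reduces to `nu`.
#'
#' @param nu stick signal fraction(s) in \[0, 1\].
#' @param nu0 isotropic signal fraction(s) in \[0, 1\]; default 0.
#' @return numeric vector of AWF values in \[0, 1\].
#' @export
awf_from_noddi <- function(nu, nu0 = 0) {
  n <- max(length(nu), length(nu0))
  nu <- rep_len(as.numeric(nu), n)
  nu0 <- rep_len(as.numeric(nu0), n)
  ok <- !is.na(nu) & !is.na(nu0)
  if (any(nu[ok] < 0 | nu[ok] > 1) || any(nu0[ok] < 0 | nu0[ok] > 1))
    stop("nu and nu0 must be in [0, 1]", call. = FALSE)
  nu * (1 - nu0)
}

#' Aggregate a microscopic axon population to voxel-level quantities
#'
#' Sums per-axon cross-sectional areas (pi cancels, so plain `r^2` is used) to
#' produce the sample's volume fractions and two voxel-level g summaries:
#' the aggregate g-ratio from the volume fractions, and the fibre-area-weighted
#' mean of the microscopic g-ratios. For populations in which every axon has
#' the same microscopic g the two coincide exactly; for moderately dispersed
#' populations they agree closely.
#'
#' With `S_I = sum(RI^2)` and `S_O = sum(RO^2)`:
#' `MVF = FVF * (S_O - S_I)/S_O`, `AVF = FVF * S_I/S_O`, `EVF = 1 - FVF`,
#' and `g_area_weighted = sum(RO^2 * RI/RO) / S_O`.
#'
#' @param pop an [axon_population()].
#' @return A list with elements `fractions` ([wm_fractions()]), `awf`
#'   (= AVF/(AVF+EVF)), `g_aggregate`, and `g_area_weighted`.
#' @export
aggregate_from_population <- function(pop) {
  stopifnot(inherits(pop, "axon_population"))
  ri <- pop$inner_radius
  ro <- pop$outer_radius
  s_i <- sum(ri^2)
  s_o <- sum(ro^2)
  mvf <- pop$fvf * (s_o - s_i) / s_o
  avf <- pop$fvf * s_i / s_o
  evf <- 1 - pop$fvf
  list(fractions = wm_fractions(mvf, avf, evf),
       awf = avf / (avf + evf),
       g_aggregate = g_from_volume_fractions(mvf, avf),
       g_area_weighted = sum(ro * ri) / s_o)
}

#' Compartment-based myelin biomarker definitions
#'
#' Computes the standard myelin biomarkers from a four-pool voxel composition:
#' myelin water fraction `MWF = f_mw/fW`, bound pool fraction
#' `BPF = fB/(fW + fB) = fB`, pool size ratio `PSR = fB/fW`, proton density
#' `PD = fW`, and macromolecular tissue volume `MTV = 1 - PD = fB`.
#'
#' A voxel with no aqueous pool (fW = 0) has undefined MWF and PSR; these are
#' returned as `NA`.
#'
#' @param comp a [voxel_composition()].
#' @return named list with elements `mwf`, `bpf`, `psr`, `pd`, `mtv`.
#' @export
biomarkers_from_composition <- function(comp) {
  stopifnot(inherits(comp, "voxel_composition"))
  f_w <- comp$f_w
  f_b <- comp$f_b
  if (f_w == 0) {
    mwf <- NA_real_
    psr <- NA_real_
  } else {
    mwf <- comp$f_mw / f_w
    psr <- f_b / f_w
  }
  list(mwf = mwf, bpf = f_b / (f_w + f_b), psr = psr, pd = f_w, mtv = f_b)
}
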