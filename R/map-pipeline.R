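# Voxel-map front end: fuse co-registered myelin and diffusion maps into an
# aggregate g-ratio map, masked by the overlap of two white-matter
# tissue-probability maps. No resampling or registration is performed here:
# misaligned inputs are rejected outright, because residual misalignment
# between modalities corrupts the fused g-ratio.

#' In-memory voxel map
#'
#' A 3-D grid of values plus the voxel-to-world affine. Missing voxels are
#' `NA`. All maps that are processed together must share the grid shape and
#' affine (elementwise tolerance 1e-4).
#'
#' @param values numeric 3-D array (or a matrix / vector, reshaped to 3-D).
#' @param affine 4x4 voxel-to-world transform; default identity.
#' @param kind optional label (`"MTsat"`, `"nu"`, `"tpm"`, ...).
#' @return object of class `voxel_map`.
#' @export
voxel_map <- function(values, affine = diag(4), kind = NULL) {
  if (is.null(dim(values))) dim(values) <- c(length(values), 1L, 1L)
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  if (length(dim(values)) != 3L)
    stop("values must be a 3-D array", call. = FALSE)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix", call. = FALSE)
  storage.mode(values) <- "double"
  structure(list(values = values, affine = affine, kind = kind),
            class = "voxel_map")
}

#' @export
print.voxel_map <- function(x, ...) {
  cat(sprintf("<voxel_map%s> %s, %d missing of %d voxels\n",
              if (is.null(x$kind)) "" else paste0(" ", x$kind),
              paste(dim(x$values), collapse = "x"),
              sum(is.na(x$values)), length(x$values)))
  invisible(x)
}

# All maps must live on the same grid; name both affines on failure so the
# user can see which header disagrees.
check_aligned <- function(maps, tol = 1e-4) {
  ref <- maps[[1]]
  for (i in seq_along(maps)[-1]) {
    m <- maps[[i]]
    if (!identical(dim(ref$values), dim(m$values)))
      stop(sprintf("grid shape mismatch: %s vs %s",
                   paste(dim(ref$values), collapse = "x"),
                   paste(dim(m$values), collapse = "x")), call. = FALSE)
    if (any(abs(ref$affine - m$affine) > tol))
      stop(sprintf("affine mismatch (tol %g):\nfirst:\n%s\nother:\n%s",
                   tol,
                   paste(utils::capture.output(print(ref$affine)), collapse = "\n"),
                   paste(utils::capture.output(print(m$affine)), collapse = "\n")),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Overlap mask from two tissue-probability maps
#'
#' A voxel survives when both white-matter tissue probabilities strictly
#' exceed the threshold (`tpm_a > t & tpm_b > t`); a probability exactly equal
#' to the threshold is excluded. Missing probabilities never pass.
#'
#' @param tpm_a,tpm_b aligned [voxel_map()]s with values in \[0, 1\].
#' @param threshold probability threshold in (0, 1); default 0.5.
#' @return a `tissue_mask`: logical 3-D array with attributes `affine` and
#'   `provenance` (threshold and source kinds).
#' @export
overlap_mask <- function(tpm_a, tpm_b, threshold = 0.5) {
  stopifnot(inherits(tpm_a, "voxel_map"), inherits(tpm_b, "voxel_map"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)", call. = FALSE)
  check_aligned(list(tpm_a, tpm_b))
  rng <- range(c(tpm_a$values, tpm_b$values), na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("tissue probabilities must be in [0, 1]", call. = FALSE)
  mask <- !is.na(tpm_a$values) & !is.na(tpm_b$values) &
    tpm_a$values > threshold & tpm_b$values > threshold
  structure(mask, affine = tpm_a$affine,
            provenance = list(threshold = threshold,
                              sources = c(tpm_a$kind, tpm_b$kind)),
            class = c("tissue_mask", class(mask)))
}

#' Compute a masked aggregate g-ratio map from voxel maps
#'
#' Chains the closed forms per voxel inside the mask:
#' `MVF = clip(alpha_eff * M)`, `AWF = nu * (1 - nu0)` (`nu0 = 0` when no
#' isotropic-fraction map is supplied), `AVF = (1 - MVF) * AWF`, and
#' `g = sqrt(AVF / (AVF + MVF))`. Voxels outside the mask, or with any
#' missing input, are missing in the output. Counts of clipped and missing
#' voxels are attached as the `qc` attribute and reported.
#'
#' @param myelin_map [voxel_map()] of the myelin biomarker M.
#' @param nu_map [voxel_map()] of the stick signal fraction.
#' @param calib an `effective_calibration` (use [calibrate_none()] upstream
#'   for fraction-scaled proxies).
#' @param mask a `tissue_mask` from [overlap_mask()]; optional — default keeps
#'   every voxel.
#' @param nu0_map optional [voxel_map()] of the isotropic signal fraction.
#' @return a [voxel_map()] of g-ratios with attribute `qc` (list:
#'   `n_clipped`, `n_missing`, `n_in_mask`).
#' @export
gratio_map <- function(myelin_map, nu_map, calib, mask = NULL, nu0_map = NULL) {
  stopifnot(inherits(myelin_map, "voxel_map"), inherits(nu_map, "voxel_map"),
            inherits(calib, "effective_calibration"))
  maps <- list(myelin_map, nu_map)
  if (!is.null(nu0_map)) maps <- c(maps, list(nu0_map))
  check_aligned(maps)
  shape <- dim(myelin_map$values)
  if (is.null(mask)) {
    mask <- array(TRUE, dim = shape)
  } else {
    stopifnot(inherits(mask, "tissue_mask"))
    if (!identical(dim(mask), shape) ||
        any(abs(attr(mask, "affine") - myelin_map$affine) > 1e-4))
      stop("mask is not aligned with the input maps", call. = FALSE)
  }
  m <- myelin_map$values
  nu <- nu_map$values
  nu0 <- if (is.null(nu0_map)) array(0, dim = shape) else nu0_map$values
  if (identical(calib$reference_kind, "none")) {
    inside <- m[as.logical(mask) & !is.na(m)]
    if (any(inside < 0 | inside > 1))
      stop("uncalibrated use requires a fraction-scaled proxy: values outside [0, 1]",
           call. = FALSE)
  }

  mvf <- calib$alpha_eff * m
  clipped <- !is.na(mvf) & (mvf < 0 | mvf > 1) & as.logical(mask)
  mvf <- pmin(pmax(mvf, 0), 1)
  awf <- awf_from_noddi(pmin(pmax(nu, 0), 1), pmin(pmax(nu0, 0), 1))
  avf <- (1 - mvf) * awf
  tot <- mvf + avf
  g <- array(NA_real_, dim = shape)
  def <- as.logical(mask) & !is.na(tot) & tot > 0
  g[def] <- sqrt(avf[def] / tot[def])

  n_in_mask <- sum(mask)
  if (n_in_mask == 0L)
    warning("mask excludes every voxel; output is entirely missing")
  qc <- list(n_clipped = sum(clipped),
             n_missing = sum(is.na(g[as.logical(mask)])),
             n_in_mask = n_in_mask)
  if (qc$n_clipped > 0)
    message(qc$n_clipped, " voxel(s) clipped to [0, 1] after calibration")
  out <- voxel_map(g, affine = myelin_map$affine, kind = "gratio")
  attr(out, "qc") <- qc
  out
}

#' ROI-based calibration of voxel maps
#'
#' Computes the ROI means of the myelin biomarker and the AWF (from the
#' diffusion fraction maps) over the valid, in-mask ROI voxels, and delegates
#' to [spc_gratio()] or [spc_mvf()].
#'
#' @param myelin_map,nu_map aligned [voxel_map()]s.
#' @param roi_mask logical 3-D array (or `tissue_mask`) selecting the
#'   reference region.
#' @param reference `"g"` or `"mvf"`.
#' @param reference_value the reference g-ratio or MVF, in (0, 1).
#' @param nu0_map optional isotropic-fraction map.
#' @param mask optional `tissue_mask`; ROI voxels outside it are discarded.
#' @return an `effective_calibration`.
#' @export
roi_calibrate_map <- function(myelin_map, nu_map, roi_mask,
                              reference = c("g", "mvf"), reference_value,
                              nu0_map = NULL, mask = NULL) {
  reference <- match.arg(reference)
  maps <- list(myelin_map, nu_map)
  if (!is.null(nu0_map)) maps <- c(maps, list(nu0_map))
  check_aligned(maps)
  roi <- as.logical(roi_mask)
  if (!identical(dim(roi_mask), dim(myelin_map$values)))
    stop("ROI mask grid does not match the input maps", call. = FALSE)
  if (!is.null(mask)) roi <- roi & as.logical(mask)
  if (!any(roi))
    stop("ROI is empty after masking", call. = FALSE)
  m_roi <- myelin_map$values[roi]
  nu0 <- if (is.null(nu0_map)) 0 else nu0_map$values[roi]
  awf_roi <- awf_from_noddi(nu_map$values[roi], nu0)
  if (reference == "g") spc_gratio(m_roi, awf_roi, reference_value)
  else spc_mvf(m_roi, reference_value)
}
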