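# Linear biomarker-MVF law and the two single-point calibration procedures.
#
# Myelin biomarkers M (MWF, BPF, MTsat, MTV, ...) relate to the myelin volume
# fraction approximately linearly, MVF = alpha * M + beta, but alpha and beta
# depend on hardware and protocol and are unknown in vivo. Single-point
# calibration (SPC) collapses the two unknowns into one effective
# proportionality constant alpha_eff = MVF_ref / <M>_ROI fixed from a single
# reference value (a literature MVF, or a literature g-ratio) inside a
# reference region of interest.

#' Linear biomarker-to-MVF calibration model
#'
#' @param alpha slope (MVF per biomarker unit), non-zero.
#' @param beta offset (MVF units); default 0.
#' @param kind biomarker kind, one of `"MWF"`, `"BPF"`, `"MTsat"`, `"MTV"`,
#'   `"generic"`.
#' @return object of class `calibration_model`.
#' @export
calibration_model <- function(alpha, beta = 0,
                              kind = c("generic", "MWF", "BPF", "MTsat", "MTV")) {
  kind <- match.arg(kind)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha == 0)
    stop("alpha must be a single non-zero finite number", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta))
    stop("beta must be a single finite number", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, kind = kind),
            class = "calibration_model")
}

#' Apply a linear calibration model to biomarker values
#'
#' Returns `MVF = alpha * M + beta`, clipped to \[0, 1\]. The number of clipped
#' samples is attached as attribute `n_clipped` and reported via a message so
#' silent saturation cannot go unnoticed. `NA` values propagate.
#'
#' @param m biomarker values (numeric vector).
#' @param model a [calibration_model()].
#' @param quiet suppress the clipping message (default FALSE).
#' @return numeric vector of MVF estimates in \[0, 1\] with attribute
#'   `n_clipped`.
#' @export
apply_linear_model <- function(m, model, quiet = FALSE) {
  stopifnot(inherits(model, "calibration_model"))
  mvf <- model$alpha * as.numeric(m) + model$beta
  clipped <- !is.na(mvf) & (mvf < 0 | mvf > 1)
  mvf[!is.na(mvf)] <- pmin(pmax(mvf[!is.na(mvf)], 0), 1)
  if (any(clipped) && !quiet)
    message(sum(clipped), " calibrated value(s) clipped to [0, 1]")
  attr(mvf, "n_clipped") <- sum(clipped)
  mvf
}

# Shared ROI validation/summary: drop missing values, insist on >= 1 valid
# sample, return arithmetic means.
roi_mean <- function(x, what) {
  x <- x[!is.na(x)]
  if (length(x) < 1L)
    stop("reference ROI has no valid ", what, " samples", call. = FALSE)
  mean(x)
}

new_effective_calibration <- function(alpha_eff, roi_mean_m, reference_kind,
                                      reference_value, n_roi,
                                      roi_mean_awf = NA_real_) {
  if (!is.finite(alpha_eff) || alpha_eff <= 0)
    stop("calibration failed: alpha_eff is not finite and positive",
         call. = FALSE)
  structure(list(alpha_eff = alpha_eff,
                 roi_mean_m = roi_mean_m,
                 roi_mean_awf = roi_mean_awf,
                 reference_kind = reference_kind,
                 reference_value = reference_value,
                 n_roi = n_roi),
            class = "effective_calibration")
}

#' @export
print.effective_calibration <- function(x, ...) {
  cat(sprintf("<effective_calibration> alpha_eff = %.6g (%s reference = %s, n_roi = %d)\n",
              x$alpha_eff, x$reference_kind,
              format(x$reference_value), x$n_roi))
  invisible(x)
}

#' MVF-referenced single-point calibration
#'
#' Fixes the effective proportionality constant from a reference myelin volume
#' fraction assumed to hold in the ROI: `alpha_eff = MVF_ref / <M>_ROI`, where
#' `<M>_ROI` is the arithmetic mean of the biomarker over the ROI (missing
#' values excluded). Calibrated maps are then `alpha_eff * M` with no offset.
#'
#' @param m_roi biomarker values inside the reference ROI.
#' @param mvf_ref reference MVF, a fraction in (0, 1).
#' @return an `effective_calibration` object.
#' @export
spc_mvf <- function(m_roi, mvf_ref) {
  if (!is.numeric(mvf_ref) || length(mvf_ref) != 1L ||
      !is.finite(mvf_ref) || mvf_ref <= 0 || mvf_ref >= 1)
    stop("mvf_ref must be a single fraction in (0, 1)", call. = FALSE)
  m_bar <- roi_mean(m_roi, "biomarker")
  if (m_bar <= 0)
    stop("calibration failed: ROI mean biomarker is <= 0", call. = FALSE)
  new_effective_calibration(mvf_ref / m_bar, m_bar, "mvf_ref", mvf_ref,
                            sum(!is.na(m_roi)))
}

# Closed-form inversion of the g-referenced calibration: the MVF value MVF*
# at which the ROI-level g-ratio (via AVF = (1 - MVF) * AWF) equals g_ref.
mvf_star_from_gref <- function(g_ref, awf) {
  a <- awf * (1 - g_ref^2)
  a / (g_ref^2 + a)
}

#' g-ratio-referenced single-point calibration
#'
#' Chooses `alpha_eff` so that the ROI-level aggregate g-ratio, recomputed from
#' the calibrated ROI-mean MVF and the ROI-mean AWF, equals a reference
#' g-ratio (e.g. 0.71 in the medullary pyramid). The minimisation of
#' `|g(alpha_eff, ROI) - g_ref|` has a closed-form solution: with
#' `A = <AWF>_ROI`, the target ROI MVF is
#' `MVF* = A (1 - g_ref^2) / (g_ref^2 + A (1 - g_ref^2))` and
#' `alpha_eff = MVF* / <M>_ROI`.
#'
#' @param m_roi biomarker values inside the reference ROI.
#' @param awf_roi axon water fraction values inside the ROI.
#' @param g_ref reference g-ratio, a fraction in (0, 1).
#' @return an `effective_calibration` object.
#' @export
spc_gratio <- function(m_roi, awf_roi, g_ref) {
  if (!is.numeric(g_ref) || length(g_ref) != 1L ||
      !is.finite(g_ref) || g_ref <= 0 || g_ref >= 1)
    stop("g_ref must be a single fraction in (0, 1)", call. = FALSE)
  m_bar <- roi_mean(m_roi, "biomarker")
  awf_bar <- roi_mean(awf_roi, "AWF")
  if (awf_bar <= 0 || awf_bar > 1)
    stop("calibration failed: ROI mean AWF must be in (0, 1]", call. = FALSE)
  if (m_bar <= 0)
    stop("calibration failed: ROI mean biomarker is <= 0", call. = FALSE)
  mvf_star <- mvf_star_from_gref(g_ref, awf_bar)
  new_effective_calibration(mvf_star / m_bar, m_bar, "g_ref", g_ref,
                            sum(!is.na(m_roi)), roi_mean_awf = awf_bar)
}

#' Identity (no-op) calibration for fraction-scaled proxies
#'
#' The "no calibration" comparison arm: the biomarker is taken to be an MVF
#' proxy as-is (`alpha_eff = 1`). This is only admissible when the biomarker is
#' already on a volume-fraction scale; values outside \[0, 1\] are an error
#' (e.g. MTsat-based g-ratio is undefined without calibration).
#'
#' @param m biomarker values; all non-missing values must lie in \[0, 1\].
#' @return an `effective_calibration` object with `alpha_eff = 1`.
#' @export
calibrate_none <- function(m) {
  v <- m[!is.na(m)]
  if (length(v) < 1L)
    stop("no valid biomarker samples", call. = FALSE)
  if (any(v < 0 | v > 1))
    stop("uncalibrated use requires a fraction-scaled proxy: values outside [0, 1]",
         call. = FALSE)
  new_effective_calibration(1, mean(v), "none", NA_real_, length(v))
}

#' Serialise an effective calibration to JSON
#'
#' @param calib an `effective_calibration`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to file.
#' @export
calibration_to_json <- function(calib, path = NULL) {
  stopifnot(inherits(calib, "effective_calibration"))
  x <- list(alpha_eff = calib$alpha_eff,
            roi_summary = calib$roi_mean_m,
            roi_mean_awf = calib$roi_mean_awf,
            reference_kind = calib$reference_kind,
            reference_value = calib$reference_value,
            n_roi = calib$n_roi)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read an effective calibration back from JSON
#'
#' @param path path to a JSON file written by [calibration_to_json()].
#' @return an `effective_calibration` object.
#' @export
calibration_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  new_effective_calibration(x$alpha_eff, x$roi_summary,
                            x$reference_kind,
                            if (is.null(x$reference_value)) NA_real_ else x$reference_value,
                            as.integer(x$n_roi),
                            if (is.null(x$roi_mean_awf)) NA_real_ else x$roi_mean_awf)
}
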