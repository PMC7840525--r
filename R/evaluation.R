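# Bland-Altman agreement analysis and the calibration experiment runner.
#
# The evaluation asks: if the MR-derived g-ratio replaced the ground truth,
# what systematic offset (bias) and what spread (error) would we incur? Bias
# is the mean paired difference delta_g = g_GT - g_MRI; error is 1.96 times
# the sample standard deviation of the differences (the half-width of the 95%
# limits of agreement). Bias is retrospectively correctable; error bounds the
# method's sensitivity to group differences or change over time.

#' Bland-Altman comparison of two paired g-ratio series
#'
#' @param g_gt ground-truth g-ratios.
#' @param g_mri MR-derived g-ratios, same length.
#' @return object of class `bland_altman`: list with `differences`
#'   (`g_gt - g_mri`), `means` (`(g_gt + g_mri)/2`), `bias` (mean difference),
#'   `error` (1.96 x sample sd of differences, n-1 denominator), `n` (valid
#'   pairs) and `n_dropped` (pairs removed because either member was missing).
#' @examples
#' ba <- bland_altman(c(0.7, 0.7), c(0.6, 0.8))
#' ba$bias; ba$error
#' @export
bland_altman <- function(g_gt, g_mri) {
  if (length(g_gt) != length(g_mri))
    stop("g_gt and g_mri must have equal length", call. = FALSE)
  keep <- !is.na(g_gt) & !is.na(g_mri)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " pair(s) with missing values dropped")
  g_gt <- g_gt[keep]
  g_mri <- g_mri[keep]
  if (length(g_gt) < 2L)
    stop("need at least 2 valid pairs", call. = FALSE)
  d <- g_gt - g_mri
  structure(list(differences = d,
                 means = (g_gt + g_mri) / 2,
                 bias = mean(d),
                 error = 1.96 * stats::sd(d),
                 n = length(d),
                 n_dropped = n_dropped),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d, bias = %.6g, error (1.96 sd) = %.6g\n",
              x$n, x$bias, x$error))
  invisible(x)
}

#' Bland-Altman plot (base graphics)
#'
#' Scatter of paired differences against paired means, with the bias line and
#' the 95% limits of agreement. Purely presentational; all numbers come from
#' [bland_altman()].
#'
#' @param x a `bland_altman` object.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.bland_altman <- function(x, ...) {
  plot(x$means, x$differences,
       xlab = expression(m[g] == (g[GT] + g[MRI]) / 2),
       ylab = expression(delta * g == g[GT] - g[MRI]), ...)
  graphics::abline(h = x$bias, lty = 1)
  graphics::abline(h = x$bias + c(-1, 1) * x$error, lty = 2)
  invisible(x)
}

# Resolve a reference ROI specification to row indices of the cohort.
# Default: middle tercile of true MVF (a mid-myelination reference region).
resolve_roi <- function(cohort, roi = NULL) {
  n <- nrow(cohort)
  if (is.null(roi)) {
    q <- stats::quantile(cohort$mvf, c(1 / 3, 2 / 3), names = FALSE)
    idx <- which(cohort$mvf > q[1] & cohort$mvf <= q[2])
  } else if (is.logical(roi)) {
    stopifnot(length(roi) == n)
    idx <- which(roi)
  } else {
    idx <- as.integer(roi)
    stopifnot(all(idx >= 1 & idx <= n))
  }
  if (length(idx) < 1L)
    stop("reference ROI is empty", call. = FALSE)
  idx
}

# True ROI-level reference values, computed the same way the calibrated ROI
# summary is: from ROI-mean quantities (unbiased references).
roi_truth <- function(cohort, idx) {
  mvf_bar <- mean(cohort$mvf[idx])
  awf_bar <- mean(cohort$awf[idx])
  list(mvf_ref = mvf_bar,
       g_ref = g_from_volume_fractions(mvf_bar, avf_from_awf(awf_bar, mvf_bar)))
}

#' Run the biomarker-by-calibration-mode evaluation experiment
#'
#' For each biomarker in the cohort and each calibration mode, derives a
#' per-sample MR g-ratio and compares it to the ground truth with a
#' Bland-Altman analysis. The chain per sample is: calibrate the biomarker
#' (`MVF_est = clip(alpha_eff * M)`), rescale the axon water fraction to the
#' axonal volume fraction (`AVF = (1 - MVF_est) * AWF`), then
#' `g_MRI = sqrt(AVF/(AVF + MVF_est))`.
#'
#' Modes: `"none"` uses the biomarker as an MVF proxy unchanged (only valid
#' for fraction-scaled proxies), `"g_spc"` is the g-ratio-referenced
#' single-point calibration, `"mvf_spc"` the MVF-referenced one. Reference
#' values default to the exact (unbiased) ROI truth computed from ROI-mean
#' MVF and AWF; pass `g_ref`/`mvf_ref` to use biased references.
#'
#' Conditions whose calibration fails (e.g. a proxy outside \[0, 1\] with mode
#' `"none"`) are reported as failed rows with `NA` statistics, not dropped.
#'
#' @param cohort a `gratio_cohort` from [build_cohort()] (or any data frame
#'   with columns `mvf`, `awf`, `g_true` and one column per biomarker).
#' @param biomarkers character vector of biomarker column names; default all
#'   cohort biomarker columns.
#' @param modes subset of `c("none", "g_spc", "mvf_spc")`.
#' @param roi reference-ROI specification: `NULL` (default, middle tercile of
#'   true MVF), a logical vector over samples, or integer indices.
#' @param g_ref,mvf_ref optional reference values; default: exact ROI truth.
#' @return object of class `gratio_experiment`: list with `table` (one row per
#'   biomarker x mode: `biomarker`, `mode`, `alpha_eff`, `bias`, `error`, `n`,
#'   `status`), `details` (per-condition `bland_altman` + calibration +
#'   per-sample series), and `roi` (indices and reference values used).
#' @export
run_calibration_experiment <- function(cohort,
                                       biomarkers = NULL,
                                       modes = c("none", "g_spc", "mvf_spc"),
                                       roi = NULL,
                                       g_ref = NULL, mvf_ref = NULL) {
  modes <- match.arg(modes, several.ok = TRUE)
  if (is.null(biomarkers)) {
    reserved <- c("sample_id", "arm", "mvf", "avf", "evf", "awf", "g_true")
    biomarkers <- setdiff(names(cohort), reserved)
  }
  stopifnot(length(biomarkers) >= 1, all(biomarkers %in% names(cohort)))
  idx <- resolve_roi(cohort, roi)
  truth <- roi_truth(cohort, idx)
  if (is.null(g_ref)) g_ref <- truth$g_ref
  if (is.null(mvf_ref)) mvf_ref <- truth$mvf_ref

  rows <- list()
  details <- list()
  for (bm in biomarkers) {
    m <- cohort[[bm]]
    for (mode in modes) {
      key <- paste(bm, mode, sep = ".")
      res <- tryCatch({
        calib <- switch(mode,
          none    = calibrate_none(m),
          g_spc   = spc_gratio(m[idx], cohort$awf[idx], g_ref),
          mvf_spc = spc_mvf(m[idx], mvf_ref))
        mvf_est <- apply_linear_model(
          m, calibration_model(calib$alpha_eff, 0), quiet = TRUE)
        avf_est <- avf_from_awf(cohort$awf, mvf_est)
        g_mri <- g_from_volume_fractions(mvf_est, avf_est)
        ba <- bland_altman(cohort$g_true, g_mri)
        list(calibration = calib, bland_altman = ba,
             mvf_est = mvf_est, g_mri = g_mri, status = "ok")
      }, error = function(e) list(status = "failed", message = conditionMessage(e)))
      details[[key]] <- res
      rows[[key]] <- if (identical(res$status, "ok")) {
        data.frame(biomarker = bm, mode = mode,
                   alpha_eff = res$calibration$alpha_eff,
                   bias = res$bland_altman$bias,
                   error = res$bland_altman$error,
                   n = res$bland_altman$n, status = "ok",
                   stringsAsFactors = FALSE)
      } else {
        data.frame(biomarker = bm, mode = mode, alpha_eff = NA_real_,
                   bias = NA_real_, error = NA_real_, n = NA_integer_,
                   status = paste0("failed: ", res$message),
                   stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 details = details,
                 roi = list(indices = idx, g_ref = g_ref, mvf_ref = mvf_ref)),
            class = "gratio_experiment")
}

#' @export
print.gratio_experiment <- function(x, ...) {
  cat("<gratio_experiment>\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write experiment results to CSV (+ JSON summary)
#'
#' @param experiment a `gratio_experiment`.
#' @param path output CSV path; a JSON summary with the ROI/reference metadata
#'   is written alongside as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_experiment_csv <- function(experiment, path) {
  stopifnot(inherits(experiment, "gratio_experiment"))
  utils::write.csv(experiment$table, path, row.names = FALSE)
  jsonlite::write_json(
    list(roi_n = length(experiment$roi$indices),
         g_ref = experiment$roi$g_ref,
         mvf_ref = experiment$roi$mvf_ref,
         conditions = experiment$table),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
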