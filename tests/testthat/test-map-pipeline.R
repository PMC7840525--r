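test_that("overlap_mask implements the strict-threshold AND rule", {
  tpm_a <- voxel_map(array(c(0.9, 0.6, 0.4, 0.9), c(2, 2, 1)), kind = "tpm_mt")
  tpm_b <- voxel_map(array(c(0.8, 0.4, 0.9, 0.9), c(2, 2, 1)), kind = "tpm_dwi")
  mask <- overlap_mask(tpm_a, tpm_b, 0.5)
  expect_equal(as.vector(mask), c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(sum(mask), 2L)
  expect_equal(attr(mask, "provenance")$threshold, 0.5)

  # a probability exactly at the threshold is excluded (strict >)
  at <- voxel_map(array(c(0.5, 0.6), c(2, 1, 1)))
  ones <- voxel_map(array(1, c(2, 1, 1)))
  expect_equal(as.vector(overlap_mask(at, ones, 0.5)), c(FALSE, TRUE))
  # degenerate second map: mask reduces to the first comparison
  expect_equal(as.vector(overlap_mask(tpm_a, voxel_map(array(1, c(2, 2, 1))), 0.5)),
               as.vector(tpm_a$values > 0.5))
  expect_error(overlap_mask(tpm_a, voxel_map(array(1.2, c(2, 2, 1))), 0.5),
               "\\[0, 1\\]")
})

test_that("misaligned grids are rejected with both affines named", {
  a <- voxel_map(array(0.5, c(2, 2, 1)))
  b <- voxel_map(array(0.5, c(2, 2, 1)), affine = diag(c(2, 2, 2, 1)))
  expect_error(overlap_mask(a, b, 0.5), "affine mismatch")
  d <- voxel_map(array(0.5, c(2, 2, 2)))
  expect_error(overlap_mask(a, d, 0.5), "shape mismatch")
  # tolerance 1e-4 absorbs header rounding
  almost <- voxel_map(array(0.6, c(2, 2, 1)), affine = diag(4) + 5e-5)
  expect_silent(mask <- overlap_mask(a, almost, 0.5))
})

test_that("gratio_map chains the closed forms and handles masking/missing", {
  shape <- c(2, 2, 1)
  m <- voxel_map(array(0.3, shape))
  nu <- voxel_map(array(0.6, shape))
  nu0 <- voxel_map(array(0.1, shape))
  calib <- calibrate_none(0.3)   # alpha_eff = 1
  g <- gratio_map(m, nu, calib, nu0_map = nu0)
  # M=0.3, AWF=0.54, AVF=0.378, g = sqrt(0.378/0.678) = 0.746674
  expect_equal(as.vector(g$values), rep(sqrt(0.378 / 0.678), 4),
               tolerance = 1e-12)
  expect_equal(g$values[1, 1, 1], 0.74667, tolerance = 1e-4)

  # masked voxels are missing; in-mask missing inputs stay missing
  tpm_a <- voxel_map(array(c(0.9, 0.6, 0.4, 0.9), shape))
  tpm_b <- voxel_map(array(c(0.8, 0.4, 0.9, 0.9), shape))
  mask <- overlap_mask(tpm_a, tpm_b, 0.5)
  m2 <- m; m2$values[1, 1, 1] <- NA
  g2 <- gratio_map(m2, nu, calib, mask = mask, nu0_map = nu0)
  expect_true(is.na(g2$values[1, 1, 1]))            # missing input
  expect_true(is.na(g2$values[2, 1, 1]))            # outside mask
  expect_false(is.na(g2$values[2, 2, 1]))
  qc <- attr(g2, "qc")
  expect_equal(qc$n_in_mask, 2L)
  expect_equal(qc$n_missing, 1L)

  # unmyelinated limit: M = 0 everywhere gives g = 1 inside the mask
  g3 <- gratio_map(voxel_map(array(0, shape)), nu, calib, mask = mask)
  expect_equal(as.vector(g3$values)[as.vector(mask)], c(1, 1))
})

test_that("masking commutes with the g computation and is idempotent", {
  set.seed(77)
  shape <- c(4, 3, 2)
  m <- voxel_map(array(runif(24, 0.05, 0.4), shape))
  nu <- voxel_map(array(runif(24, 0.3, 0.8), shape))
  tpm_a <- voxel_map(array(runif(24), shape))
  tpm_b <- voxel_map(array(runif(24), shape))
  mask <- overlap_mask(tpm_a, tpm_b, 0.5)
  calib <- calibrate_none(0.5)

  g_then_mask <- gratio_map(m, nu, calib)
  g_then_mask$values[!mask] <- NA
  m_masked <- m; m_masked$values[!mask] <- NA
  mask_then_g <- gratio_map(m_masked, nu, calib, mask = mask)
  direct <- gratio_map(m, nu, calib, mask = mask)
  expect_equal(mask_then_g$values, g_then_mask$values, tolerance = 1e-15)
  expect_equal(direct$values, g_then_mask$values, tolerance = 1e-15)
  # idempotence: re-masking the masked result changes nothing
  again <- gratio_map(voxel_map(m_masked$values), nu, calib, mask = mask)
  expect_equal(again$values, mask_then_g$values, tolerance = 1e-15)
})

test_that("NIfTI round-trip preserves values, missingness, and the affine", {
  set.seed(88)
  shape <- c(5L, 4L, 3L)
  vals <- array(runif(60), shape)
  vals[c(3, 17, 41)] <- NA
  affine <- rbind(c(2, 0, 0, -10), c(0, 2, 0, -12), c(0, 0, 2.5, -7),
                  c(0, 0, 0, 1))
  map <- voxel_map(vals, affine = affine, kind = "test")

  for (ext in c(".nii", ".nii.gz")) {
    path <- withr::local_tempfile(fileext = ext)
    write_nifti(map, path, datatype = "float64")
    back <- read_nifti(path)
    expect_identical(dim(back$values), shape)
    expect_equal(back$values, vals, tolerance = 1e-15)     # float64: exact
    expect_identical(is.na(back$values), is.na(vals))
    expect_equal(back$affine, affine, tolerance = 1e-6)
  }
  # float32 storage precision
  p32 <- withr::local_tempfile(fileext = ".nii")
  write_nifti(map, p32, datatype = "float32")
  expect_equal(read_nifti(p32)$values, vals, tolerance = 1e-6)
  # integer datatypes refuse missing values
  expect_error(write_nifti(map, p32, datatype = "uint8"), "missing")
})

test_that("map pipeline agrees with the scalar pipeline on cohort-derived maps", {
  coh <- tiny_cohort(n = 24, seed = 91)
  shape <- c(4, 3, 2)
  m_map <- cohort_to_maps(coh, "bpf", shape)
  # invert AWF = nu * (1 - nu0) with a fixed nu0 to build the fraction maps
  nu0 <- 0.08
  nu_map <- voxel_map(array(coh$awf / (1 - nu0), shape))
  nu0_map <- voxel_map(array(nu0, shape))

  roi <- array(FALSE, shape); roi[1:8] <- TRUE
  calib <- roi_calibrate_map(m_map, nu_map, roi, reference = "mvf",
                             reference_value = mean(coh$mvf[1:8]),
                             nu0_map = nu0_map)
  g_map <- gratio_map(m_map, nu_map, calib, nu0_map = nu0_map)

  mvf_est <- as.numeric(apply_linear_model(
    coh$bpf, calibration_model(calib$alpha_eff), quiet = TRUE))
  g_scalar <- g_from_volume_fractions(mvf_est, avf_from_awf(coh$awf, mvf_est))
  expect_equal(as.vector(g_map$values), g_scalar, tolerance = 1e-12)
})

test_that("roi_calibrate_map matches the scalar closed form and validates the ROI", {
  shape <- c(3, 2, 1)
  m <- voxel_map(array(0.2, shape))
  nu <- voxel_map(array(0.5, shape))
  roi <- array(TRUE, shape)
  calib <- roi_calibrate_map(m, nu, roi, reference = "g", reference_value = 0.71)
  expect_equal(calib$alpha_eff, 0.3297 / 0.2, tolerance = 1e-3)
  mvf <- calib$alpha_eff * 0.2
  expect_equal(g_from_volume_fractions(mvf, avf_from_awf(0.5, mvf)), 0.71,
               tolerance = 1e-10)
  # consistency: an MVF reference equal to the prior calibrated ROI mean
  # reproduces the same alpha_eff
  calib2 <- roi_calibrate_map(m, nu, roi, reference = "mvf",
                              reference_value = calib$alpha_eff * 0.2)
  expect_equal(calib2$alpha_eff, calib$alpha_eff, tolerance = 1e-12)
  # ROI entirely outside the overlap mask is an error
  tpm0 <- voxel_map(array(0.1, shape))
  mask <- overlap_mask(tpm0, tpm0, 0.5)
  expect_error(roi_calibrate_map(m, nu, roi, reference = "g",
                                 reference_value = 0.71, mask = mask),
               "empty")
})

test_that("the CLI drives simulate -> evaluate -> calibrate -> map end to end", {
  dir <- withr::local_tempdir()
  cohort_csv <- file.path(dir, "cohort.csv")
  gratio_cli(c("simulate", "--seed", "11", "--n", "30", "--out", cohort_csv))
  expect_true(file.exists(cohort_csv))
  coh <- read_cohort_csv(cohort_csv)
  expect_equal(nrow(coh), 30L)

  exp_csv <- file.path(dir, "exp.csv")
  gratio_cli(c("evaluate", "--cohort", cohort_csv, "--out", exp_csv))
  tab <- utils::read.csv(exp_csv)
  expect_equal(nrow(tab), 9L)               # 3 biomarkers x 3 modes

  # synthetic voxel maps from the cohort
  shape <- c(5, 3, 2)
  write_nifti(cohort_to_maps(coh, "mwf", shape), file.path(dir, "m.nii.gz"))
  write_nifti(voxel_map(array(coh$awf, shape)), file.path(dir, "nu.nii.gz"))
  roi_vals <- array(0, shape); roi_vals[1:10] <- 1
  write_nifti(voxel_map(roi_vals), file.path(dir, "roi.nii.gz"))
  write_nifti(voxel_map(array(0.9, shape)), file.path(dir, "tpma.nii.gz"))
  tpmb <- array(0.9, shape); tpmb[1, 1, 1] <- 0.2
  write_nifti(voxel_map(tpmb), file.path(dir, "tpmb.nii.gz"))

  calib_json <- file.path(dir, "calib.json")
  gratio_cli(c("calibrate", "--myelin", file.path(dir, "m.nii.gz"),
               "--nu", file.path(dir, "nu.nii.gz"),
               "--roi", file.path(dir, "roi.nii.gz"),
               "--reference", "g", "--reference-value", "0.71",
               "--out", calib_json))
  expect_true(file.exists(calib_json))

  out_nii <- file.path(dir, "g.nii.gz")
  gratio_cli(c("map", "--myelin", file.path(dir, "m.nii.gz"),
               "--nu", file.path(dir, "nu.nii.gz"),
               "--calibration", calib_json,
               "--tpm-a", file.path(dir, "tpma.nii.gz"),
               "--tpm-b", file.path(dir, "tpmb.nii.gz"),
               "--out", out_nii))
  g <- read_nifti(out_nii)
  expect_true(is.na(g$values[1, 1, 1]))     # below threshold in tpm_b
  expect_true(all(!is.na(g$values[-1])))
  expect_true(all(g$values[-1] > 0 & g$values[-1] <= 1))
  expect_true(file.exists(file.path(dir, "g_mask.nii.gz")))
  qc <- jsonlite::fromJSON(paste0(out_nii, ".qc.json"))
  expect_equal(qc$n_in_mask, 29L)
})
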