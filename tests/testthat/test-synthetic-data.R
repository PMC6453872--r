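test_that("fBm textures are deterministic and hit the requested moments", {
  a <- make_fbm_texture(32, 48, hurst = 0.5, mean_gv = 500, sd_gv = 25, seed = 7)
  b <- make_fbm_texture(32, 48, hurst = 0.5, mean_gv = 500, sd_gv = 25, seed = 7)
  expect_identical(a, b)
  expect_equal(mean(a), 500, tolerance = 1e-9)
  expect_equal(sd(a), 25, tolerance = 1e-9)
  d <- make_fbm_texture(32, 48, hurst = 0.5, mean_gv = 500, sd_gv = 25, seed = 8)
  expect_false(identical(a, d))
  # caller RNG untouched
  withr::with_seed(1, {
    before <- runif(1)
  })
  withr::with_seed(1, {
    invisible(make_fbm_texture(32, 32, 0.4, seed = 3))
    expect_equal(runif(1), before)
  })
})

test_that("fBm parameter guards reject non-finite and out-of-range input", {
  expect_error(make_fbm_texture(8, 32, 0.5), class = "radbone_invalid_parameter")
  expect_error(make_fbm_texture(32, 32, 1.2), class = "radbone_invalid_parameter")
  expect_error(make_fbm_texture(32, 32, NaN), class = "radbone_invalid_parameter")
  expect_error(make_fbm_texture(32, 32, 0.5, sd_gv = 0),
               class = "radbone_invalid_parameter")
  expect_error(make_fbm_texture(32, 32, 0.5, anisotropy = -1),
               class = "radbone_invalid_parameter")
})

test_that("isotropic fBm yields matching directional fractal dimensions", {
  diffs <- vapply(1:10, function(s) {
    img <- make_fbm_texture(256, 256, 0.5, 1, 10000, 200, seed = s)
    sig <- fsa_roi(img, 0.148)
    sig$vertical$fd_global - sig$horizontal$fd_global
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.05)
})

test_that("noiseless wedge rendering reproduces the response cubic exactly", {
  spec <- small_wedge()
  cf <- c(1000, 900, -12, 0.05)
  img <- render_step_wedge(spec, cf, saturation_gv = Inf, noise_sd = 0)
  for (i in seq_along(spec$step_thicknesses_mm)) {
    expect_equal(mean(rect_extract_for_test(img, spec$step_rects[[i]])),
                 cf[1] + cf[2] * spec$step_thicknesses_mm[i] +
                   cf[3] * spec$step_thicknesses_mm[i]^2 +
                   cf[4] * spec$step_thicknesses_mm[i]^3,
                 tolerance = 1e-12)
  }
})

test_that("saturation between steps 8 and 9 clips the two thickest steps", {
  spec <- small_wedge()
  cf <- c(1000, 900, -12, 0.05)
  sat <- 19600 # between cubic(32) = 19150 and cubic(36) = 20180
  img <- render_step_wedge(spec, cf, saturation_gv = sat, noise_sd = 0)
  m9 <- mean(rect_extract_for_test(img, spec$step_rects[[9]]))
  m10 <- mean(rect_extract_for_test(img, spec$step_rects[[10]]))
  expect_equal(m9, sat)
  expect_equal(m10, sat)
  m8 <- mean(rect_extract_for_test(img, spec$step_rects[[8]]))
  expect_lt(m8, sat)
})

test_that("noisy wedge rendering is reproducible for a fixed seed", {
  spec <- small_wedge()
  a <- render_step_wedge(spec, c(1000, 900, -12, 0.05), 19600, noise_sd = 2,
                         seed = 11)
  b <- render_step_wedge(spec, c(1000, 900, -12, 0.05), 19600, noise_sd = 2,
                         seed = 11)
  expect_identical(a, b)
})

test_that("a decreasing wedge response is rejected", {
  expect_error(
    render_step_wedge(small_wedge(), c(1000, -50, 0, 0), Inf, 0),
    class = "radbone_configuration_error")
})

test_that("identity contrast with zero gain is a no-op", {
  img <- make_fbm_texture(32, 32, 0.5, 1, 5000, 100, seed = 2)
  out <- apply_clinical_pp(abs(img), pp_params(curve = "identity", gain = 0))
  expect_equal(out, abs(img))
  expect_error(pp_params(gain = -1), class = "radbone_invalid_parameter")
  expect_error(pp_params(blur_sigma_px = 0), class = "radbone_invalid_parameter")
})

test_that("monotone contrast preserves the rank order of step means", {
  spec <- small_wedge()
  img <- render_step_wedge(spec, c(1000, 900, -12, 0.05), Inf, noise_sd = 5,
                           seed = 3)
  out <- apply_clinical_pp(img, pp_params(gain = 0))
  means_in <- vapply(spec$step_rects,
                     function(r) mean(rect_extract_for_test(img, r)), numeric(1))
  means_out <- vapply(spec$step_rects,
                      function(r) mean(rect_extract_for_test(out, r)), numeric(1))
  expect_identical(order(means_in), order(means_out))
})

test_that("clinical processing perturbs coarse-scale FD more than fine-scale", {
  shifts <- vapply(1:10, function(s) {
    img <- make_fbm_texture(256, 256, 0.35, 1, 12000, 200, seed = s)
    f0 <- fsa_roi(img, 0.148)
    f1 <- fsa_roi(apply_clinical_pp(img, pp_params()), 0.148)
    d <- function(sig0, sig1) sig1$fd_local_by_scale_mm - sig0$fd_local_by_scale_mm
    (d(f0$vertical, f1$vertical) + d(f0$horizontal, f1$horizontal)) / 2
  }, numeric(4))
  shift_030 <- abs(mean(shifts[1, ]))
  shift_074 <- abs(mean(shifts[4, ]))
  expect_gt(shift_074, shift_030)
})

test_that("an empty cohort is empty and a populated one is deterministic", {
  empty <- generate_cohort(small_cohort_config(n_per_group = c(0L, 0L, 0L)))
  expect_length(empty$subjects, 0)
  expect_equal(nrow(empty$truth), 0)

  c1 <- generate_cohort(small_cohort_config(n_per_group = c(2L, 1L, 1L), seed = 9))
  c2 <- generate_cohort(small_cohort_config(n_per_group = c(2L, 1L, 1L), seed = 9))
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$subjects[[3]]$minimal$pixels, c2$subjects[[3]]$minimal$pixels)
  expect_identical(c1$subjects[[2]]$clinical$pixels, c2$subjects[[2]]$clinical$pixels)
})

test_that("measured medial subchondral density is ordered control < OA < BML", {
  cfg <- small_cohort_config(n_per_group = c(12L, 12L, 12L), seed = 21,
                             texture_sd_gv = 60)
  co <- generate_cohort(cfg)
  feats <- extract_features(co, "minimal")
  subj <- unique(co$truth[, c("subject_id", "group")])
  by_group <- tapply(feats$gv_mmal_medial_SB[match(subj$subject_id, feats$subject_id)],
                     subj$group, mean, na.rm = TRUE)
  # injected band means are 26.9 / 29.2 / 29.6; with n = 12 per group the
  # control group must sit clearly below the two disease groups, and the
  # recovered means must be near the truth-table group means
  truth_means <- tapply(
    co$truth$true_density_mmal[co$truth$roi_name == "medial_SB"],
    subj$group, mean)
  expect_equal(unname(by_group), unname(truth_means), tolerance = 0.02)
  expect_lt(by_group[["0"]], by_group[["1"]])
  expect_lt(by_group[["0"]], by_group[["2"]])
})

test_that("zero-noise generation reproduces the wedge response at the ROI mean", {
  cfg <- small_cohort_config(n_per_group = c(1L, 0L, 0L), seed = 5,
                             background_noise_sd = 0, wedge_noise_sd = 0)
  co <- generate_cohort(cfg)
  rg <- co$subjects[[1]]$minimal
  for (i in c(1, 5, 12)) {
    truth <- co$truth$true_density_mmal[co$truth$roi_name == co$rois$roi_name[i]]
    expected_gv <- cubic_for_test(cfg$response_coeffs, truth)
    measured_gv <- mean(extract_roi(rg, co$rois[i, ]))
    expect_lt(abs(measured_gv - expected_gv), 0.5)
  }
})

test_that("the truth table survives a CSV round trip", {
  co <- generate_cohort(small_cohort_config(n_per_group = c(2L, 1L, 1L), seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(co$truth, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(co$truth), tolerance = 1e-12)
})

test_that("a ROI overlapping the wedge is a layout error", {
  lm_bad <- landmarks(medial_border_px = 200, lateral_border_px = 530,
                      spine_apex_px = c(80, 300),
                      plate_row_medial_px = 90, plate_row_lateral_px = 90,
                      dense_band_bottom_row_px = 170)
  cfg <- small_cohort_config()
  cfg$lm <- lm_bad # grid now reaches into the wedge columns
  expect_error(generate_cohort(cfg), class = "radbone_layout_error")
})
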