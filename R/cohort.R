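#' Default group-wise density and roughness parameters
#'
#' Per-ROI-band aluminum-equivalent density means and SDs (mm Al) for the
#' three study groups: 0 = control (no radiographic OA), 1 = radiographic
#' knee OA without medial tibial bone marrow lesion, 2 = medial tibial
#' BML. Subchondral-bone and medial-grid values are anchored to published
#' group summaries of calibrated density in knee OA (medial subchondral
#' bone 26.9/29.2/29.6 mm Al; the strongest medial grid ROI
#' 20.1/22.3/24.0 mm Al); the lateral bands, where disease effects are
#' small, are flat across groups.
#'
#' @return Tibble with columns `band, mean_g0..mean_g2, sd_g0..sd_g2`.
#' @export
default_density_table <- function() {
  tibble(
    band = c("medial_SB", "lateral_SB", "grid_medial", "grid_lateral"),
    mean_g0 = c(26.9, 24.5, 20.1, 23.0),
    mean_g1 = c(29.2, 25.0, 22.3, 23.2),
    mean_g2 = c(29.6, 25.2, 24.0, 23.2),
    sd_g0 = c(3.1, 3.0, 2.1, 2.5),
    sd_g1 = c(4.7, 3.0, 2.9, 2.5),
    sd_g2 = c(4.5, 3.0, 4.0, 2.5)
  )
}

# band of a ROI under the default numbering: grid columns 1..4 from the
# medial edge are "medial", 5..8 "lateral"; numbering is top row first.
roi_band <- function(roi_name) {
  ifelse(roi_name %in% c("medial_SB", "lateral_SB"), roi_name,
    ifelse(((suppressWarnings(as.integer(sub("^ROI", "", roi_name))) - 1L) %% 8L) < 4L,
           "grid_medial", "grid_lateral"))
}

#' Configuration for a synthetic radiograph cohort
#'
#' Bundles everything [generate_cohort()] needs: group sizes, the
#' group-wise density and Hurst-roughness parameters, the step-wedge
#' geometry and grayscale response, the clinical post-processing
#' parameters, covariate distributions, and the seed. Defaults define the
#' reference study conditions: groups of 20/15/10 subjects, 0.148 mm
#' pixels, a 10-step 4--40 mm wedge fitted on its 8 thinnest steps with
#' the 2 thickest saturated, and group Hurst exponents in the medial
#' bands (0.35/0.32/0.29) chosen so fractal dimension rises with disease
#' as published vertical fractal signatures do (FD close to 3 - H).
#'
#' @param n_per_group Counts `c(control, OA_no_BML, BML)`, each >= 0.
#' @param density_table Band-wise density means/SDs;
#'   see [default_density_table()].
#' @param hurst_medial,hurst_lateral Per-group Hurst exponents (length 3,
#'   each in (0,1)) for the medial and lateral bands.
#' @param anisotropy Texture anisotropy ratio passed to
#'   [make_fbm_texture()]; default 1 (isotropic) because the closed-form
#'   FD = 3 - H ground truth holds for isotropic surfaces.
#' @param texture_sd_gv Texture SD in intensity units.
#' @param wedge [step_wedge_spec()] of the embedded phantom.
#' @param response_coeffs Cubic thickness-to-grayscale wedge response.
#' @param saturation_gv Detector saturation grayscale; the default sits
#'   between the responses of steps 8 and 9, so the 2 thickest steps clip.
#' @param wedge_noise_sd,background_noise_sd Gaussian noise SDs.
#' @param background_gv Soft-tissue background grayscale.
#' @param image_dim Canvas `c(n_rows, n_cols)` in pixels.
#' @param pixel_size_mm Pixel edge (mm).
#' @param lm [landmarks()] used for ROI placement.
#' @param layout [roi_layout()] geometry.
#' @param pp [pp_params()] of the simulated clinical post-processing.
#' @param age_mean,age_sd,bmi_mean,bmi_sd Per-group covariate normals
#'   (length 3); defaults follow published OA cohort summaries.
#' @param p_female Per-group probability of female sex.
#' @param seed Integer seed; the cohort is a pure function of the config.
#'
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_per_group = c(20L, 15L, 10L),
                          density_table = default_density_table(),
                          hurst_medial = c(0.35, 0.32, 0.29),
                          hurst_lateral = c(0.35, 0.35, 0.35),
                          anisotropy = 1,
                          texture_sd_gv = 200,
                          wedge = step_wedge_spec(),
                          response_coeffs = c(1000, 900, -12, 0.05),
                          saturation_gv = 19600,
                          wedge_noise_sd = 30,
                          background_gv = 3000,
                          background_noise_sd = 30,
                          image_dim = c(720L, 900L),
                          pixel_size_mm = 0.148,
                          lm = default_landmarks(),
                          layout = roi_layout(),
                          pp = pp_params(),
                          age_mean = c(56.4, 58.3, 60.8),
                          age_sd = c(6.3, 5.5, 4.4),
                          bmi_mean = c(25.0, 28.1, 30.9),
                          bmi_sd = c(2.5, 3.8, 5.8),
                          p_female = c(0.5, 0.5, 0.5),
                          seed = 1L) {
  if (length(n_per_group) != 3L || any(n_per_group < 0)) {
    abort("`n_per_group` must be 3 nonnegative counts.",
          class = "radbone_invalid_parameter")
  }
  stopifnot(inherits(wedge, "step_wedge_spec"), inherits(pp, "pp_params"),
            inherits(lm, "landmarks"))
  if (any(hurst_medial <= 0 | hurst_medial >= 1) ||
      any(hurst_lateral <= 0 | hurst_lateral >= 1)) {
    abort("Hurst exponents must lie strictly in (0, 1).",
          class = "radbone_invalid_parameter")
  }
  check_number(texture_sd_gv, "texture_sd_gv", min = 1e-9)
  check_number(wedge_noise_sd, "wedge_noise_sd", min = 0)
  check_number(background_noise_sd, "background_noise_sd", min = 0)
  check_wedge_response(response_coeffs, range(wedge$step_thicknesses_mm))
  structure(
    list(n_per_group = as.integer(n_per_group),
         density_table = density_table,
         hurst_medial = hurst_medial, hurst_lateral = hurst_lateral,
         anisotropy = anisotropy, texture_sd_gv = texture_sd_gv,
         wedge = wedge, response_coeffs = response_coeffs,
         saturation_gv = saturation_gv, wedge_noise_sd = wedge_noise_sd,
         background_gv = background_gv,
         background_noise_sd = background_noise_sd,
         image_dim = as.integer(image_dim), pixel_size_mm = pixel_size_mm,
         lm = lm, layout = layout, pp = pp,
         age_mean = age_mean, age_sd = age_sd,
         bmi_mean = bmi_mean, bmi_sd = bmi_sd, p_female = p_female,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Default landmarks matching the default synthetic canvas
#'
#' Chosen so that on the 720 x 900 px default canvas the 18 ROIs sit left
#' of, and disjoint from, the default step wedge (columns 700+).
#' @return A [landmarks()] object.
#' @export
default_landmarks <- function() {
  landmarks(medial_border_px = 60, lateral_border_px = 660,
            spine_apex_px = c(150, 360),
            plate_row_medial_px = 170, plate_row_lateral_px = 170,
            dense_band_bottom_row_px = 330)
}

#' Generate a seeded synthetic radiograph cohort
#'
#' For each subject, composes a minimally processed radiograph: a noisy
#' soft-tissue background, one fractional-Brownian texture patch per ROI
#' whose local mean grayscale is the wedge response evaluated at the
#' subject's true aluminum-equivalent density and whose Hurst exponent
#' follows the subject's group, and the embedded step wedge (with
#' saturation of its thickest steps). The clinical-processing variant is
#' [apply_clinical_pp()] of the minimal image. Covariates (age, sex, BMI)
#' are drawn from group-specific normals. Ground truth for every ROI is
#' returned alongside the images.
#'
#' @param config A [cohort_config()].
#' @return A `radbone_cohort` object: list with `subjects` (each holding
#'   `minimal` and `clinical` [radiograph()]s), `truth` (tibble, one row
#'   per subject x ROI: group, covariates, true density and Hurst
#'   exponents), `rois` (the [place_rois()] tibble) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  rois <- place_rois(config$lm, config$pixel_size_mm, config$layout,
                     image_dim = config$image_dim)
  # the wedge must not collide with any ROI
  for (i in seq_len(nrow(rois))) {
    roi_rect <- as.numeric(rois[i, c("row0", "col0", "n_rows", "n_cols")])
    for (wrect in config$wedge$step_rects) {
      if (!rects_disjoint(roi_rect, wrect)) {
        abort(sprintf("ROI %s overlaps a wedge step rectangle.",
                      rois$roi_name[i]),
              class = "radbone_layout_error")
      }
      if (!rect_in_bounds(wrect, config$image_dim[1], config$image_dim[2])) {
        abort("wedge step rectangle exits the image.",
              class = "radbone_layout_error")
      }
    }
  }

  n_total <- sum(config$n_per_group)
  groups <- rep(0:2, times = config$n_per_group)
  fit_th <- config$wedge$step_thicknesses_mm[seq_len(config$wedge$n_steps_fit)]
  density_clamp <- range(fit_th) + c(0.5, -0.5)

  subjects <- vector("list", n_total)
  truth_rows <- vector("list", n_total)
  if (n_total > 0) {
    subject_seeds <- withr::with_seed(config$seed,
      sample.int(.Machine$integer.max - 1L, n_total))
    bands <- roi_band(rois$roi_name)
    dens_tab <- config$density_table
    for (s in seq_len(n_total)) {
      g <- groups[s]
      id <- sprintf("S%03d", s)
      drawn <- withr::with_seed(subject_seeds[s], {
        list(
          age = rnorm(1, config$age_mean[g + 1], config$age_sd[g + 1]),
          sex = if (runif(1) < config$p_female[g + 1]) "F" else "M",
          bmi = rnorm(1, config$bmi_mean[g + 1], config$bmi_sd[g + 1]),
          dens = {
            idx <- match(bands, dens_tab$band)
            rnorm(nrow(rois),
                  dens_tab[[paste0("mean_g", g)]][idx],
                  dens_tab[[paste0("sd_g", g)]][idx])
          }
        )
      })
      dens <- pmin(pmax(drawn$dens, density_clamp[1]), density_clamp[2])
      hurst <- ifelse(bands %in% c("medial_SB", "grid_medial"),
                      config$hurst_medial[g + 1], config$hurst_lateral[g + 1])

      img <- withr::with_seed(subject_seeds[s] %% 1000003L + 7L,
        matrix(config$background_gv +
                 rnorm(prod(config$image_dim), sd = config$background_noise_sd),
               config$image_dim[1], config$image_dim[2]))
      for (i in seq_len(nrow(rois))) {
        rect <- as.numeric(rois[i, c("row0", "col0", "n_rows", "n_cols")])
        tex <- make_fbm_texture(
          rect[3], rect[4], hurst = hurst[i], anisotropy = config$anisotropy,
          mean_gv = cubic_eval(config$response_coeffs, dens[i]),
          sd_gv = config$texture_sd_gv,
          seed = (as.numeric(subject_seeds[s]) + 131 * i) %% 2147483629)
        img <- rect_assign(img, rect, tex)
      }
      wimg <- render_step_wedge(
        config$wedge, config$response_coeffs, config$saturation_gv,
        config$wedge_noise_sd, seed = subject_seeds[s] %% 999983L + 11L,
        canvas_dim = config$image_dim)
      for (wrect in config$wedge$step_rects) {
        img <- rect_assign(img, wrect, rect_extract(wimg, wrect))
      }
      minimal_px <- pmin(pmax(round(img), 0), 65535)
      clinical_px <- pmin(pmax(round(apply_clinical_pp(minimal_px, config$pp)),
                               0), 65535)
      subjects[[s]] <- list(
        minimal = radiograph(minimal_px, config$pixel_size_mm, "minimal", id),
        clinical = radiograph(clinical_px, config$pixel_size_mm, "clinical", id)
      )
      truth_rows[[s]] <- tibble(
        subject_id = id, group = g, age = drawn$age, sex = drawn$sex,
        bmi = drawn$bmi, roi_name = rois$roi_name,
        true_density_mmal = dens,
        true_hurst_vertical = hurst, true_hurst_horizontal = hurst)
    }
  }
  truth <- if (n_total > 0) dplyr::bind_rows(truth_rows) else
    tibble(subject_id = character(), group = integer(), age = numeric(),
           sex = character(), bmi = numeric(), roi_name = character(),
           true_density_mmal = numeric(), true_hurst_vertical = numeric(),
           true_hurst_horizontal = numeric())
  structure(list(subjects = subjects, truth = truth, rois = rois,
                 config = config),
            class = "radbone_cohort")
}

#' @method print radbone_cohort
#' @export
print.radbone_cohort <- function(x, ...) {
  cat(sprintf("<radbone_cohort> %d subjects (groups %s), %d ROIs, %d x %d px\n",
              length(x$subjects),
              paste(x$config$n_per_group, collapse = "/"),
              nrow(x$rois), x$config$image_dim[1], x$config$image_dim[2]))
  invisible(x)
}

#' Write a cohort to disk as TIFF pairs, truth table and layout
#'
#' Writes `<id>_minimal.tif` and `<id>_clinical.tif` per subject (16-bit
#' grayscale), `truth.csv`, and `layout.json` describing the ROI and
#' wedge-step rectangles (0-based, half-open) and the pixel size.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "radbone_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sub in cohort$subjects) {
    write_radiograph(sub$minimal,
                     file.path(dir, paste0(sub$minimal$subject_id, "_minimal.tif")))
    write_radiograph(sub$clinical,
                     file.path(dir, paste0(sub$clinical$subject_id, "_clinical.tif")))
  }
  readr::write_csv(cohort$truth, file.path(dir, "truth.csv"))
  layout <- list(
    rect_convention = "c(row0, col0, n_rows, n_cols), 0-based, half-open",
    pixel_size_mm = cohort$config$pixel_size_mm,
    rois = cohort$rois,
    wedge = list(step_thicknesses_mm = cohort$config$wedge$step_thicknesses_mm,
                 step_rects = cohort$config$wedge$step_rects,
                 n_steps_fit = cohort$config$wedge$n_steps_fit)
  )
  jsonlite::write_json(layout, file.path(dir, "layout.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
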