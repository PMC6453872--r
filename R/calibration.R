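#' Mean grayscale value of an ROI
#'
#' The first of the two density readouts: the plain arithmetic mean
#' grayscale (GV) over all ROI pixels. GV depends on the image's
#' post-processing; its wedge-calibrated counterpart (GV_mmAl, see
#' [gv_to_mmal()]) is what transfers between processing modes.
#'
#' @param roi_pixels Nonempty numeric matrix (or vector) of intensities.
#' @return Scalar mean intensity.
#' @export
mean_gv <- function(roi_pixels) {
  if (length(roi_pixels) == 0L || !is.numeric(roi_pixels)) {
    abort("`roi_pixels` must be a nonempty numeric array.",
          class = "radbone_invalid_parameter")
  }
  if (any(!is.finite(roi_pixels))) {
    abort("`roi_pixels` contains non-finite values.",
          class = "radbone_invalid_parameter")
  }
  mean(roi_pixels)
}

#' Fit the step-wedge calibration cubic
#'
#' Computes the mean grayscale of each wedge step over its rectangle and
#' fits a third-order polynomial (least squares) to thickness versus mean
#' grayscale of the `n_steps_fit` thinnest steps. The thickest steps are
#' deliberately not fitted: on real detectors they saturate. The fitted
#' cubic is checked for monotonicity on a 0.001 mm grid over the fitted
#' thickness range; a non-monotone fit is flagged (`monotone = FALSE`)
#' and inversion falls back to nearest-value search either way.
#'
#' @param wedge_image Numeric matrix containing the rendered/imaged wedge.
#' @param spec A [step_wedge_spec()].
#' @return A `calibration_curve` object: cubic coefficients `coeffs`
#'   (c0..c3), `fit_thicknesses_mm`, `fit_gvs`, `all_thicknesses_mm`,
#'   `all_gvs`, `valid_range_mm` and the `monotone` flag.
#' @export
fit_wedge_curve <- function(wedge_image, spec) {
  check_matrix(wedge_image, "wedge_image")
  stopifnot(inherits(spec, "step_wedge_spec"))
  if (spec$n_steps_fit < 4L) {
    abort("cubic calibration needs at least 4 fitted steps.",
          class = "radbone_invalid_parameter")
  }
  for (r in spec$step_rects) {
    if (!rect_in_bounds(r, nrow(wedge_image), ncol(wedge_image))) {
      abort("a wedge step rect lies outside the image.",
            class = "radbone_layout_error")
    }
  }
  all_gvs <- vapply(spec$step_rects,
                    function(r) mean(rect_extract(wedge_image, r)),
                    numeric(1))
  keep <- seq_len(spec$n_steps_fit)
  th <- spec$step_thicknesses_mm[keep]
  gv <- all_gvs[keep]
  fit <- lm(gv ~ th + I(th^2) + I(th^3))
  coeffs <- unname(coef(fit))
  valid_range <- range(th)
  grid <- seq(valid_range[1], valid_range[2], by = 0.001)
  monotone <- !any(diff(cubic_eval(coeffs, grid)) < 0)
  structure(
    list(coeffs = coeffs, fit_thicknesses_mm = th, fit_gvs = gv,
         all_thicknesses_mm = spec$step_thicknesses_mm, all_gvs = all_gvs,
         valid_range_mm = valid_range, monotone = monotone),
    class = "calibration_curve"
  )
}

#' @method print calibration_curve
#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> gv = %.4g + %.4g t + %.4g t^2 + %.4g t^3  (t in [%g, %g] mm)%s\n",
    x$coeffs[1], x$coeffs[2], x$coeffs[3], x$coeffs[4],
    x$valid_range_mm[1], x$valid_range_mm[2],
    if (x$monotone) "" else "  [non-monotone fit]"))
  invisible(x)
}

#' Invert the calibration curve: grayscale to mm of aluminum
#'
#' Evaluates the fitted cubic on a 0.001 mm grid over the fitted
#' thickness range and returns the thickness whose predicted grayscale is
#' nearest the measured GV. A GV above the curve's maximum (or below its
#' minimum) on that range is never extrapolated: the ROI is excluded with
#' reason `"out-of-range"` — the same rule that excludes a subchondral
#' ROI brighter than the brightest unfitted wedge step in real data.
#'
#' @param curve A [fit_wedge_curve()] result.
#' @param gv Finite measured mean grayscale.
#' @return A one-row tibble: `gv, gv_mmal, excluded, exclusion_reason`
#'   (`gv_mmal` is `NA` iff `excluded`).
#' @export
gv_to_mmal <- function(curve, gv) {
  stopifnot(inherits(curve, "calibration_curve"))
  check_number(gv, "gv")
  grid <- seq(curve$valid_range_mm[1], curve$valid_range_mm[2], by = 0.001)
  vals <- cubic_eval(curve$coeffs, grid)
  if (gv > max(vals) || gv < min(vals)) {
    return(tibble(gv = gv, gv_mmal = NA_real_, excluded = TRUE,
                  exclusion_reason = "out-of-range"))
  }
  tibble(gv = gv, gv_mmal = grid[which.min(abs(vals - gv))],
         excluded = FALSE, exclusion_reason = NA_character_)
}

#' Calibrated density of every ROI of a radiograph
#'
#' Convenience wrapper: fits (or reuses) the image's own wedge curve,
#' then reports GV and GV_mmAl per ROI. Each image is calibrated against
#' the wedge embedded in that same image, so the calibration absorbs any
#' grayscale transform applied to the whole image.
#'
#' @param rg A [radiograph()].
#' @param rois Tibble from [place_rois()].
#' @param wedge A [step_wedge_spec()] locating the wedge in `rg`.
#' @param curve Optional precomputed [fit_wedge_curve()] result.
#' @return Tibble: `roi_name, gv, gv_mmal, excluded, exclusion_reason`.
#' @export
calibrate_rois <- function(rg, rois, wedge, curve = NULL) {
  if (is.null(curve)) curve <- fit_wedge_curve(rg$pixels, wedge)
  purrr::map_dfr(seq_len(nrow(rois)), function(i) {
    gv <- mean_gv(extract_roi(rg, rois[i, ]))
    dplyr::bind_cols(tibble(roi_name = rois$roi_name[i]), gv_to_mmal(curve, gv))
  })
}

#' @rdname fit_wedge_curve
#' @param x A `calibration_curve`.
#' @param ... Unused.
#' @method tidy calibration_curve
#' @export
tidy.calibration_curve <- function(x, ...) {
  tibble(
    thickness_mm = x$all_thicknesses_mm,
    gv = x$all_gvs,
    fitted_gv = cubic_eval(x$coeffs, x$all_thicknesses_mm),
    used_in_fit = seq_along(x$all_thicknesses_mm) <= length(x$fit_thicknesses_mm)
  ) |>
    dplyr::mutate(residual = ifelse(.data$used_in_fit,
                                    .data$gv - .data$fitted_gv, NA_real_))
}

#' @rdname fit_wedge_curve
#' @method glance calibration_curve
#' @export
glance.calibration_curve <- function(x, ...) {
  tibble(c0 = x$coeffs[1], c1 = x$coeffs[2], c2 = x$coeffs[3],
         c3 = x$coeffs[4], n_steps_fit = length(x$fit_thicknesses_mm),
         valid_min_mm = x$valid_range_mm[1],
         valid_max_mm = x$valid_range_mm[2], monotone = x$monotone)
}

#' @rdname fit_wedge_curve
#' @param object A `calibration_curve`.
#' @method autoplot calibration_curve
#' @export
autoplot.calibration_curve <- function(object, ...) {
  pts <- tidy(object)
  grid <- tibble(thickness_mm = seq(object$valid_range_mm[1],
                                    object$valid_range_mm[2],
                                    length.out = 200)) |>
    dplyr::mutate(gv = cubic_eval(object$coeffs, .data$thickness_mm))
  ggplot(pts, aes(x = .data$thickness_mm, y = .data$gv)) +
    geom_line(data = grid, colour = "grey40") +
    geom_point(aes(shape = .data$used_in_fit), size = 2) +
    labs(x = "aluminum thickness (mm)", y = "mean step grayscale",
         shape = "fitted",
         title = "Step-wedge calibration curve") +
    theme_minimal()
}
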