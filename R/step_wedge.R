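#' Describe an aluminum step-wedge phantom
#'
#' The step wedge is an aluminum staircase imaged alongside the knee; the
#' mean grayscale of each step of known thickness anchors the
#' grayscale-to-density calibration. The default wedge has 10 steps of
#' 4 mm increments (4--40 mm) stacked vertically, and calibration fits the
#' 8 thinnest steps: the thickest steps of a real wedge saturate the
#' detector and are left out of the fit.
#'
#' @param step_thicknesses_mm Strictly increasing per-step aluminum
#'   thicknesses in mm.
#' @param step_rects List with one rectangle `c(row0, col0, n_rows, n_cols)`
#'   per step (0-based, half-open), pairwise disjoint. The default stacks
#'   60 x 120 px rectangles downward from `(50, 700)`.
#' @param n_steps_fit Number of thinnest steps used when fitting the
#'   calibration cubic (default 8).
#'
#' @return A `step_wedge_spec` list.
#' @seealso [render_step_wedge()], [fit_wedge_curve()]
#' @export
step_wedge_spec <- function(step_thicknesses_mm = seq(4, 40, by = 4),
                            step_rects = default_step_rects(length(step_thicknesses_mm)),
                            n_steps_fit = 8L) {
  n <- length(step_thicknesses_mm)
  if (n < 2L || any(!is.finite(step_thicknesses_mm)) ||
      any(diff(step_thicknesses_mm) <= 0)) {
    abort("`step_thicknesses_mm` must be strictly increasing and finite.",
          class = "radbone_invalid_parameter")
  }
  if (length(step_rects) != n || !all(vapply(step_rects, rect_ok, logical(1)))) {
    abort("`step_rects` must hold one valid rect per step.",
          class = "radbone_invalid_parameter")
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (!rects_disjoint(step_rects[[i]], step_rects[[j]])) {
        abort(sprintf("step rects %d and %d overlap.", i, j),
              class = "radbone_layout_error")
      }
    }
  }
  check_number(n_steps_fit, "n_steps_fit", min = 1, max = n)
  structure(
    list(step_thicknesses_mm = as.numeric(step_thicknesses_mm),
         step_rects = lapply(step_rects, as.numeric),
         n_steps_fit = as.integer(n_steps_fit)),
    class = "step_wedge_spec"
  )
}

#' @rdname step_wedge_spec
#' @param n_steps Number of steps.
#' @param row0,col0 Top-left corner of the first (thinnest) step.
#' @param step_h,step_w Per-step rectangle height and width in px.
#' @export
default_step_rects <- function(n_steps, row0 = 50, col0 = 700,
                               step_h = 60, step_w = 120) {
  lapply(seq_len(n_steps) - 1L, function(i) c(row0 + i * step_h, col0, step_h, step_w))
}

#' Render a step-wedge image with detector saturation
#'
#' Fills each step rectangle with the wedge response
#' `min(cubic(thickness), saturation_gv)` plus Gaussian noise. With the
#' default 10-step wedge and a saturation level set between the responses
#' of steps 8 and 9, the two thickest steps clip to the same saturated
#' grayscale — the situation that forces real calibrations to drop them.
#'
#' @param spec A [step_wedge_spec()].
#' @param response_coeffs Cubic coefficients `c(c0, c1, c2, c3)` mapping
#'   thickness (mm) to expected grayscale; must be nondecreasing over the
#'   wedge thickness range.
#' @param saturation_gv Grayscale ceiling (use `Inf` for no saturation).
#' @param noise_sd Gaussian noise SD in intensity units (>= 0).
#' @param seed Integer seed for the noise.
#' @param canvas_dim Optional `c(n_rows, n_cols)` of the output image;
#'   defaults to the smallest canvas containing every step rect.
#' @param background_gv Grayscale used outside the step rects.
#'
#' @return Numeric matrix of the rendered wedge.
#' @export
render_step_wedge <- function(spec, response_coeffs, saturation_gv = Inf,
                              noise_sd = 0, seed = 1L, canvas_dim = NULL,
                              background_gv = 0) {
  stopifnot(inherits(spec, "step_wedge_spec"))
  check_wedge_response(response_coeffs, range(spec$step_thicknesses_mm))
  check_number(saturation_gv, "saturation_gv", allow_inf = TRUE)
  check_number(noise_sd, "noise_sd", min = 0)
  th_fit_max <- spec$step_thicknesses_mm[spec$n_steps_fit]
  if (saturation_gv <= cubic_eval(response_coeffs, th_fit_max)) {
    abort("`saturation_gv` must exceed the response at the last fitted step.",
          class = "radbone_configuration_error")
  }
  if (is.null(canvas_dim)) {
    canvas_dim <- c(
      max(vapply(spec$step_rects, function(r) r[1] + r[3], numeric(1))),
      max(vapply(spec$step_rects, function(r) r[2] + r[4], numeric(1)))
    )
  }
  img <- matrix(background_gv, canvas_dim[1], canvas_dim[2])
  withr::with_seed(as.integer(seed), {
    for (i in seq_along(spec$step_thicknesses_mm)) {
      r <- spec$step_rects[[i]]
      gv <- min(cubic_eval(response_coeffs, spec$step_thicknesses_mm[i]),
                saturation_gv)
      vals <- gv + if (noise_sd > 0) rnorm(r[3] * r[4], sd = noise_sd) else 0
      img <- rect_assign(img, r, vals)
    }
  })
  img
}

# the wedge response must be physically sensible: thicker aluminum never
# darkens the image. Checked on a fine grid over the thickness range.
check_wedge_response <- function(coeffs, th_range) {
  if (!is.numeric(coeffs) || length(coeffs) != 4L || any(!is.finite(coeffs))) {
    abort("`response_coeffs` must be 4 finite cubic coefficients c0..c3.",
          class = "radbone_invalid_parameter")
  }
  grid <- seq(th_range[1], th_range[2], length.out = 2048L)
  if (any(diff(cubic_eval(coeffs, grid)) < -1e-9)) {
    abort("wedge response cubic is not nondecreasing over the thickness range.",
          class = "radbone_configuration_error")
  }
  invisible(coeffs)
}
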