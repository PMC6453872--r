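#' Parameters for the simulated clinical post-processing transform
#'
#' Vendor "default clinical" post-processing of digital radiographs is
#' proprietary, but its qualitative behavior is public: a nonlinear
#' (sigmoidal) remap of the contrast curve followed by edge enhancement.
#' This simulator composes exactly those two ingredients: a monotone
#' logistic contrast curve and unsharp masking
#' `y + gain * (y - gaussian_blur(y))`.
#'
#' @param curve `"sigmoid"` for the logistic contrast remap, `"identity"`
#'   to leave grayscales untouched (useful to isolate the sharpening).
#' @param contrast_center,contrast_width Center and width (intensity
#'   units) of the logistic curve; `width` must be positive.
#' @param out_max Upper end of the valid intensity range (default 16-bit).
#' @param gain Unsharp-masking gain, >= 0; 0 disables sharpening.
#' @param blur_sigma_px Gaussian blur SD in pixels, > 0.
#'
#' @return A `pp_params` list.
#' @export
pp_params <- function(curve = c("sigmoid", "identity"),
                      contrast_center = 12000, contrast_width = 4000,
                      out_max = 65535, gain = 1, blur_sigma_px = 2) {
  curve <- match.arg(curve)
  check_number(contrast_center, "contrast_center")
  check_number(contrast_width, "contrast_width")
  check_number(out_max, "out_max", min = 1)
  check_number(gain, "gain")
  check_number(blur_sigma_px, "blur_sigma_px")
  if (gain < 0) {
    abort("`gain` must be >= 0.", class = "radbone_invalid_parameter")
  }
  if (blur_sigma_px <= 0 || contrast_width <= 0) {
    abort("`blur_sigma_px` and `contrast_width` must be > 0.",
          class = "radbone_invalid_parameter")
  }
  structure(list(curve = curve, contrast_center = contrast_center,
                 contrast_width = contrast_width, out_max = out_max,
                 gain = gain, blur_sigma_px = blur_sigma_px),
            class = "pp_params")
}

#' Apply simulated clinical post-processing to a radiograph image
#'
#' Deterministic: a monotone contrast remap, then unsharp masking, then a
#' clip to `[0, out_max]`. Because the contrast curve is monotone, the
#' rank order of region mean grayscales is preserved even though their
#' spacing is not — which is exactly why uncalibrated grayscale (GV)
#' decorrelates between processing modes while wedge-calibrated density
#' (GV_mmAl) does not.
#'
#' @param image Nonnegative numeric matrix.
#' @param params A [pp_params()] object.
#' @return Numeric matrix of the same dimension, clipped to the valid range.
#' @export
apply_clinical_pp <- function(image, params = pp_params()) {
  check_matrix(image)
  stopifnot(inherits(params, "pp_params"))
  if (any(image < 0)) {
    abort("`image` must be nonnegative.", class = "radbone_invalid_parameter")
  }
  y <- switch(params$curve,
    identity = image,
    sigmoid = params$out_max /
      (1 + exp(-(image - params$contrast_center) / params$contrast_width))
  )
  if (params$gain > 0) {
    y <- y + params$gain * (y - gaussian_blur(y, params$blur_sigma_px))
  }
  pmin(pmax(y, 0), params$out_max)
}

# separable Gaussian blur with edge replication; kernel truncated at 3 sigma
gaussian_blur <- function(img, sigma) {
  rad <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- dnorm(-rad:rad, sd = sigma)
  k <- k / sum(k)
  blur_1d <- function(mat) { # along columns
    n <- nrow(mat)
    padded <- mat[c(rep(1L, rad), seq_len(n), rep(n, rad)), , drop = FALSE]
    out <- matrix(0, n, ncol(mat))
    for (s in seq_along(k)) {
      out <- out + k[s] * padded[(s - 1) + seq_len(n), , drop = FALSE]
    }
    out
  }
  t(blur_1d(t(blur_1d(img))))
}
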