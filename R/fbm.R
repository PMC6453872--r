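#' Synthesize an anisotropic fractional-Brownian-like texture
#'
#' Generates a trabecular-bone-like random surface by spectral synthesis:
#' independent complex Gaussian Fourier coefficients are shaped by the
#' power-law amplitude \eqn{(f_x^2 + (a f_y)^2)^{-(H+1)/2}} (so the power
#' spectral density falls off as \eqn{|f|^{-(2H+2)}}, the spectrum of a
#' two-dimensional fractional Brownian surface with Hurst exponent
#' \eqn{H}), the DC term is zeroed, and the inverse Fourier transform is
#' rescaled affinely to the requested mean and standard deviation.
#'
#' A surface with Hurst exponent \eqn{H} has fractal dimension
#' \eqn{3 - H}: low \eqn{H} gives rough, high-complexity texture
#' (high fractal dimension), high \eqn{H} gives smooth texture. The
#' anisotropy ratio \eqn{a} shrinks the vertical-frequency content when
#' \eqn{a > 1}, elongating structures vertically, which is what knee
#' trabecular bone looks like under load.
#'
#' @param height_px,width_px Image dimensions in pixels, at least 16.
#' @param hurst Hurst exponent, strictly between 0 and 1.
#' @param anisotropy Positive frequency-scaling ratio applied to the
#'   vertical frequency axis; 1 is isotropic.
#' @param mean_gv,sd_gv Target sample mean and standard deviation of the
#'   output, in grayscale intensity units; `sd_gv` must be positive.
#' @param seed Integer seed; the output is a pure function of the
#'   arguments. The caller's RNG state is left untouched.
#'
#' @return A `height_px` x `width_px` numeric matrix with sample mean
#'   exactly `mean_gv` and sample SD exactly `sd_gv`.
#'
#' @examples
#' tex <- make_fbm_texture(64, 64, hurst = 0.35, mean_gv = 1000, sd_gv = 50,
#'                         seed = 1)
#' c(mean(tex), sd(tex))
#' @export
make_fbm_texture <- function(height_px, width_px, hurst, anisotropy = 1,
                             mean_gv = 0, sd_gv = 1, seed = 1L) {
  check_number(height_px, "height_px", min = 16)
  check_number(width_px, "width_px", min = 16)
  check_number(hurst, "hurst")
  check_number(anisotropy, "anisotropy")
  check_number(mean_gv, "mean_gv")
  check_number(sd_gv, "sd_gv")
  check_number(seed, "seed")
  if (hurst <= 0 || hurst >= 1) {
    abort("`hurst` must lie strictly between 0 and 1.",
          class = "radbone_invalid_parameter")
  }
  if (anisotropy <= 0 || sd_gv <= 0) {
    abort("`anisotropy` and `sd_gv` must be positive.",
          class = "radbone_invalid_parameter")
  }
  n <- as.integer(height_px); m <- as.integer(width_px)
  withr::with_seed(as.integer(seed), {
    fy <- fft_freq(n)
    fx <- fft_freq(m)
    amp <- outer((anisotropy * fy)^2, fx^2, "+")^(-(hurst + 1) / 2)
    amp[1, 1] <- 0 # zero DC: the mean is set by the affine step, not the spectrum
    z <- matrix(complex(real = rnorm(n * m), imaginary = rnorm(n * m)), n, m)
    surf <- Re(fft(z * amp, inverse = TRUE))
    mean_gv + sd_gv * (surf - mean(surf)) / sd(surf)
  })
}

# FFT sample frequencies in cycles per pixel (numpy fftfreq layout)
fft_freq <- function(n) {
  half <- n %/% 2
  c(0:(n - half - 1), -(half:1)) / n
}
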