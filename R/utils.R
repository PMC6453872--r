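# shared internal helpers: argument guards and the rectangle convention.
#
# Every rectangle in the package is 0-based and half-open:
#   rect = c(row0, col0, n_rows, n_cols)
# covers image rows [row0, row0 + n_rows) and columns [col0, col0 + n_cols)
# in 0-based indexing. R subsetting adds 1 internally. This single
# convention is shared by ROI layouts, wedge steps and layout.json.

check_number <- function(x, name, min = -Inf, max = Inf, allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (!allow_inf && !is.finite(x))) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "radbone_invalid_parameter")
  }
  if (x < min || x > max) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name,
                  format(min), format(max), format(x)),
          class = "radbone_invalid_parameter")
  }
  invisible(x)
}

check_matrix <- function(x, name = "image") {
  if (!is.matrix(x) || !is.numeric(x) || length(x) == 0L) {
    abort(sprintf("`%s` must be a nonempty numeric matrix.", name),
          class = "radbone_invalid_parameter")
  }
  if (!all(is.finite(x))) {
    abort(sprintf("`%s` contains non-finite values.", name),
          class = "radbone_invalid_parameter")
  }
  invisible(x)
}

# round half away from zero (base round() is banker's rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

rect_ok <- function(rect) {
  is.numeric(rect) && length(rect) == 4L && all(is.finite(rect)) &&
    all(rect == floor(rect)) && rect[1] >= 0 && rect[2] >= 0 &&
    rect[3] >= 1 && rect[4] >= 1
}

rects_disjoint <- function(a, b) {
  # half-open intervals: disjoint iff one ends before the other begins
  a[1] + a[3] <= b[1] || b[1] + b[3] <= a[1] ||
    a[2] + a[4] <= b[2] || b[2] + b[4] <= a[2]
}

rect_in_bounds <- function(rect, n_rows, n_cols) {
  rect[1] + rect[3] <= n_rows && rect[2] + rect[4] <= n_cols
}

# fill a half-open rect of a matrix
rect_assign <- function(img, rect, values) {
  img[(rect[1] + 1):(rect[1] + rect[3]),
      (rect[2] + 1):(rect[2] + rect[4])] <- values
  img
}

rect_extract <- function(img, rect) {
  img[(rect[1] + 1):(rect[1] + rect[3]),
      (rect[2] + 1):(rect[2] + rect[4]), drop = FALSE]
}

cubic_eval <- function(coeffs, t) {
  coeffs[1] + coeffs[2] * t + coeffs[3] * t^2 + coeffs[4] * t^3
}
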