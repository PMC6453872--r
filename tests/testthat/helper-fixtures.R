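# Shared fixtures: a compact cohort configuration for fast unit tests.
# The geometry is a scaled-down version of the default canvas (5 mm grid
# ROIs, 30 x 40 px wedge steps) so a 10-subject cohort generates in a
# couple of seconds; the physics (wedge response, saturation, group
# effects) is unchanged.

small_wedge <- function() {
  step_wedge_spec(
    step_thicknesses_mm = seq(4, 40, by = 4),
    step_rects = default_step_rects(10, row0 = 40, col0 = 480,
                                    step_h = 30, step_w = 40),
    n_steps_fit = 8L
  )
}

small_landmarks <- function() {
  landmarks(medial_border_px = 40, lateral_border_px = 400,
            spine_apex_px = c(80, 220),
            plate_row_medial_px = 90, plate_row_lateral_px = 90,
            dense_band_bottom_row_px = 170)
}

small_cohort_config <- function(n_per_group = c(4L, 3L, 3L), seed = 1L, ...) {
  cohort_config(
    n_per_group = n_per_group,
    wedge = small_wedge(),
    lm = small_landmarks(),
    layout = roi_layout(grid_roi_mm = 5, grid_gap_mm = 1),
    image_dim = c(420L, 560L),
    seed = seed,
    ...
  )
}

# independent re-statements of the rect and cubic conventions, so tests
# do not share code with the implementation under test
rect_extract_for_test <- function(img, rect) {
  img[(rect[1] + 1):(rect[1] + rect[3]), (rect[2] + 1):(rect[2] + rect[4]),
      drop = FALSE]
}

cubic_for_test <- function(cf, t) cf[1] + cf[2] * t + cf[3] * t^2 + cf[4] * t^3

# brute-force flat dilation/erosion oracle: naive loops, no shared code
# with blanket_volumes(). Same anchoring convention (origin offset
# floor((r-1)/2)) and the same fixed interior where the longest element
# fits.
brute_blanket_volumes <- function(img, orientation, r_max = 7L) {
  n <- nrow(img); m <- ncol(img)
  max_off <- (r_max - 1L) %/% 2L
  max_reach <- r_max - 1L - max_off
  V <- numeric(r_max)
  for (r in 2:r_max) {
    off <- (r - 1L) %/% 2L
    tot <- 0
    if (orientation == "horizontal") {
      for (i in 1:n) for (j in (max_off + 1L):(m - max_reach)) {
        win <- img[i, (j - off):(j - off + r - 1L)]
        tot <- tot + max(win) - min(win)
      }
    } else {
      for (i in (max_off + 1L):(n - max_reach)) for (j in 1:m) {
        win <- img[(i - off):(i - off + r - 1L), j]
        tot <- tot + max(win) - min(win)
      }
    }
    V[r] <- tot
  }
  V
}

# brute-force all-pairs Mann-Whitney AUC (ties count 1/2)
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}
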