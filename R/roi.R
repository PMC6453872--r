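#' Convert a rectangle in mm to pixel coordinates
#'
#' Sizes and origin are converted independently with round-half-away-from-
#' zero, so a 14 mm x 6 mm region at 0.148 mm/px becomes 95 x 41 px.
#'
#' @param origin_mm `c(row_mm, col_mm)` of the rectangle's top-left corner.
#' @param size_mm `c(height_mm, width_mm)`, both > 0.
#' @param pixel_size_mm Pixel edge in mm (> 0).
#'
#' @return Integer rect `c(row0, col0, n_rows, n_cols)`, 0-based half-open.
#' @export
mm_rect_to_px <- function(origin_mm, size_mm, pixel_size_mm) {
  check_number(pixel_size_mm, "pixel_size_mm")
  if (pixel_size_mm <= 0) {
    abort("`pixel_size_mm` must be > 0.", class = "radbone_invalid_parameter")
  }
  if (!is.numeric(size_mm) || length(size_mm) != 2L || any(!is.finite(size_mm)) ||
      any(size_mm <= 0)) {
    abort("`size_mm` must be two positive numbers.",
          class = "radbone_invalid_parameter")
  }
  if (!is.numeric(origin_mm) || length(origin_mm) != 2L || any(!is.finite(origin_mm))) {
    abort("`origin_mm` must be two finite numbers.",
          class = "radbone_invalid_parameter")
  }
  c(round_half_away(origin_mm[1] / pixel_size_mm),
    round_half_away(origin_mm[2] / pixel_size_mm),
    round_half_away(size_mm[1] / pixel_size_mm),
    round_half_away(size_mm[2] / pixel_size_mm))
}

#' Anatomical landmarks for ROI placement on a proximal tibia
#'
#' The layout is anchored to the landmarks a reader would mark on the
#' image: the outer (medial/lateral) borders of the proximal tibia, the
#' tibial spine apex, the subchondral bone plate row on each plateau, and
#' the lower boundary of the dense subchondral trabecular band. All
#' coordinates are 0-based pixels.
#'
#' @param medial_border_px,lateral_border_px Columns of the outer tibial
#'   borders, medial < lateral.
#' @param spine_apex_px `c(row, col)` of the tibial spine apex; its column
#'   must lie strictly between the two borders.
#' @param plate_row_medial_px,plate_row_lateral_px Rows of the
#'   cartilage-bone interface on the medial / lateral plateau.
#' @param dense_band_bottom_row_px Lower boundary row of the dense
#'   subchondral trabecular bone; must be below both plate rows.
#'
#' @return A `landmarks` list.
#' @export
landmarks <- function(medial_border_px, lateral_border_px, spine_apex_px,
                      plate_row_medial_px, plate_row_lateral_px,
                      dense_band_bottom_row_px) {
  for (nm in c("medial_border_px", "lateral_border_px",
               "plate_row_medial_px", "plate_row_lateral_px",
               "dense_band_bottom_row_px")) {
    check_number(get(nm), nm, min = 0)
  }
  if (!is.numeric(spine_apex_px) || length(spine_apex_px) != 2L) {
    abort("`spine_apex_px` must be c(row, col).",
          class = "radbone_invalid_parameter")
  }
  if (!(medial_border_px < spine_apex_px[2] &&
        spine_apex_px[2] < lateral_border_px)) {
    abort("need medial border < spine column < lateral border.",
          class = "radbone_invalid_parameter")
  }
  if (dense_band_bottom_row_px <= max(plate_row_medial_px, plate_row_lateral_px)) {
    abort("dense band bottom must lie below both plate rows.",
          class = "radbone_invalid_parameter")
  }
  structure(list(medial_border_px = medial_border_px,
                 lateral_border_px = lateral_border_px,
                 spine_apex_px = as.numeric(spine_apex_px),
                 plate_row_medial_px = plate_row_medial_px,
                 plate_row_lateral_px = plate_row_lateral_px,
                 dense_band_bottom_row_px = dense_band_bottom_row_px),
            class = "landmarks")
}

#' Default ROI layout geometry
#'
#' Two 14 mm x 6 mm subchondral-bone ROIs (one per plateau, horizontally
#' centered between the outer border and the tibial spine, top edge
#' immediately below the plate row) plus a 2-row x 8-column grid of square
#' 10 mm ROIs with 1 mm gaps placed below the dense subchondral band,
#' spanning medial to lateral. ROI numbering runs medial to lateral, top
#' row first (ROI1..ROI8, then ROI9..ROI16).
#'
#' @param sb_size_mm Subchondral ROI `c(height_mm, width_mm)`.
#' @param grid_roi_mm Grid ROI edge length in mm.
#' @param grid_gap_mm Gap between grid ROIs in mm.
#' @param grid_rows,grid_cols Grid dimensions.
#' @return A list of layout parameters.
#' @export
roi_layout <- function(sb_size_mm = c(6, 14), grid_roi_mm = 10,
                       grid_gap_mm = 1, grid_rows = 2L, grid_cols = 8L) {
  list(sb_size_mm = sb_size_mm, grid_roi_mm = grid_roi_mm,
       grid_gap_mm = grid_gap_mm, grid_rows = as.integer(grid_rows),
       grid_cols = as.integer(grid_cols))
}

#' Place the 18-ROI layout from landmarks
#'
#' Deterministic replacement for semi-automatic ROI placement: given
#' explicit landmarks, emits `medial_SB`, `lateral_SB` and `ROI1..ROI16`
#' as 0-based half-open pixel rectangles. Placement is translation-
#' equivariant in the landmarks.
#'
#' @param lm A [landmarks()] object.
#' @param pixel_size_mm Pixel edge in mm.
#' @param layout A [roi_layout()] list.
#' @param image_dim Optional `c(n_rows, n_cols)`; when given, any ROI
#'   leaving the image raises a layout error.
#'
#' @return A tibble with columns `roi_name, row0, col0, n_rows, n_cols`
#'   (18 rows, unique names).
#' @export
place_rois <- function(lm, pixel_size_mm = 0.148, layout = roi_layout(),
                       image_dim = NULL) {
  stopifnot(inherits(lm, "landmarks"))
  sb_px <- c(round_half_away(layout$sb_size_mm[1] / pixel_size_mm),
             round_half_away(layout$sb_size_mm[2] / pixel_size_mm))
  cell <- round_half_away(layout$grid_roi_mm / pixel_size_mm)
  gap <- round_half_away(layout$grid_gap_mm / pixel_size_mm)

  sb_rect <- function(border, plate_row) {
    center_col <- round_half_away((border + lm$spine_apex_px[2]) / 2)
    c(plate_row + 1, center_col - sb_px[2] %/% 2, sb_px[1], sb_px[2])
  }
  rois <- list(
    medial_SB = sb_rect(lm$medial_border_px, lm$plate_row_medial_px),
    lateral_SB = sb_rect(lm$lateral_border_px, lm$plate_row_lateral_px)
  )

  grid_w <- layout$grid_cols * cell + (layout$grid_cols - 1) * gap
  if (lm$medial_border_px + grid_w > lm$lateral_border_px) {
    abort(sprintf(
      "ROI grid (%d px wide) does not fit between the tibial borders (%d px).",
      grid_w, lm$lateral_border_px - lm$medial_border_px),
      class = "radbone_layout_error")
  }
  k <- 0L
  for (row in seq_len(layout$grid_rows) - 1L) {
    for (col in seq_len(layout$grid_cols) - 1L) {
      k <- k + 1L
      rois[[paste0("ROI", k)]] <- c(
        lm$dense_band_bottom_row_px + 1 + row * (cell + gap),
        lm$medial_border_px + col * (cell + gap),
        cell, cell)
    }
  }

  nm <- names(rois)
  offenders <- character(0)
  for (i in seq_along(rois)) {
    if (rois[[i]][3] < 8 || rois[[i]][4] < 8) {
      offenders <- c(offenders, sprintf("%s smaller than 8 px", nm[i]))
    }
    if (!is.null(image_dim) && !rect_in_bounds(rois[[i]], image_dim[1], image_dim[2])) {
      offenders <- c(offenders, sprintf("%s exits the image", nm[i]))
    }
    if (i < length(rois)) {
      for (j in (i + 1):length(rois)) {
        if (!rects_disjoint(rois[[i]], rois[[j]])) {
          offenders <- c(offenders, sprintf("%s overlaps %s", nm[i], nm[j]))
        }
      }
    }
  }
  if (length(offenders)) {
    abort(paste0("invalid ROI layout: ", paste(offenders, collapse = "; ")),
          class = "radbone_layout_error")
  }
  tibble(
    roi_name = nm,
    row0 = vapply(rois, `[`, numeric(1), 1),
    col0 = vapply(rois, `[`, numeric(1), 2),
    n_rows = vapply(rois, `[`, numeric(1), 3),
    n_cols = vapply(rois, `[`, numeric(1), 4)
  )
}

#' Extract an ROI pixel array from a radiograph
#'
#' @param rg A [radiograph()] object.
#' @param roi Either a one-row tibble from [place_rois()] or a rect
#'   `c(row0, col0, n_rows, n_cols)` (0-based, half-open).
#' @return Numeric matrix of shape `n_rows` x `n_cols`.
#' @export
extract_roi <- function(rg, roi) {
  stopifnot(inherits(rg, "radiograph"))
  rect <- if (is.data.frame(roi)) {
    as.numeric(roi[1, c("row0", "col0", "n_rows", "n_cols")])
  } else {
    as.numeric(roi)
  }
  if (!rect_ok(rect)) {
    abort("`roi` is not a valid rect.", class = "radbone_invalid_parameter")
  }
  if (!rect_in_bounds(rect, nrow(rg$pixels), ncol(rg$pixels))) {
    abort(sprintf("ROI [%s] exceeds the %d x %d image.",
                  paste(rect, collapse = ", "),
                  nrow(rg$pixels), ncol(rg$pixels)),
          class = "radbone_layout_error")
  }
  rect_extract(rg$pixels, rect)
}
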