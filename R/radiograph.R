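#' Construct a radiograph object
#'
#' A radiograph is a 2-D nonnegative grayscale intensity matrix plus the
#' metadata every downstream stage needs: the (square) pixel edge length
#' in mm and the post-processing mode of the image.
#'
#' @param pixels Nonnegative numeric matrix of grayscale intensities.
#' @param pixel_size_mm Square pixel edge in mm (> 0); 0.148 mm is the
#'   typical digital knee radiograph.
#' @param pp_mode `"minimal"` or `"clinical"` post-processing.
#' @param subject_id Identifier string.
#'
#' @return A `radiograph` object.
#' @export
radiograph <- function(pixels, pixel_size_mm = 0.148,
                       pp_mode = c("minimal", "clinical"),
                       subject_id = "") {
  check_matrix(pixels, "pixels")
  if (any(pixels < 0)) {
    abort("`pixels` must be nonnegative.", class = "radbone_invalid_parameter")
  }
  check_number(pixel_size_mm, "pixel_size_mm")
  if (pixel_size_mm <= 0) {
    abort("`pixel_size_mm` must be > 0.", class = "radbone_invalid_parameter")
  }
  pp_mode <- match.arg(pp_mode)
  structure(list(pixels = pixels, pixel_size_mm = pixel_size_mm,
                 pp_mode = pp_mode, subject_id = as.character(subject_id)),
            class = "radiograph")
}

#' @method print radiograph
#' @export
print.radiograph <- function(x, ...) {
  cat(sprintf("<radiograph> %s  %d x %d px @ %.3f mm  [%s PP]\n",
              if (nzchar(x$subject_id)) x$subject_id else "(unnamed)",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_mm, x$pp_mode))
  invisible(x)
}

#' Load a radiograph from a 16-bit TIFF or PNG file
#'
#' Intensities are preserved exactly as stored integers (0..65535 for
#' 16-bit, 0..255 for 8-bit); no rescaling or windowing is applied.
#' Multi-channel images are rejected. DICOM is not supported; convert to
#' 16-bit TIFF upstream.
#'
#' @param path Path to a single-channel 8/16-bit TIFF or PNG file.
#' @param pixel_size_mm Pixel edge in mm (> 0).
#' @param pp_mode Post-processing mode recorded on the object.
#' @param subject_id Identifier; defaults to the file stem.
#'
#' @return A [radiograph()] object.
#' @seealso [write_radiograph()]
#' @export
load_radiograph <- function(path, pixel_size_mm = 0.148,
                            pp_mode = c("minimal", "clinical"),
                            subject_id = NULL) {
  pp_mode <- match.arg(pp_mode)
  if (!file.exists(path)) {
    abort(sprintf("radiograph file does not exist: %s", path),
          class = "radbone_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path, as.is = TRUE),
    png = {
      if (!requireNamespace("png", quietly = TRUE)) {
        abort("reading PNG requires the 'png' package.",
              class = "radbone_io_error")
      }
      raw <- png::readPNG(path)
      # png package returns [0,1]; undo the normalization exactly
      bits <- if (max(raw) <= 1 && is.double(raw)) 16L else 8L
      round(raw * (2^bits - 1))
    },
    abort(sprintf("unsupported image format '%s': %s", ext, path),
          class = "radbone_io_error")
  )
  if (length(dim(img)) != 2L) {
    abort(sprintf("expected a single-channel image, got %d channels: %s",
                  dim(img)[3], path),
          class = "radbone_io_error")
  }
  if (is.null(subject_id)) {
    subject_id <- sub("_(minimal|clinical)$", "",
                      tools::file_path_sans_ext(basename(path)))
  }
  radiograph(matrix(as.numeric(img), nrow(img), ncol(img)),
             pixel_size_mm, pp_mode, subject_id)
}

#' Write a radiograph as a 16-bit grayscale TIFF
#'
#' Pixels are rounded to integers and clipped to 0..65535; a write/load
#' round trip of an integer-valued image is bit-identical.
#'
#' @param rg A [radiograph()] object.
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_radiograph <- function(rg, path) {
  stopifnot(inherits(rg, "radiograph"))
  px <- pmin(pmax(round(rg$pixels), 0), 65535)
  tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}
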