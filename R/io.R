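#' Read / write rasters and label masks as PNG
#'
#' Rasters are written as 8-bit RGB PNG. Label masks are written as
#' single-channel indexed PNG holding the raw class codes 0..4 (palette:
#' 0 background, 1 Bowman's space, 2 glomerular tuft, 3 crescentic,
#' 4 sclerotic); the micron calibration and origin are not stored in the
#' file and must be supplied when reading back.
#'
#' @param wsi A [wsi_raster()].
#' @param mask A [label_mask()].
#' @param path File path.
#' @param frame A [pixel_frame()] for the mask read back.
#' @param origin Micron origin for the mask read back.
#' @return Writers return `path` invisibly; readers return the object.
#' @name png_io
NULL

#' @rdname png_io
#' @export
write_raster_png <- function(wsi, path) {
  stopifnot(inherits(wsi, "wsi_raster"))
  png::writePNG(wsi$raster / 255, path)
  invisible(path)
}

#' @rdname png_io
#' @export
read_raster_png <- function(path, frame) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3), dim = c(dim(arr), 3))
  arr <- arr[, , 1:3, drop = FALSE] * 255
  storage.mode(arr) <- "integer"
  wsi_raster(arr, frame)
}

#' @rdname png_io
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  png::writePNG(mask$labels / 255, path)
  invisible(path)
}

#' @rdname png_io
#' @export
read_mask_png <- function(path, frame, origin = c(0, 0)) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  label_mask(matrix(as.integer(round_half_up(m * 255)), nrow(m), ncol(m)),
             frame, origin)
}
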