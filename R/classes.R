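#' Five-class labelling scheme for glomerular components
#'
#' Class codes used throughout the package:
#' `0` background, `1` Bowman's space, `2` glomerular tuft, `3` crescentic
#' region, `4` sclerotic region.
#'
#' @format Named integer vector of length 5.
#' @export
GLOM_CLASSES <- c(background = 0L, bowman_space = 1L, tuft = 2L,
                  crescentic = 3L, sclerotic = 4L)

#' Phantom rendering palette
#'
#' One RGB centroid per class (rows in class order 0..4), pairwise separated
#' by >= 100 intensity units so that nearest-colour classification is exact
#' on noise-free phantoms.
#'
#' @format 5 x 3 integer matrix, values in 0..255.
#' @export
GLOM_PALETTE <- matrix(
  c(255, 255, 255,   # 0 background: white
      0,   0, 255,   # 1 Bowman's space: blue
    255,   0,   0,   # 2 glomerular tuft: red
      0, 160,   0,   # 3 crescentic region: green
     90,  90,  90),  # 4 sclerotic region: grey
  nrow = 5, byrow = TRUE,
  dimnames = list(names(GLOM_CLASSES), c("r", "g", "b"))
)

#' WSI raster with micron calibration
#'
#' @param raster Numeric or integer array `[height, width, 3]`, intensities
#'   in 0..255. Row index is y (downward), column index is x (rightward).
#' @param frame A [pixel_frame()].
#' @return An object of class `wsi_raster`.
#' @export
wsi_raster <- function(raster, frame) {
  stopifnot(is.array(raster), length(dim(raster)) == 3L, dim(raster)[3] == 3L,
            inherits(frame, "pixel_frame"))
  structure(list(raster = raster, frame = frame), class = "wsi_raster")
}

#' @export
print.wsi_raster <- function(x, ...) {
  d <- dim(x$raster)
  cat(sprintf("<wsi_raster> %d x %d px at %.4g um/px (%.4g x %.4g um)\n",
              d[2], d[1], x$frame$microns_per_pixel,
              d[2] * x$frame$microns_per_pixel, d[1] * x$frame$microns_per_pixel))
  invisible(x)
}

#' Micron extent (width, height) of a WSI raster
#' @param wsi A [wsi_raster()].
#' @return Length-2 numeric `(width_um, height_um)`.
#' @export
wsi_extent <- function(wsi) {
  stopifnot(inherits(wsi, "wsi_raster"))
  d <- dim(wsi$raster)
  c(d[2], d[1]) * wsi$frame$microns_per_pixel
}

#' Per-pixel class map over the five-class scheme
#'
#' @param labels Integer matrix of class codes in `0..4`; rows are y,
#'   columns x.
#' @param frame A [pixel_frame()].
#' @param origin Length-2 micron offset `(x, y)` of the mask's top-left
#'   corner in the WSI frame.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, frame, origin = c(0, 0)) {
  stopifnot(is.matrix(labels), inherits(frame, "pixel_frame"),
            length(origin) == 2L)
  if (any(dim(labels) == 0L)) stop("label mask must have positive dimensions", call. = FALSE)
  storage.mode(labels) <- "integer"
  rng <- range(labels)
  if (rng[1] < 0L || rng[2] > 4L) {
    stop("label codes must lie in 0..4", call. = FALSE)
  }
  structure(list(labels = labels, frame = frame, origin = as.numeric(origin)),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_mask> %d x %d px at %.4g um/px, origin (%g, %g) um\n",
              d[2], d[1], x$frame$microns_per_pixel, x$origin[1], x$origin[2]))
  tab <- tabulate(x$labels + 1L, nbins = 5L)
  cat("  pixels per class:", paste(sprintf("%s=%d", names(GLOM_CLASSES), tab),
                                   collapse = " "), "\n")
  invisible(x)
}
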