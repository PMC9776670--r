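#' Pixel frame: micron calibration of a raster
#'
#' A `pixel_frame` ties a raster to physical units through its
#' microns-per-pixel calibration. Downsampling a raster by an integer factor
#' `k` multiplies `microns_per_pixel` by exactly `k`.
#'
#' @param microns_per_pixel Positive scalar, microns per pixel side.
#' @param magnification_label Free-text label, e.g. `"40x"` or `"5x"`.
#' @return An object of class `pixel_frame`.
#' @examples
#' pixel_frame(0.23, "40x")
#' @export
pixel_frame <- function(microns_per_pixel, magnification_label = "") {
  if (!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1L ||
      !is.finite(microns_per_pixel) || microns_per_pixel <= 0) {
    stop("calibration error: microns_per_pixel must be a positive finite scalar",
         call. = FALSE)
  }
  structure(
    list(microns_per_pixel = as.numeric(microns_per_pixel),
         magnification_label = as.character(magnification_label)),
    class = "pixel_frame"
  )
}

#' @export
print.pixel_frame <- function(x, ...) {
  cat(sprintf("<pixel_frame> %.4g um/px%s\n", x$microns_per_pixel,
              if (nzchar(x$magnification_label))
                paste0(" (", x$magnification_label, ")") else ""))
  invisible(x)
}

#' Downsample a pixel frame by an integer factor
#'
#' @param frame A [pixel_frame()].
#' @param k Positive integer downsampling factor.
#' @return A new `pixel_frame` with `microns_per_pixel` multiplied by `k`.
#' @export
downsample_frame <- function(frame, k) {
  stopifnot(inherits(frame, "pixel_frame"))
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("downsample factor must be an integer >= 1", call. = FALSE)
  pixel_frame(frame$microns_per_pixel * k,
              if (nzchar(frame$magnification_label))
                paste0(frame$magnification_label, "/", k) else "")
}

# round half-up (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

#' Convert micron lengths or coordinates to pixels
#'
#' Lengths intended as integer pixel counts are rounded half-up. The inverse
#' [pixel_to_micron()] satisfies a round trip within half a pixel.
#'
#' @param p Numeric vector of micron values (coordinates or lengths).
#' @param frame A [pixel_frame()].
#' @param round One of `"half_up"` (default, for pixel counts), `"floor"`,
#'   `"ceiling"` (for box origins / far edges), or `"none"`.
#' @return Numeric (or integer-valued) pixel vector.
#' @examples
#' micron_to_pixel(20, pixel_frame(0.23))   # 87
#' micron_to_pixel(2000, pixel_frame(1.84)) # 1087
#' @export
micron_to_pixel <- function(p, frame, round = c("half_up", "floor", "ceiling", "none")) {
  stopifnot(inherits(frame, "pixel_frame"))
  round <- match.arg(round)
  v <- p / frame$microns_per_pixel
  switch(round,
         half_up = round_half_up(v),
         floor = floor(v),
         ceiling = ceiling(v),
         none = v)
}

#' Convert pixels to microns
#'
#' @param px Numeric vector of pixel values.
#' @param frame A [pixel_frame()].
#' @return Micron values.
#' @export
pixel_to_micron <- function(px, frame) {
  stopifnot(inherits(frame, "pixel_frame"))
  px * frame$microns_per_pixel
}

#' Axis-aligned bounding box in the WSI micron frame
#'
#' Coordinates use the WSI convention: origin at the top-left, x rightward,
#' y downward, units microns. Boxes are half-open `[min, max)` when
#' rasterized.
#'
#' @param x_min,y_min,x_max,y_max Box edges in microns; `min < max` on both
#'   axes.
#' @return A named numeric vector of class `micron_box`.
#' @export
micron_box <- function(x_min, y_min, x_max, y_max) {
  b <- c(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
         x_max = as.numeric(x_max), y_max = as.numeric(y_max))
  if (any(!is.finite(b))) stop("box edges must be finite", call. = FALSE)
  if (b["x_min"] >= b["x_max"] || b["y_min"] >= b["y_max"]) {
    stop("invalid box: need x_min < x_max and y_min < y_max", call. = FALSE)
  }
  structure(b, class = "micron_box")
}

box_area <- function(b) {
  unname((b[["x_max"]] - b[["x_min"]]) * (b[["y_max"]] - b[["y_min"]]))
}

box_intersection_area <- function(a, b) {
  w <- min(a[["x_max"]], b[["x_max"]]) - max(a[["x_min"]], b[["x_min"]])
  h <- min(a[["y_max"]], b[["y_max"]]) - max(a[["y_min"]], b[["y_min"]])
  if (w <= 0 || h <= 0) return(0)
  w * h
}

#' Overlap ratio of two boxes (intersection over minimum area)
#'
#' The denominator is the smaller box's area, so a box fully contained in
#' another scores 1. This is the ratio used by the duplicate-detection merge
#' rule: when one glomerulus is split across window borders, one fragment box
#' is typically small and an IoU-based rule would under-trigger.
#'
#' @param a,b Boxes as [micron_box()] or length-4 numeric vectors
#'   `(x_min, y_min, x_max, y_max)`.
#' @return Scalar in `[0, 1]`; 0 when disjoint, 1 under containment.
#' @export
box_overlap_ratio <- function(a, b) {
  a <- as_box(a); b <- as_box(b)
  inter <- box_intersection_area(a, b)
  if (inter <= 0) return(0)
  inter / min(box_area(a), box_area(b))
}

#' Intersection-over-union of two boxes
#'
#' @inheritParams box_overlap_ratio
#' @return Scalar in `[0, 1]`; 1 iff the boxes are identical.
#' @export
box_iou <- function(a, b) {
  a <- as_box(a); b <- as_box(b)
  inter <- box_intersection_area(a, b)
  if (inter <= 0) return(0)
  inter / (box_area(a) + box_area(b) - inter)
}

as_box <- function(b) {
  if (inherits(b, "micron_box")) return(b)
  if (is.numeric(b) && length(b) == 4L) {
    return(micron_box(b[[1]], b[[2]], b[[3]], b[[4]]))
  }
  if (is.data.frame(b) && nrow(b) == 1L) {
    return(micron_box(b$x_min, b$y_min, b$x_max, b$y_max))
  }
  stop("cannot interpret object as a box", call. = FALSE)
}

#' Sliding-window grid over a WSI extent
#'
#' Windows are square, laid out row-by-row, left-to-right. The stride is
#' `window_side * (1 - overlap_fraction)`; the final origin per axis is
#' clamped so that the last window's far edge coincides with the WSI edge —
#' no window extends beyond the slide, and every point is covered by at least
#' one window.
#'
#' @param wsi_extent Length-2 numeric `(width, height)` in microns.
#' @param window_side Window side in microns (default 2000).
#' @param overlap_fraction Fraction of the side shared by neighbouring
#'   windows, in `[0, 1)` (default 0.10, i.e. a 200 um strip for 2000 um
#'   windows).
#' @return An object of class `window_grid` with fields `window_side`,
#'   `stride`, `extent`, and `origins` (a data.frame of `(x, y)` micron
#'   pairs in row-major order).
#' @examples
#' g <- build_window_grid(c(4000, 2000), 2000, 0.10)
#' g$origins
#' @export
build_window_grid <- function(wsi_extent, window_side = 2000, overlap_fraction = 0.10) {
  stopifnot(length(wsi_extent) == 2L, all(wsi_extent > 0), window_side > 0)
  if (!is.numeric(overlap_fraction) || overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("invalid parameter: overlap_fraction must be in [0, 1)", call. = FALSE)
  }
  stride <- window_side * (1 - overlap_fraction)
  axis_origins <- function(extent) {
    if (window_side >= extent) return(0) # single edge-clamped window
    o <- 0
    out <- numeric(0)
    while (o + window_side < extent) {
      out <- c(out, o)
      o <- o + stride
    }
    final <- extent - window_side
    if (length(out) == 0L || final > out[length(out)]) out <- c(out, final)
    out
  }
  xs <- axis_origins(wsi_extent[[1]])
  ys <- axis_origins(wsi_extent[[2]])
  origins <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  origins <- origins[order(origins$y, origins$x), , drop = FALSE] # row-major
  rownames(origins) <- NULL
  structure(
    list(window_side = window_side, stride = stride,
         extent = as.numeric(wsi_extent), origins = origins),
    class = "window_grid"
  )
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("<window_grid> %d windows of %g um (stride %g um) over %g x %g um\n",
              nrow(x$origins), x$window_side, x$stride, x$extent[1], x$extent[2]))
  invisible(x)
}

#' Convert a micron box to a half-open pixel box
#'
#' Origins are floored and far edges ceiled so the pixel box never
#' under-covers the micron box. Pixel boxes are 0-based half-open
#' `[x_min, x_max)`.
#'
#' @param box A box (see [box_overlap_ratio()] for accepted forms).
#' @param frame A [pixel_frame()].
#' @return Named numeric vector `(x_min, y_min, x_max, y_max)` in pixels.
#' @export
box_to_pixels <- function(box, frame) {
  b <- as_box(box)
  c(x_min = micron_to_pixel(b[["x_min"]], frame, "floor"),
    y_min = micron_to_pixel(b[["y_min"]], frame, "floor"),
    x_max = micron_to_pixel(b[["x_max"]], frame, "ceiling"),
    y_max = micron_to_pixel(b[["y_max"]], frame, "ceiling"))
}

#' Read / write glomerulus box tables
#'
#' CSV dialect: header `glom_id,x_min,y_min,x_max,y_max,frame`, coordinates
#' in microns in the WSI frame. A `confidence` column is preserved when
#' present.
#'
#' @param boxes Data frame with columns `glom_id, x_min, y_min, x_max, y_max`
#'   (microns) and optionally `confidence`.
#' @param path File path.
#' @param frame_label Free-text frame tag written to the `frame` column.
#' @return `read_boxes_csv` returns the box data frame; `write_boxes_csv`
#'   returns `path` invisibly.
#' @export
write_boxes_csv <- function(boxes, path, frame_label = "wsi_microns") {
  stopifnot(is.data.frame(boxes))
  cols <- c("glom_id", "x_min", "y_min", "x_max", "y_max")
  if (!all(cols %in% names(boxes))) {
    stop("box table must have columns ", paste(cols, collapse = ", "), call. = FALSE)
  }
  out <- boxes[, c(cols, intersect("confidence", names(boxes))), drop = FALSE]
  out$frame <- frame_label
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_boxes_csv
#' @export
read_boxes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("glom_id", "x_min", "y_min", "x_max", "y_max")
  if (!all(cols %in% names(df))) {
    stop("not a box table: missing columns", call. = FALSE)
  }
  df
}

#' Write detections as COCO-style JSON (pixel coordinates)
#'
#' Boxes are converted to pixels in the given frame and written as a list of
#' `{id, bbox: [x, y, width, height], score}` records with frame metadata.
#'
#' @param boxes Box data frame (micron coordinates).
#' @param path Output path.
#' @param frame A [pixel_frame()] used for the conversion.
#' @return `path`, invisibly.
#' @export
write_boxes_coco <- function(boxes, path, frame) {
  stopifnot(is.data.frame(boxes), inherits(frame, "pixel_frame"))
  anns <- lapply(seq_len(nrow(boxes)), function(i) {
    px <- box_to_pixels(boxes[i, ], frame)
    list(id = boxes$glom_id[i],
         bbox = c(px[["x_min"]], px[["y_min"]],
                  px[["x_max"]] - px[["x_min"]], px[["y_max"]] - px[["y_min"]]),
         score = if ("confidence" %in% names(boxes)) boxes$confidence[i] else 1.0)
  })
  obj <- list(
    info = list(microns_per_pixel = frame$microns_per_pixel,
                magnification_label = frame$magnification_label),
    annotations = anns
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
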