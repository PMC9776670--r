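#' Reference detector backends
#'
#' Detection backends are pluggable: a detector is any function
#' `(window_raster, frame, window)` returning a data frame
#' `x_min, y_min, x_max, y_max, confidence` in 0-based half-open
#' window-local pixel coordinates (see [scan_wsi()]). Trained neural
#' detectors plug in through the same contract. Three reference backends
#' ship with the package:
#'
#' * `detector_oracle(truth_boxes)` — returns the ground-truth boxes
#'   intersecting the window, clipped to it; for exactness tests.
#' * `detector_jitter(truth_boxes, ...)` — oracle boxes perturbed by seeded
#'   Gaussian jitter on every edge, with per-box drop and spurious-box
#'   rates; for controlled degradation tests.
#' * `detector_blob(...)` — model-free classical detector: thresholds
#'   non-background pixels (distance from white above `bg_distance`),
#'   labels connected components and returns their bounding boxes; works on
#'   the phantom palette without any ground truth.
#'
#' @param truth_boxes Data frame of ground-truth boxes in WSI microns
#'   (`x_min, y_min, x_max, y_max`).
#' @param jitter_sd SD of the Gaussian edge perturbation, microns
#'   (default 40).
#' @param drop_rate Probability of dropping each box (default 0.05).
#' @param spurious_rate Expected number of spurious ~200 um boxes per
#'   window (default 0).
#' @param seed Integer seed; the jitter detector derives a per-window
#'   stream from `seed + window index`, so a full scan is deterministic.
#' @param bg_distance RGB Euclidean distance from white above which a pixel
#'   counts as tissue (default 120).
#' @param min_area_um2 Minimum component area to report (default 2000 um^2).
#' @return A detector function.
#' @name detectors
NULL

# clip truth boxes to the window and express them in window-local pixels
window_truth_px <- function(truth_boxes, frame, window) {
  if (nrow(truth_boxes) == 0L) return(NULL)
  dm <- frame$microns_per_pixel
  wx0 <- window$origin[1]; wy0 <- window$origin[2]
  wx1 <- wx0 + window$size[1]; wy1 <- wy0 + window$size[2]
  x0 <- pmax(truth_boxes$x_min, wx0); y0 <- pmax(truth_boxes$y_min, wy0)
  x1 <- pmin(truth_boxes$x_max, wx1); y1 <- pmin(truth_boxes$y_max, wy1)
  keep <- x0 < x1 & y0 < y1
  if (!any(keep)) return(NULL)
  data.frame(x_min = (x0[keep] - wx0) / dm, y_min = (y0[keep] - wy0) / dm,
             x_max = (x1[keep] - wx0) / dm, y_max = (y1[keep] - wy0) / dm,
             confidence = 1.0)
}

#' @rdname detectors
#' @export
detector_oracle <- function(truth_boxes) {
  force(truth_boxes)
  function(window_raster, frame, window) {
    window_truth_px(truth_boxes, frame, window)
  }
}

#' @rdname detectors
#' @export
detector_jitter <- function(truth_boxes, jitter_sd = 40, drop_rate = 0.05,
                            spurious_rate = 0, seed = 1L) {
  force(truth_boxes)
  function(window_raster, frame, window) {
    withr::with_seed(seed + window$index, {
      det <- window_truth_px(truth_boxes, frame, window)
      dm <- frame$microns_per_pixel
      wpx <- dim(window_raster)[2]; hpx <- dim(window_raster)[1]
      out <- NULL
      if (!is.null(det)) {
        keep <- stats::runif(nrow(det)) >= drop_rate
        det <- det[keep, , drop = FALSE]
        if (nrow(det)) {
          j <- matrix(stats::rnorm(4 * nrow(det), 0, jitter_sd / dm), ncol = 4)
          x0 <- det$x_min + j[, 1]; y0 <- det$y_min + j[, 2]
          x1 <- det$x_max + j[, 3]; y1 <- det$y_max + j[, 4]
          out <- data.frame(x_min = pmax(0, pmin(x0, x1)),
                            y_min = pmax(0, pmin(y0, y1)),
                            x_max = pmin(wpx, pmax(x0, x1)),
                            y_max = pmin(hpx, pmax(y0, y1)),
                            confidence = stats::runif(nrow(det), 0.5, 1))
          out <- out[out$x_min < out$x_max & out$y_min < out$y_max, , drop = FALSE]
          if (!nrow(out)) out <- NULL
        }
      }
      n_spur <- stats::rpois(1, spurious_rate)
      if (n_spur > 0) {
        side <- 200 / dm
        sx <- stats::runif(n_spur, 0, max(1e-6, wpx - side))
        sy <- stats::runif(n_spur, 0, max(1e-6, hpx - side))
        spur <- data.frame(x_min = sx, y_min = sy,
                           x_max = pmin(wpx, sx + side), y_max = pmin(hpx, sy + side),
                           confidence = stats::runif(n_spur, 0.5, 1))
        out <- rbind(out, spur)
      }
      out
    })
  }
}

#' @rdname detectors
#' @export
detector_blob <- function(bg_distance = 120, min_area_um2 = 2000) {
  function(window_raster, frame, window) {
    dm <- frame$microns_per_pixel
    d2 <- (255 - window_raster[, , 1])^2 + (255 - window_raster[, , 2])^2 +
      (255 - window_raster[, , 3])^2
    tissue <- d2 > bg_distance^2
    if (!any(tissue)) return(NULL)
    lab <- EBImage::bwlabel(tissue)
    nlab <- max(lab)
    if (nlab == 0) return(NULL)
    min_px <- min_area_um2 / dm^2
    out <- list()
    for (l in seq_len(nlab)) {
      idx <- which(lab == l, arr.ind = TRUE)
      if (nrow(idx) < min_px) next
      out[[length(out) + 1L]] <- data.frame(
        x_min = min(idx[, 2]) - 1, y_min = min(idx[, 1]) - 1,
        x_max = max(idx[, 2]), y_max = max(idx[, 1]),
        confidence = 1.0)
    }
    if (!length(out)) return(NULL)
    do.call(rbind, out)
  }
}
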