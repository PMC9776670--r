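#' Crop a glomerulus from a WSI with a margin
#'
#' A margin (default 20 um, one tenth of the ~200 um glomerulus diameter)
#' is added on all four sides so the segmenter sees the tissue context just
#' outside the capsule; the effective box is clipped to the slide. The
#' returned pixel box uses floored origins and ceiled far edges, so the
#' crop never under-covers the micron box.
#'
#' @param wsi A [wsi_raster()].
#' @param box Glomerulus box (microns; any form accepted by
#'   [box_overlap_ratio()]).
#' @param margin Margin in microns (default 20).
#' @return List with `crop` (RGB array), `box_um` (the clipped effective
#'   micron box), `box_px` (0-based half-open pixel box of the crop in the
#'   WSI raster) and `frame`.
#' @examples
#' ph <- generate_phantom(phantom_spec(c(1200, 1000), n_glomeruli = 1, seed = 2))
#' cm <- crop_with_margin(ph$wsi, ph$truth_boxes[1, ])
#' dim(cm$crop)
#' @export
crop_with_margin <- function(wsi, box, margin = 20) {
  stopifnot(inherits(wsi, "wsi_raster"), margin >= 0)
  b <- as_box(box)
  ext <- wsi_extent(wsi)
  eff <- c(x_min = max(0, b[["x_min"]] - margin),
           y_min = max(0, b[["y_min"]] - margin),
           x_max = min(ext[1], b[["x_max"]] + margin),
           y_max = min(ext[2], b[["y_max"]] + margin))
  if (eff[["x_min"]] >= eff[["x_max"]] || eff[["y_min"]] >= eff[["y_max"]]) {
    stop("invalid input: box lies fully outside the WSI", call. = FALSE)
  }
  H <- dim(wsi$raster)[1]; W <- dim(wsi$raster)[2]
  px <- box_to_pixels(eff, wsi$frame)
  px[["x_max"]] <- min(px[["x_max"]], W); px[["y_max"]] <- min(px[["y_max"]], H)
  crop <- wsi$raster[(px[["y_min"]] + 1):px[["y_max"]],
                     (px[["x_min"]] + 1):px[["x_max"]], , drop = FALSE]
  list(crop = crop, box_um = eff, box_px = px, frame = wsi$frame)
}

#' Reference segmenter backends
#'
#' A segmenter is any function `(crop, frame, box_px)` returning an integer
#' label matrix (codes 0..4, see [GLOM_CLASSES]) with the same dimensions
#' as the crop; trained segmentation networks plug in through the same
#' contract. Shipped references:
#'
#' * `segmenter_oracle(truth_mask)` — reads labels straight from the
#'   ground-truth mask at the crop's position; for round-trip tests.
#' * `segmenter_palette(palette)` — nearest-palette-colour per pixel;
#'   exact on noise-free phantoms rendered with the same palette.
#' * `segmenter_noisy(noise_rate, seed, palette)` — palette segmentation
#'   with a seeded fraction of pixels flipped to a random other class; for
#'   metric degradation tests. The per-crop stream is derived from `seed`
#'   and the crop's pixel box, so a full run is deterministic.
#'
#' @param truth_mask Full-WSI [label_mask()] ground truth.
#' @param palette 5 x 3 RGB matrix in class order (default [GLOM_PALETTE]).
#' @param noise_rate Fraction of pixels whose label is corrupted.
#' @param seed Integer seed.
#' @return A segmenter function.
#' @name segmenters
NULL

#' @rdname segmenters
#' @export
segmenter_oracle <- function(truth_mask) {
  stopifnot(inherits(truth_mask, "label_mask"))
  function(crop, frame, box_px) {
    truth_mask$labels[(box_px[["y_min"]] + 1):box_px[["y_max"]],
                      (box_px[["x_min"]] + 1):box_px[["x_max"]], drop = FALSE]
  }
}

#' @rdname segmenters
#' @export
segmenter_palette <- function(palette = GLOM_PALETTE) {
  force(palette)
  function(crop, frame, box_px) {
    classify_palette(crop, palette)
  }
}

#' @rdname segmenters
#' @export
segmenter_noisy <- function(noise_rate = 0.1, seed = 1L, palette = GLOM_PALETTE) {
  function(crop, frame, box_px) {
    lab <- classify_palette(crop, palette)
    local_seed <- (seed + box_px[["x_min"]] * 7L + box_px[["y_min"]] * 13L) %% .Machine$integer.max
    withr::with_seed(as.integer(local_seed), {
      n <- length(lab)
      flip <- which(stats::runif(n) < noise_rate)
      if (length(flip)) {
        lab[flip] <- (lab[flip] + sample(1:4, length(flip), replace = TRUE)) %% 5L
      }
    })
    lab
  }
}

# nearest palette colour per pixel
classify_palette <- function(crop, palette) {
  d <- dim(crop)
  n <- d[1] * d[2]
  px <- cbind(as.numeric(crop[, , 1]), as.numeric(crop[, , 2]), as.numeric(crop[, , 3]))
  dist2 <- matrix(0, n, nrow(palette))
  for (k in seq_len(nrow(palette))) {
    dist2[, k] <- (px[, 1] - palette[k, 1])^2 + (px[, 2] - palette[k, 2])^2 +
      (px[, 3] - palette[k, 3])^2
  }
  lab <- max.col(-dist2, ties.method = "first") - 1L
  matrix(as.integer(lab), d[1], d[2])
}

#' Stitch per-glomerulus masks into a full-WSI label map
#'
#' The output is initialized to background; each glomerulus mask is written
#' at its origin. Pixels the detector never covered therefore stay
#' background. Where two crops overlap, a non-background label beats
#' background; among competing non-background labels the crop whose box
#' center is nearer wins (`rule = "nearest_center"`, ties to the lower
#' glomerulus id), or the later write wins (`rule = "last_write"`).
#'
#' @param wsi A [wsi_raster()] (provides the output dimensions and frame).
#' @param detections A [merge_boxes()] `detection_run` (or a box data
#'   frame) giving each mask's box, used for the center rule.
#' @param per_glom_masks List of [label_mask()]s, one per detection, each
#'   carrying its origin in WSI microns.
#' @param rule Overlap resolution rule (see above).
#' @return Full-WSI [label_mask()].
#' @export
stitch_masks <- function(wsi, detections, per_glom_masks,
                         rule = c("nearest_center", "last_write")) {
  stopifnot(inherits(wsi, "wsi_raster"))
  rule <- match.arg(rule)
  boxes <- if (inherits(detections, "detection_run")) detections$boxes else detections
  stopifnot(length(per_glom_masks) == nrow(boxes))
  H <- dim(wsi$raster)[1]; W <- dim(wsi$raster)[2]
  mpp <- wsi$frame$microns_per_pixel
  full <- matrix(0L, H, W)
  d2best <- NULL
  if (rule == "nearest_center" && length(per_glom_masks) > 1L) {
    d2best <- matrix(Inf, H, W)
  }
  for (g in seq_along(per_glom_masks)) {
    m <- per_glom_masks[[g]]
    stopifnot(inherits(m, "label_mask"))
    c0 <- as.integer(round_half_up(m$origin[1] / mpp))
    r0 <- as.integer(round_half_up(m$origin[2] / mpp))
    nr <- nrow(m$labels); nc <- ncol(m$labels)
    if (r0 < 0L || c0 < 0L || r0 + nr > H || c0 + nc > W) {
      stop(sprintf("contract violation: mask %d extends beyond the WSI", g),
           call. = FALSE)
    }
    rows <- (r0 + 1):(r0 + nr); cols <- (c0 + 1):(c0 + nc)
    lab <- m$labels
    nonbg <- lab != 0L
    if (!any(nonbg)) next
    cur <- full[rows, cols]
    if (is.null(d2best)) {
      write <- nonbg & (cur == 0L | rule == "last_write")
      cur[write] <- lab[write]
      full[rows, cols] <- cur
    } else {
      cx <- (boxes$x_min[g] + boxes$x_max[g]) / 2
      cy <- (boxes$y_min[g] + boxes$y_max[g]) / 2
      px <- (cols - 0.5) * mpp; py <- (rows - 0.5) * mpp
      d2 <- outer((py - cy)^2, (px - cx)^2, "+")
      curd <- d2best[rows, cols]
      write <- nonbg & (cur == 0L | d2 < curd)
      cur[write] <- lab[write]
      curd[write] <- d2[write]
      full[rows, cols] <- cur
      d2best[rows, cols] <- curd
    }
  }
  label_mask(full, wsi$frame, c(0, 0))
}

#' Run the full detection + segmentation pipeline
#'
#' Composition of the two pipeline steps: [scan_wsi()] with the sliding
#' window, [merge_boxes()] on the raw detections, [crop_with_margin()] on
#' each merged box, the segmenter on each crop, and [stitch_masks()] back
#' into WSI coordinates. Deterministic when both backends are.
#'
#' @param wsi A [wsi_raster()].
#' @param detector Detector backend (see [detectors]).
#' @param segmenter Segmenter backend (see [segmenters]).
#' @param window_side,overlap,detection_downsample Passed to [scan_wsi()].
#' @param merge_threshold Passed to [merge_boxes()].
#' @param margin Crop margin in microns (default 20).
#' @param write_margin If `TRUE` (default) predicted labels of margin
#'   pixels are written back into the composite; if `FALSE` the write-back
#'   is restricted to the unmargined detection box.
#' @param stitch_rule Overlap rule for [stitch_masks()].
#' @return List with `detections` (`detection_run`), `wsi_mask` (full-WSI
#'   [label_mask()]) and `glom_masks` (per-glomerulus [label_mask()]s).
#' @examples
#' ph <- generate_phantom(phantom_spec(c(2500, 2000), n_glomeruli = 3, seed = 5))
#' res <- run_pipeline(ph$wsi, detector_oracle(ph$truth_boxes), segmenter_palette())
#' identical(res$wsi_mask$labels, ph$truth_mask$labels)
#' @export
run_pipeline <- function(wsi, detector, segmenter,
                         window_side = 2000, overlap = 0.10,
                         detection_downsample = 8, merge_threshold = 0.35,
                         margin = 20, write_margin = TRUE,
                         stitch_rule = "nearest_center") {
  raw <- with_stage("detection", scan_wsi(wsi, detector, window_side, overlap,
                                          detection_downsample))
  run <- with_stage("merge", merge_boxes(raw, merge_threshold))
  segment_boxes(wsi, run, segmenter, margin = margin,
                write_margin = write_margin, stitch_rule = stitch_rule)
}

#' Segment a fixed set of boxes (no detection step)
#'
#' Runs the segmentation half of the pipeline on given boxes — used for
#' "segmentation alone" evaluations against ground-truth boxes, and as the
#' second stage of [run_pipeline()].
#'
#' @param wsi A [wsi_raster()].
#' @param boxes A `detection_run` or box data frame (micron coordinates;
#'   a `glom_id` column is added if absent).
#' @param segmenter Segmenter backend.
#' @inheritParams run_pipeline
#' @return Same structure as [run_pipeline()].
#' @export
segment_boxes <- function(wsi, boxes, segmenter, margin = 20,
                          write_margin = TRUE, stitch_rule = "nearest_center") {
  run <- if (inherits(boxes, "detection_run")) {
    boxes
  } else {
    b <- boxes
    if (!"glom_id" %in% names(b)) b$glom_id <- seq_len(nrow(b))
    if (!"confidence" %in% names(b)) b$confidence <- 1
    structure(list(boxes = b, provenance = as.list(seq_len(nrow(b))), threshold = NA),
              class = "detection_run")
  }
  mpp <- wsi$frame$microns_per_pixel
  masks <- vector("list", nrow(run$boxes))
  for (g in seq_len(nrow(run$boxes))) {
    cm <- with_stage("crop", crop_with_margin(wsi, run$boxes[g, ], margin))
    lab <- with_stage("segmentation", segmenter(cm$crop, wsi$frame, cm$box_px))
    if (!is.matrix(lab) || !all(dim(lab) == dim(cm$crop)[1:2])) {
      stop(sprintf("contract violation: segmenter output shape differs from crop %d", g),
           call. = FALSE)
    }
    px <- cm$box_px
    if (!write_margin) {
      # restrict write-back to the unmargined detection box
      inner <- box_to_pixels(run$boxes[g, ], wsi$frame)
      r <- (max(inner[["y_min"]], px[["y_min"]]) + 1):min(inner[["y_max"]], px[["y_max"]])
      c <- (max(inner[["x_min"]], px[["x_min"]]) + 1):min(inner[["x_max"]], px[["x_max"]])
      lab <- lab[r - px[["y_min"]], c - px[["x_min"]], drop = FALSE]
      px <- c(x_min = min(c) - 1, y_min = min(r) - 1, x_max = max(c), y_max = max(r))
    }
    masks[[g]] <- label_mask(lab, wsi$frame,
                             origin = c(px[["x_min"]], px[["y_min"]]) * mpp)
  }
  wsi_mask <- with_stage("stitch", stitch_masks(wsi, run, masks, rule = stitch_rule))
  list(detections = run, wsi_mask = wsi_mask, glom_masks = masks)
}

# wrap stage errors with stage-named context
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage: %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}
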