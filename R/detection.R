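#' Scan a WSI with a sliding-window detector
#'
#' Step 1 of the pipeline. The slide is covered by the window grid of
#' [build_window_grid()] (row-by-row, left-to-right), each window's raster
#' is extracted and downsampled by `detection_downsample` (integer stride,
#' so the detection frame has `microns_per_pixel * detection_downsample`
#' calibration — e.g. 40x to 5x for a factor of 8), and the detector is run
#' per window. Detector boxes are remapped window-local pixels -> microns ->
#' WSI microns. Output order follows grid order, then detector order.
#'
#' A detector is a function `(window_raster, frame, window)` returning a
#' data.frame `x_min, y_min, x_max, y_max, confidence` in 0-based half-open
#' window-local pixel coordinates at the detection frame. `window` is a
#' list with `index`, `origin` (pixel-aligned micron offset of the window
#' raster) and `size` (micron extent of the window raster); see
#' [detector_oracle()] for the shipped reference backends.
#'
#' @param wsi A [wsi_raster()].
#' @param detector Detector function honouring the contract above.
#' @param window_side Window side in microns (default 2000).
#' @param overlap Window overlap fraction (default 0.10).
#' @param detection_downsample Integer downsampling factor for the
#'   detection frame (default 8).
#' @return Data frame of raw detections in WSI microns:
#'   `x_min, y_min, x_max, y_max, confidence, window`.
#' @export
scan_wsi <- function(wsi, detector, window_side = 2000, overlap = 0.10,
                     detection_downsample = 8) {
  stopifnot(inherits(wsi, "wsi_raster"), is.function(detector))
  k <- as.integer(detection_downsample)
  if (is.na(k) || k < 1L) stop("detection_downsample must be an integer >= 1", call. = FALSE)
  mpp <- wsi$frame$microns_per_pixel
  det_frame <- downsample_frame(wsi$frame, k)
  grid <- build_window_grid(wsi_extent(wsi), window_side, overlap)
  H <- dim(wsi$raster)[1]; W <- dim(wsi$raster)[2]

  out <- vector("list", nrow(grid$origins))
  for (i in seq_len(nrow(grid$origins))) {
    ox <- grid$origins$x[i]; oy <- grid$origins$y[i]
    side_x <- min(grid$window_side, grid$extent[1])
    side_y <- min(grid$window_side, grid$extent[2])
    c0 <- floor(ox / mpp); c1 <- min(W, ceiling((ox + side_x) / mpp))
    r0 <- floor(oy / mpp); r1 <- min(H, ceiling((oy + side_y) / mpp))
    crop <- wsi$raster[(r0 + 1):r1, (c0 + 1):c1, , drop = FALSE]
    sub <- crop[seq(1, nrow(crop), by = k), seq(1, ncol(crop), by = k), , drop = FALSE]
    window <- list(index = i,
                   origin = c(c0, r0) * mpp,
                   size = c(ncol(crop), nrow(crop)) * mpp)
    det <- detector(sub, det_frame, window)
    if (is.null(det) || nrow(det) == 0L) next
    wpx <- dim(sub)[2]; hpx <- dim(sub)[1]
    if (any(det$x_min < 0 | det$y_min < 0 | det$x_max > wpx | det$y_max > hpx |
            det$x_min >= det$x_max | det$y_min >= det$y_max)) {
      stop(sprintf("contract violation: detector emitted a box outside window %d", i),
           call. = FALSE)
    }
    dm <- det_frame$microns_per_pixel
    out[[i]] <- data.frame(
      x_min = window$origin[1] + det$x_min * dm,
      y_min = window$origin[2] + det$y_min * dm,
      x_max = window$origin[1] + det$x_max * dm,
      y_max = window$origin[2] + det$y_max * dm,
      confidence = if ("confidence" %in% names(det)) det$confidence else 1.0,
      window = i
    )
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(x_min = numeric(0), y_min = numeric(0), x_max = numeric(0),
                      y_max = numeric(0), confidence = numeric(0), window = integer(0))
  }
  rownames(res) <- NULL
  res
}

#' Merge duplicate detections across windows
#'
#' Detections of one glomerulus split across neighbouring windows are
#' collapsed: boxes whose [box_overlap_ratio()] is at least `threshold` are
#' merged into the bounding-box union of their group, transitively, and the
#' process is iterated to a fixpoint (a newly formed union may overlap
#' further boxes). The result is independent of input order; a merged box's
#' confidence is the maximum over its constituents.
#'
#' @param raw Data frame of raw detections (micron coordinates, columns
#'   `x_min, y_min, x_max, y_max` and optionally `confidence`).
#' @param threshold Merge threshold on the overlap ratio, in `(0, 1]`
#'   (default 0.35).
#' @param strips Optional data frame of rectangles (same columns); when
#'   given, only box pairs whose intersection touches at least one strip
#'   (e.g. the inter-window overlap strips from [grid_overlap_strips()])
#'   are eligible for merging.
#' @return An object of class `detection_run`: list with `boxes` (data
#'   frame `glom_id, x_min, y_min, x_max, y_max, confidence`), `provenance`
#'   (per merged box, the row indices of its contributing raw boxes) and
#'   `threshold`.
#' @export
merge_boxes <- function(raw, threshold = 0.35, strips = NULL) {
  stopifnot(is.data.frame(raw))
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("invalid parameter: threshold must be in (0, 1]", call. = FALSE)
  }
  n <- nrow(raw)
  if (!"confidence" %in% names(raw)) raw$confidence <- rep(1, n)
  boxes <- as.matrix(raw[, c("x_min", "y_min", "x_max", "y_max")])
  conf <- raw$confidence
  prov <- as.list(seq_len(n))

  if (n > 1L) {
    repeat {
      m <- nrow(boxes)
      adj <- matrix(FALSE, m, m)
      for (i in seq_len(m - 1L)) {
        for (j in (i + 1L):m) {
          if (box_overlap_ratio(boxes[i, ], boxes[j, ]) >= threshold &&
              pair_in_strips(boxes[i, ], boxes[j, ], strips)) {
            adj[i, j] <- adj[j, i] <- TRUE
          }
        }
      }
      if (!any(adj)) break
      comp <- graph_components(adj)
      ord <- order(vapply(split(seq_len(m), comp), min, integer(1)))
      groups <- split(seq_len(m), comp)[ord]
      boxes <- do.call(rbind, lapply(groups, function(g) {
        c(min(boxes[g, 1]), min(boxes[g, 2]), max(boxes[g, 3]), max(boxes[g, 4]))
      }))
      conf <- vapply(groups, function(g) max(conf[g]), numeric(1))
      prov <- lapply(groups, function(g) sort(unique(unlist(prov[g]))))
      if (length(groups) == m) break
    }
  }

  # canonical output order, independent of input permutation
  if (nrow(boxes) > 0L) {
    ord <- order(boxes[, 1], boxes[, 2], boxes[, 3], boxes[, 4])
    boxes <- boxes[ord, , drop = FALSE]
    conf <- conf[ord]
    prov <- prov[ord]
  }
  out <- data.frame(glom_id = seq_len(nrow(boxes)),
                    x_min = boxes[, 1], y_min = boxes[, 2],
                    x_max = boxes[, 3], y_max = boxes[, 4],
                    confidence = conf)
  rownames(out) <- NULL
  structure(list(boxes = out, provenance = unname(prov), threshold = threshold),
            class = "detection_run")
}

pair_in_strips <- function(a, b, strips) {
  if (is.null(strips)) return(TRUE)
  ix_min <- max(a[1], b[1]); iy_min <- max(a[2], b[2])
  ix_max <- min(a[3], b[3]); iy_max <- min(a[4], b[4])
  for (s in seq_len(nrow(strips))) {
    if (ix_min < strips$x_max[s] && strips$x_min[s] < ix_max &&
        iy_min < strips$y_max[s] && strips$y_min[s] < iy_max) return(TRUE)
  }
  FALSE
}

# connected components of a boolean adjacency matrix (BFS)
graph_components <- function(adj) {
  m <- nrow(adj)
  comp <- integer(m)
  cur <- 0L
  for (v in seq_len(m)) {
    if (comp[v] > 0L) next
    cur <- cur + 1L
    queue <- v
    comp[v] <- cur
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[u, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Inter-window overlap strips of a grid
#'
#' Rectangles where neighbouring windows of a [build_window_grid()] overlap;
#' used with the `strips` argument of [merge_boxes()] to restrict merging
#' to window borders.
#'
#' @param grid A `window_grid`.
#' @return Data frame of strip rectangles `x_min, y_min, x_max, y_max`
#'   (microns).
#' @export
grid_overlap_strips <- function(grid) {
  stopifnot(inherits(grid, "window_grid"))
  xs <- sort(unique(grid$origins$x)); ys <- sort(unique(grid$origins$y))
  out <- list()
  if (length(xs) > 1L) {
    for (i in 2:length(xs)) {
      lo <- xs[i]; hi <- xs[i - 1] + grid$window_side
      if (hi > lo) out[[length(out) + 1L]] <-
          data.frame(x_min = lo, y_min = 0, x_max = hi, y_max = grid$extent[2])
    }
  }
  if (length(ys) > 1L) {
    for (i in 2:length(ys)) {
      lo <- ys[i]; hi <- ys[i - 1] + grid$window_side
      if (hi > lo) out[[length(out) + 1L]] <-
          data.frame(x_min = 0, y_min = lo, x_max = grid$extent[1], y_max = hi)
    }
  }
  if (!length(out)) {
    return(data.frame(x_min = numeric(0), y_min = numeric(0),
                      x_max = numeric(0), y_max = numeric(0)))
  }
  do.call(rbind, out)
}

#' @export
print.detection_run <- function(x, ...) {
  cat(sprintf("<detection_run> %d merged boxes (threshold %.2f)\n",
              nrow(x$boxes), x$threshold))
  invisible(x)
}

#' Evaluate detections against ground truth
#'
#' Greedy one-to-one matching in descending [box_iou()]: a prediction-truth
#' pair with IoU at least `match_iou` is a true positive; unmatched
#' predictions are false positives and unmatched truths false negatives.
#' Precision, recall and F1 use the 0/0 -> 0 convention.
#'
#' @param pred,truth Box data frames (`x_min, y_min, x_max, y_max` microns).
#' @param match_iou Matching threshold in `(0, 1]` (default 0.5, standard
#'   detection practice).
#' @return An object of class `detection_eval` with `true_positives`,
#'   `false_positives`, `false_negatives`, `precision`, `recall`, `f1`, and
#'   `matches` (data frame of matched pred/truth indices with IoU).
#' @export
evaluate_detection <- function(pred, truth, match_iou = 0.5) {
  if (inherits(pred, "detection_run")) pred <- pred$boxes
  stopifnot(is.data.frame(pred), is.data.frame(truth))
  if (!is.numeric(match_iou) || match_iou <= 0 || match_iou > 1) {
    stop("match_iou must be in (0, 1]", call. = FALSE)
  }
  np <- nrow(pred); nt <- nrow(truth)
  pairs <- NULL
  if (np > 0L && nt > 0L) {
    iou <- matrix(0, np, nt)
    for (i in seq_len(np)) for (j in seq_len(nt)) {
      iou[i, j] <- box_iou(as.numeric(pred[i, c("x_min", "y_min", "x_max", "y_max")]),
                           as.numeric(truth[j, c("x_min", "y_min", "x_max", "y_max")]))
    }
    cand <- which(iou >= match_iou, arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(-iou[cand], cand[, 1], cand[, 2]), , drop = FALSE]
      used_p <- logical(np); used_t <- logical(nt)
      keep <- list()
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1]; j <- cand[r, 2]
        if (!used_p[i] && !used_t[j]) {
          used_p[i] <- TRUE; used_t[j] <- TRUE
          keep[[length(keep) + 1L]] <- data.frame(pred = i, truth = j, iou = iou[i, j])
        }
      }
      pairs <- do.call(rbind, keep)
    }
  }
  tp <- if (is.null(pairs)) 0L else nrow(pairs)
  fp <- np - tp
  fn <- nt - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(
    list(true_positives = tp, false_positives = fp, false_negatives = fn,
         precision = precision, recall = recall, f1 = f1,
         matches = if (is.null(pairs))
           data.frame(pred = integer(0), truth = integer(0), iou = numeric(0))
         else pairs),
    class = "detection_eval"
  )
}

#' @export
print.detection_eval <- function(x, ...) {
  cat(sprintf("<detection_eval> TP=%d FP=%d FN=%d  precision=%.3f recall=%.3f F1=%.3f\n",
              x$true_positives, x$false_positives, x$false_negatives,
              x$precision, x$recall, x$f1))
  invisible(x)
}
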