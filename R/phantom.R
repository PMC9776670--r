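#' Specification of a phantom WSI
#'
#' Describes a synthetic slide: a white background carrying
#' `n_glomeruli` non-overlapping glomeruli, each drawn as an outer ellipse
#' (the interior of Bowman's capsule) containing a concentric tuft ellipse.
#' The ring between the two is Bowman's space; an angular sector of the tuft
#' may be converted to sclerotic tissue, and a sector of the ring to a
#' crescent. Each class is painted its palette colour (see [GLOM_PALETTE])
#' plus optional Gaussian intensity noise.
#'
#' `sclerotic_fraction_dist` / `crescent_fraction_dist` are functions
#' `n -> numeric vector in [0,1]` drawing the per-glomerulus lesion area
#' fractions (of the tuft and of the Bowman ring respectively). Use
#' `function(n) rep(0.5, n)` for a fixed fraction.
#'
#' @param wsi_extent Length-2 numeric `(width, height)` in microns.
#' @param microns_per_pixel Raster calibration (default 2 um/px, a
#'   desk-scale working resolution; scanner-native 0.23 um/px is supported
#'   but produces very large rasters).
#' @param n_glomeruli Number of glomeruli to place.
#' @param glom_diameter_mean Mean outer diameter in microns (default 200,
#'   the textbook glomerulus size).
#' @param sclerotic_fraction_dist,crescent_fraction_dist Sampling functions
#'   (see Details); defaults draw no lesions.
#' @param noise_sd Gaussian intensity noise SD in 0..255 units (default 0).
#' @param seed Integer seed; fully determines the output.
#' @param centers Optional `n_glomeruli` x 2 matrix of `(x, y)` micron
#'   centers, bypassing random placement (still checked for box overlap).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(wsi_extent = c(4000, 3000),
                         microns_per_pixel = 2,
                         n_glomeruli = 6,
                         glom_diameter_mean = 200,
                         sclerotic_fraction_dist = function(n) rep(0, n),
                         crescent_fraction_dist = function(n) rep(0, n),
                         noise_sd = 0,
                         seed = 1L,
                         centers = NULL) {
  stopifnot(length(wsi_extent) == 2L, all(wsi_extent > 0),
            microns_per_pixel > 0, n_glomeruli >= 0,
            glom_diameter_mean > 0, noise_sd >= 0,
            is.function(sclerotic_fraction_dist),
            is.function(crescent_fraction_dist))
  structure(
    list(wsi_extent = as.numeric(wsi_extent),
         microns_per_pixel = microns_per_pixel,
         n_glomeruli = as.integer(n_glomeruli),
         glom_diameter_mean = glom_diameter_mean,
         sclerotic_fraction_dist = sclerotic_fraction_dist,
         crescent_fraction_dist = crescent_fraction_dist,
         noise_sd = noise_sd,
         seed = as.integer(seed),
         centers = centers),
    class = "phantom_spec"
  )
}

# ratio of tuft semi-axes to outer (capsule) semi-axes; the ring between the
# similar concentric ellipses is Bowman's space
TUFT_SCALE <- 0.72
# minimum micron gap enforced between placed bounding boxes; exceeds twice
# the default 20 um crop margin, so margin-padded crops of distinct
# glomeruli never overlap and stitched areas are exactly conserved
PLACEMENT_GAP <- 50

#' Generate a phantom WSI with ground truth
#'
#' Deterministic given `spec$seed`. Glomeruli are placed by rejection
#' sampling of non-overlapping bounding boxes (generation fails with an
#' informative error if the extent cannot host `n_glomeruli` disjoint
#' boxes). Lesion sectors are wedges in the ellipses' parametric angle:
#' for concentric similar ellipses the enclosed area fraction equals the
#' parametric-angle fraction exactly, so a target area fraction maps to a
#' wedge in closed form (pixelation is then the only source of error).
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_wsi`: list with
#'   \describe{
#'     \item{wsi}{[wsi_raster()] of the rendered slide}
#'     \item{truth_boxes}{data.frame `glom_id, x_min, y_min, x_max, y_max`
#'       (microns)}
#'     \item{truth_mask}{full-WSI [label_mask()]}
#'     \item{per_glom_truth}{data.frame of per-glomerulus class areas (um^2),
#'       sclerotic proportion, and the target lesion fractions drawn from
#'       the spec's distributions}
#'   }
#' @examples
#' ph <- generate_phantom(phantom_spec(c(1500, 1200), n_glomeruli = 3, seed = 7))
#' ph$truth_boxes
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  mpp <- spec$microns_per_pixel
  W <- as.integer(round_half_up(spec$wsi_extent[1] / mpp))
  H <- as.integer(round_half_up(spec$wsi_extent[2] / mpp))
  frame <- pixel_frame(mpp)
  mask <- matrix(0L, nrow = H, ncol = W)
  n <- spec$n_glomeruli

  boxes <- data.frame(glom_id = integer(0), x_min = numeric(0), y_min = numeric(0),
                      x_max = numeric(0), y_max = numeric(0))
  per_glom <- data.frame(glom_id = integer(0), area_bowman = numeric(0),
                         area_tuft = numeric(0), area_crescent = numeric(0),
                         area_sclerotic = numeric(0), sclerotic_prop = numeric(0),
                         target_sclerotic_fraction = numeric(0),
                         target_crescent_fraction = numeric(0))

  if (n > 0) {
    # geometry draws
    diam <- spec$glom_diameter_mean * exp(stats::rnorm(n, 0, 0.06))
    ecc <- stats::runif(n, 0.8, 1.0)        # b/a axis ratio
    swap <- stats::runif(n) < 0.5           # randomly orient long axis
    a <- diam / 2
    b <- a * ecc
    tmp <- a
    a <- ifelse(swap, b, a)
    b <- ifelse(swap, tmp, b)
    scl_f <- pmin(1, pmax(0, spec$sclerotic_fraction_dist(n)))
    cre_f <- pmin(1, pmax(0, spec$crescent_fraction_dist(n)))
    scl_theta0 <- stats::runif(n, 0, 2 * pi)
    cre_theta0 <- stats::runif(n, 0, 2 * pi)

    centers <- place_glomeruli(spec, a, b)

    for (g in seq_len(n)) {
      cx <- centers[g, 1]; cy <- centers[g, 2]
      mask <- paint_glomerulus(mask, frame, cx, cy, a[g], b[g],
                               scl_f[g], scl_theta0[g], cre_f[g], cre_theta0[g])
      boxes[g, ] <- list(g, cx - a[g], cy - b[g], cx + a[g], cy + b[g])
    }

    # per-glomerulus truth: crop the mask by each truth box and count
    for (g in seq_len(n)) {
      px <- box_to_pixels(boxes[g, ], frame)
      rows <- (px[["y_min"]] + 1):min(px[["y_max"]], H)
      cols <- (px[["x_min"]] + 1):min(px[["x_max"]], W)
      counts <- tabulate(mask[rows, cols] + 1L, nbins = 5L)
      areas <- counts * mpp^2
      whole_tuft <- areas[3] + areas[5]
      per_glom[g, ] <- list(g, areas[2], areas[3], areas[4], areas[5],
                            if (whole_tuft > 0) areas[5] / whole_tuft else NA_real_,
                            scl_f[g], cre_f[g])
    }
  }

  raster <- render_mask(mask, spec$noise_sd)

  structure(
    list(wsi = wsi_raster(raster, frame),
         truth_boxes = boxes,
         truth_mask = label_mask(mask, frame, c(0, 0)),
         per_glom_truth = per_glom,
         spec = spec),
    class = "phantom_wsi"
  )
}

# rejection-sample non-overlapping glomerulus centers (or validate supplied ones)
place_glomeruli <- function(spec, a, b) {
  n <- spec$n_glomeruli
  ext <- spec$wsi_extent
  gap <- PLACEMENT_GAP
  if (!is.null(spec$centers)) {
    centers <- as.matrix(spec$centers)
    stopifnot(nrow(centers) == n, ncol(centers) == 2L)
  } else {
    centers <- matrix(NA_real_, n, 2)
    max_tries <- 200L * max(n, 1L)
    tries <- 0L
    for (g in seq_len(n)) {
      repeat {
        tries <- tries + 1L
        if (tries > max_tries) {
          stop(sprintf(paste0("generation error: could not place %d glomeruli with ",
                              "non-overlapping boxes in a %g x %g um extent ",
                              "(placed %d)"), n, ext[1], ext[2], g - 1L),
               call. = FALSE)
        }
        if (a[g] + gap >= ext[1] / 2 || b[g] + gap >= ext[2] / 2) {
          stop("generation error: extent too small for glomerulus diameter",
               call. = FALSE)
        }
        cx <- stats::runif(1, a[g] + gap, ext[1] - a[g] - gap)
        cy <- stats::runif(1, b[g] + gap, ext[2] - b[g] - gap)
        ok <- TRUE
        if (g > 1L) {
          for (h in seq_len(g - 1L)) {
            if (!(cx + a[g] + gap <= centers[h, 1] - a[h] ||
                  centers[h, 1] + a[h] + gap <= cx - a[g] ||
                  cy + b[g] + gap <= centers[h, 2] - b[h] ||
                  centers[h, 2] + b[h] + gap <= cy - b[g])) {
              ok <- FALSE; break
            }
          }
        }
        if (ok) { centers[g, ] <- c(cx, cy); break }
      }
    }
  }
  # supplied centers must still give disjoint boxes
  if (n > 1L) {
    for (g in 2:n) for (h in 1:(g - 1)) {
      if (!(centers[g, 1] - a[g] >= centers[h, 1] + a[h] ||
            centers[h, 1] - a[h] >= centers[g, 1] + a[g] ||
            centers[g, 2] - b[g] >= centers[h, 2] + b[h] ||
            centers[h, 2] - b[h] >= centers[g, 2] + b[g])) {
        stop("generation error: glomerulus bounding boxes overlap", call. = FALSE)
      }
    }
  }
  centers
}

# classify the pixels of one glomerulus into the local patch of `mask`
paint_glomerulus <- function(mask, frame, cx, cy, a, b,
                             scl_f, scl_theta0, cre_f, cre_theta0) {
  mpp <- frame$microns_per_pixel
  H <- nrow(mask); W <- ncol(mask)
  c0 <- max(1L, floor((cx - a) / mpp)); c1 <- min(W, ceiling((cx + a) / mpp))
  r0 <- max(1L, floor((cy - b) / mpp)); r1 <- min(H, ceiling((cy + b) / mpp))
  cols <- c0:c1; rows <- r0:r1
  # pixel-center coordinates in microns
  xs <- (cols - 0.5) * mpp
  ys <- (rows - 0.5) * mpp
  u <- outer(rep(1, length(rows)), (xs - cx) / a)
  v <- outer((ys - cy) / b, rep(1, length(cols)))
  r2 <- u^2 + v^2
  theta <- atan2(v, u) %% (2 * pi)
  in_wedge <- function(theta0, f) ((theta - theta0) %% (2 * pi)) < (2 * pi * f)
  patch <- mask[rows, cols]
  tuft <- r2 <= TUFT_SCALE^2
  ring <- r2 <= 1 & !tuft
  patch[tuft] <- GLOM_CLASSES[["tuft"]]
  patch[tuft & in_wedge(scl_theta0, scl_f)] <- GLOM_CLASSES[["sclerotic"]]
  patch[ring] <- GLOM_CLASSES[["bowman_space"]]
  patch[ring & in_wedge(cre_theta0, cre_f)] <- GLOM_CLASSES[["crescentic"]]
  mask[rows, cols] <- patch
  mask
}

# palette lookup + optional noise; returns integer array [H, W, 3]
render_mask <- function(mask, noise_sd) {
  H <- nrow(mask); W <- ncol(mask)
  raster <- array(0L, dim = c(H, W, 3))
  idx <- mask + 1L
  for (ch in 1:3) {
    plane <- matrix(GLOM_PALETTE[idx, ch], H, W)
    if (noise_sd > 0) {
      plane <- plane + stats::rnorm(H * W, 0, noise_sd)
      plane <- pmin(255, pmax(0, plane))
    }
    raster[, , ch] <- as.integer(round_half_up(plane))
  }
  raster
}

#' @export
print.phantom_wsi <- function(x, ...) {
  cat(sprintf("<phantom_wsi> %d glomeruli, extent %g x %g um, %.4g um/px, seed %d\n",
              nrow(x$truth_boxes), x$spec$wsi_extent[1], x$spec$wsi_extent[2],
              x$spec$microns_per_pixel, x$spec$seed))
  invisible(x)
}
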