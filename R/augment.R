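#' Image augmentation pipeline
#'
#' Applies an ordered list of augmentation operations to an RGB image. The
#' operation set mirrors the transforms commonly used to train
#' histopathology networks: flipping, scaling, cropping, contrast change,
#' Gaussian blurring and sharpening. All operations are deterministic; the
#' `seed` argument is accepted for forward compatibility with randomized
#' parameter sampling and is currently unused.
#'
#' Each op is a list with an `op` field and parameters:
#' \describe{
#'   \item{`flip_h`}{mirror across the vertical axis (involution)}
#'   \item{`flip_v`}{mirror across the horizontal axis (involution)}
#'   \item{`gaussian_blur`}{`sigma` (pixels); separable Gaussian, kernel
#'     mass 1, circular boundary — total intensity is conserved}
#'   \item{`sharpen`}{`amount`; unsharp mask `img + amount * (img - blur(img, 1))`}
#'   \item{`contrast`}{`factor`; scales intensities about mid-grey 127.5}
#'   \item{`scale`}{`factor`; bilinear resize, output dims =
#'     `round(dims * factor)`}
#'   \item{`crop`}{`box` = `(x_min, y_min, x_max, y_max)` in 0-based
#'     half-open pixel coordinates; must lie within the image}
#' }
#'
#' @param image Numeric/integer array `[h, w, 3]` with intensities 0..255,
#'   or a [wsi_raster()] (returned type matches the input; a cropped or
#'   scaled `wsi_raster` keeps its calibration for blur/flip/contrast ops
#'   and rescales it for `scale`).
#' @param ops List of op specifications, applied in order. Empty list is
#'   the identity.
#' @param seed Unused; reserved.
#' @return Augmented image, same container type as the input.
#' @examples
#' img <- array(runif(48, 0, 255), dim = c(4, 4, 3))
#' out <- augment(img, list(list(op = "flip_h"), list(op = "contrast", factor = 1.2)))
#' @export
augment <- function(image, ops = list(), seed = NULL) {
  is_wsi <- inherits(image, "wsi_raster")
  arr <- if (is_wsi) image$raster else image
  stopifnot(is.array(arr), length(dim(arr)) == 3L, dim(arr)[3] == 3L)
  int_in <- is.integer(arr)
  arr <- arr * 1.0 # numeric working copy
  mpp_scale <- 1.0
  for (o in ops) {
    if (is.null(o$op)) stop("invalid parameter: op entry without an 'op' field", call. = FALSE)
    arr <- switch(
      o$op,
      flip_h = arr[, rev(seq_len(dim(arr)[2])), , drop = FALSE],
      flip_v = arr[rev(seq_len(dim(arr)[1])), , , drop = FALSE],
      gaussian_blur = apply_per_channel(arr, function(m) EBImage::gblur(m, sigma = o$sigma)),
      sharpen = {
        blurred <- apply_per_channel(arr, function(m) EBImage::gblur(m, sigma = 1))
        clamp255(arr + o$amount * (arr - blurred))
      },
      contrast = clamp255((arr - 127.5) * o$factor + 127.5),
      scale = {
        d <- dim(arr)
        nh <- max(1L, as.integer(round_half_up(d[1] * o$factor)))
        nw <- max(1L, as.integer(round_half_up(d[2] * o$factor)))
        mpp_scale <- mpp_scale * (d[1] / nh)
        apply_per_channel(arr, function(m) EBImage::resize(m, w = nh, h = nw),
                          out_dim = c(nh, nw))
      },
      crop = {
        b <- o$box
        d <- dim(arr)
        if (length(b) != 4L || b[1] < 0 || b[2] < 0 || b[3] > d[2] || b[4] > d[1] ||
            b[1] >= b[3] || b[2] >= b[4]) {
          stop("invalid parameter: crop box outside image", call. = FALSE)
        }
        arr[(b[2] + 1):b[4], (b[1] + 1):b[3], , drop = FALSE]
      },
      stop(sprintf("invalid parameter: unknown augmentation op '%s'", o$op), call. = FALSE)
    )
  }
  if (int_in && all(arr == floor(arr))) storage.mode(arr) <- "integer"
  if (is_wsi) {
    wsi_raster(arr, pixel_frame(image$frame$microns_per_pixel * mpp_scale,
                                image$frame$magnification_label))
  } else {
    arr
  }
}

apply_per_channel <- function(arr, f, out_dim = dim(arr)[1:2]) {
  out <- array(0, dim = c(out_dim, 3))
  for (ch in 1:3) out[, , ch] <- f(arr[, , ch])
  out
}

clamp255 <- function(x) pmin(255, pmax(0, x))

#' Per-channel colour normalization to a reference image
#'
#' Shifts and scales each channel so its mean and standard deviation match
#' the reference tile — a minimal stain-variation correction applied before
#' detection and segmentation when slides come from different facilities.
#' The method is deliberately simple and swappable.
#'
#' @param image Array `[h, w, 3]` or [wsi_raster()].
#' @param reference Array `[h, w, 3]` or [wsi_raster()] providing target
#'   channel statistics.
#' @return Normalized image, same container type as `image`.
#' @export
normalize_color <- function(image, reference) {
  is_wsi <- inherits(image, "wsi_raster")
  arr <- if (is_wsi) image$raster else image
  ref <- if (inherits(reference, "wsi_raster")) reference$raster else reference
  out <- array(0, dim = dim(arr))
  for (ch in 1:3) {
    m <- arr[, , ch]
    s <- stats::sd(m)
    if (s == 0) s <- 1
    out[, , ch] <- clamp255((m - mean(m)) / s * stats::sd(ref[, , ch]) + mean(ref[, , ch]))
  }
  if (is_wsi) wsi_raster(out, image$frame) else out
}
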