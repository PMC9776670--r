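#' Quantify glomerular component areas
#'
#' Converts per-glomerulus label masks into physical class areas
#' (pixel counts times the squared calibration) and the sclerotic
#' proportion: sclerotic area over the whole glomerular tuft, where the
#' whole tuft is the sum of the tuft and sclerotic areas. A globally
#' sclerosed glomerulus (no remaining tuft) therefore scores 1; a
#' glomerulus with neither tuft nor sclerosis has an undefined proportion
#' (`NA`), excluded from WSI-level summaries.
#'
#' @param per_glom_masks List of [label_mask()]s (must carry calibration).
#' @param glom_ids Optional integer ids (default sequence).
#' @return Data frame `glom_id, area_bowman, area_tuft, area_crescent,
#'   area_sclerotic, whole_tuft_area, sclerotic_prop` (areas in um^2).
#' @export
quantify_glomeruli <- function(per_glom_masks, glom_ids = seq_along(per_glom_masks)) {
  stopifnot(length(glom_ids) == length(per_glom_masks))
  rows <- lapply(seq_along(per_glom_masks), function(i) {
    m <- per_glom_masks[[i]]
    stopifnot(inherits(m, "label_mask"))
    a <- m$frame$microns_per_pixel^2
    counts <- tabulate(m$labels + 1L, nbins = 5L)
    areas <- counts * a
    whole_tuft <- areas[3] + areas[5]
    data.frame(glom_id = glom_ids[i],
               area_bowman = areas[2], area_tuft = areas[3],
               area_crescent = areas[4], area_sclerotic = areas[5],
               whole_tuft_area = whole_tuft,
               sclerotic_prop = if (whole_tuft > 0) areas[5] / whole_tuft else NA_real_)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(glom_id = integer(0), area_bowman = numeric(0),
                      area_tuft = numeric(0), area_crescent = numeric(0),
                      area_sclerotic = numeric(0), whole_tuft_area = numeric(0),
                      sclerotic_prop = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' WSI-level sclerotic proportion
#'
#' `mean_of_gloms` (default) is the unweighted mean of the defined
#' per-glomerulus proportions — the "mean proportion over all glomeruli in
#' a WSI" summary used as the prognostic variable. `pooled_areas` divides
#' the summed sclerotic area by the summed whole-tuft area, weighting
#' glomeruli by size; provided for sensitivity analysis. Glomeruli with an
#' undefined proportion (no whole tuft) are excluded from the mean.
#'
#' @param quants Output of [quantify_glomeruli()].
#' @param mode Aggregation mode.
#' @return Scalar proportion in `[0, 1]`.
#' @export
wsi_sclerotic_proportion <- function(quants, mode = c("mean_of_gloms", "pooled_areas")) {
  mode <- match.arg(mode)
  if (mode == "mean_of_gloms") {
    p <- quants$sclerotic_prop[!is.na(quants$sclerotic_prop)]
    if (!length(p)) stop("undefined result: no glomerulus with a defined proportion",
                         call. = FALSE)
    mean(p)
  } else {
    tot <- sum(quants$whole_tuft_area)
    if (tot <= 0) stop("undefined result: zero total whole-tuft area", call. = FALSE)
    sum(quants$area_sclerotic) / tot
  }
}

#' Per-class intersection-over-union of two label masks
#'
#' For each class `c`: pixels labelled `c` in both masks over pixels
#' labelled `c` in either. A class absent from both masks is undefined
#' (`NA`) and excluded from the mean — scoring it 1 would inflate results
#' on lesion-free crops.
#'
#' @param pred,truth [label_mask()]s or integer matrices of identical
#'   dimensions.
#' @return Named numeric vector of length 5 (classes 0..4), `NA` for
#'   classes absent from both.
#' @seealso [mean_iou()], [pool_iou()]
#' @export
iou_per_class <- function(pred, truth) {
  p <- if (inherits(pred, "label_mask")) pred$labels else pred
  t <- if (inherits(truth, "label_mask")) truth$labels else truth
  if (!all(dim(p) == dim(t))) stop("invalid input: mask shapes differ", call. = FALSE)
  counts <- iou_counts(p, t)
  iou_from_counts(counts)
}

# joint tabulation: intersection and union pixel counts per class
iou_counts <- function(p, t) {
  joint <- tabulate(as.integer(p) * 5L + as.integer(t) + 1L, nbins = 25L)
  joint <- matrix(joint, 5, 5, byrow = TRUE) # [pred class + 1, truth class + 1]
  inter <- diag(joint)
  pred_n <- rowSums(joint)
  truth_n <- colSums(joint)
  list(inter = inter, union = pred_n + truth_n - inter)
}

iou_from_counts <- function(counts) {
  iou <- ifelse(counts$union > 0, counts$inter / counts$union, NA_real_)
  names(iou) <- names(GLOM_CLASSES)
  iou
}

#' Mean IoU over the five classes
#'
#' Unweighted mean of the defined per-class IoUs.
#'
#' @param iou Per-class IoU vector from [iou_per_class()] or [pool_iou()].
#' @return Scalar mean IoU.
#' @export
mean_iou <- function(iou) mean(iou, na.rm = TRUE)

#' Pooled (micro-averaged) per-class IoU over several mask pairs
#'
#' Intersection and union pixel counts are pooled over all pairs before
#' the ratio is taken — the within-fold aggregation used by the evaluation
#' harness.
#'
#' @param preds,truths Lists of masks/matrices, pairwise comparable.
#' @return Named per-class IoU vector.
#' @export
pool_iou <- function(preds, truths) {
  stopifnot(length(preds) == length(truths), length(preds) >= 1L)
  inter <- numeric(5); uni <- numeric(5)
  for (i in seq_along(preds)) {
    p <- if (inherits(preds[[i]], "label_mask")) preds[[i]]$labels else preds[[i]]
    t <- if (inherits(truths[[i]], "label_mask")) truths[[i]]$labels else truths[[i]]
    if (!all(dim(p) == dim(t))) stop("invalid input: mask shapes differ", call. = FALSE)
    counts <- iou_counts(p, t)
    inter <- inter + counts$inter
    uni <- uni + counts$union
  }
  iou_from_counts(list(inter = inter, union = uni))
}

#' Aggregate per-fold metrics into mean and standard error
#'
#' @param fold_values Numeric vector (one scalar metric per fold) or a
#'   matrix/data frame with one row per fold (e.g. per-class IoUs).
#' @return List with `mean`, `se` (sample SD over sqrt(k); `NA` with fewer
#'   than 2 folds) and `k`.
#' @examples
#' aggregate_folds(c(0.6, 0.8)) # mean 0.7, SE 0.1
#' @export
aggregate_folds <- function(fold_values) {
  if (is.data.frame(fold_values)) fold_values <- as.matrix(fold_values)
  if (is.matrix(fold_values)) {
    k <- nrow(fold_values)
    mu <- colMeans(fold_values, na.rm = TRUE)
    se <- if (k >= 2L) apply(fold_values, 2, stats::sd, na.rm = TRUE) / sqrt(k)
          else rep(NA_real_, ncol(fold_values))
  } else {
    k <- length(fold_values)
    mu <- mean(fold_values, na.rm = TRUE)
    se <- if (k >= 2L) stats::sd(fold_values, na.rm = TRUE) / sqrt(k) else NA_real_
  }
  list(mean = mu, se = se, k = k)
}

#' Welch's t-test for the equality of two fold-metric means
#'
#' Thin wrapper over [stats::t.test()] with unequal variances (Welch), the
#' test used to compare per-facility metric samples.
#'
#' @param a,b Numeric samples (each of size >= 2; at least one with
#'   positive variance).
#' @return List with `t`, `df` (Welch-Satterthwaite) and two-sided `p`.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("undefined result: both samples need >= 2 values", call. = FALSE)
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    stop("undefined result: both samples are constant", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Pearson correlation between ground-truth and predicted region totals
#'
#' @param truth,pred Paired per-WSI totals (e.g. sclerotic areas), length
#'   >= 3, each with positive variance.
#' @return Pearson r.
#' @export
truth_pred_correlation <- function(truth, pred) {
  if (length(truth) != length(pred) || length(truth) < 3L) {
    stop("undefined result: need >= 3 paired totals", call. = FALSE)
  }
  if (stats::sd(truth) == 0 || stats::sd(pred) == 0) {
    stop("undefined result: zero variance", call. = FALSE)
  }
  stats::cor(truth, pred)
}

#' Write a per-class IoU report table
#'
#' CSV shaped like a cross-facility performance table: one row per
#' model-to-data direction, columns for the five classes and the mean,
#' cells formatted `"mean (SE)"`.
#'
#' @param reports Named list: each element a matrix/data frame of per-fold
#'   per-class IoU rows (classes 0..4 plus optionally a mean column).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_iou_report_csv <- function(reports, path) {
  rows <- lapply(names(reports), function(nm) {
    m <- as.matrix(reports[[nm]])
    if (ncol(m) == 5L) m <- cbind(m, mean_iou = rowMeans(m, na.rm = TRUE))
    agg <- aggregate_folds(m)
    cells <- sprintf("%.3f (%.3f)", agg$mean, agg$se)
    stats::setNames(data.frame(direction = nm, t(cells)),
                    c("direction", names(GLOM_CLASSES), "mean_iou"))
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a per-glomerulus quantification table
#'
#' CSV dialect `wsi_id, glom_id, area_bowman, area_tuft, area_crescent,
#' area_sclerotic, sclerotic_prop`.
#'
#' @param quants Output of [quantify_glomeruli()].
#' @param path Output CSV path.
#' @param wsi_id Slide identifier written to each row.
#' @return `path`, invisibly.
#' @export
write_quant_csv <- function(quants, path, wsi_id = "wsi") {
  out <- cbind(wsi_id = wsi_id,
               quants[, c("glom_id", "area_bowman", "area_tuft",
                          "area_crescent", "area_sclerotic", "sclerotic_prop")])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
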