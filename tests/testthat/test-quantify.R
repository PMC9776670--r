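make_mask <- function(labels, mpp = 1) label_mask(labels, pixel_frame(mpp))

test_that("glomerular quantification follows the sclerotic-proportion formula", {
  # no sclerosis
  m0 <- make_mask(matrix(c(rep(2L, 500), rep(0L, 12)), 16, 32))
  q0 <- quantify_glomeruli(list(m0))
  expect_equal(q0$sclerotic_prop, 0)

  # sclerotic 30 px, tuft 70 px -> 0.30
  m1 <- make_mask(matrix(c(rep(4L, 30), rep(2L, 70)), 10, 10))
  q1 <- quantify_glomeruli(list(m1))
  expect_equal(q1$sclerotic_prop, 0.30)
  expect_equal(q1$whole_tuft_area, 100)

  # global sclerosis: no tuft left, proportion must be 1
  m2 <- make_mask(matrix(c(rep(4L, 400), rep(1L, 41)), 21, 21))
  expect_equal(quantify_glomeruli(list(m2))$sclerotic_prop, 1)

  # neither tuft nor sclerosis: undefined, excluded from the WSI mean
  m3 <- make_mask(matrix(c(rep(1L, 50), rep(0L, 50)), 10, 10))
  q3 <- quantify_glomeruli(list(m3, m1))
  expect_true(is.na(q3$sclerotic_prop[1]))
  expect_equal(wsi_sclerotic_proportion(q3), 0.30)

  # calibration scales areas quadratically
  q1b <- quantify_glomeruli(list(make_mask(matrix(c(rep(4L, 30), rep(2L, 70)), 10, 10),
                                           mpp = 2)))
  expect_equal(q1b$area_sclerotic, 30 * 4)
  expect_equal(q1b$sclerotic_prop, 0.30)
})

test_that("WSI-level aggregation distinguishes mean-of-glomeruli from pooled areas", {
  two <- function(p, px) make_mask(matrix(c(rep(4L, round(p * px)),
                                            rep(2L, px - round(p * px))), ncol = 1))
  # equal areas: both modes agree
  q <- quantify_glomeruli(list(two(0.2, 100), two(0.4, 100)))
  expect_equal(wsi_sclerotic_proportion(q, "mean_of_gloms"), 0.3)
  expect_equal(wsi_sclerotic_proportion(q, "pooled_areas"), 0.3)

  # proportions {0, 1}, areas {300, 100}: mean 0.5, pooled 0.25
  q2 <- quantify_glomeruli(list(two(0, 300), two(1, 100)))
  expect_equal(wsi_sclerotic_proportion(q2, "mean_of_gloms"), 0.5)
  expect_equal(wsi_sclerotic_proportion(q2, "pooled_areas"), 0.25)

  # single glomerulus: both modes equal its proportion
  q3 <- quantify_glomeruli(list(two(0.3, 200)))
  expect_equal(wsi_sclerotic_proportion(q3, "mean_of_gloms"),
               wsi_sclerotic_proportion(q3, "pooled_areas"))

  expect_error(wsi_sclerotic_proportion(q3[0, ]), "undefined result")
})

test_that("per-class IoU matches hand counts and the brute-force oracle", {
  # identity prediction: all defined classes 1, mean 1
  full <- matrix(c(0L, 1L, 2L, 3L, 4L, 0L), 2, 3)
  expect_equal(unname(iou_per_class(full, full)), c(1, 1, 1, 1, 1))
  expect_equal(mean_iou(iou_per_class(full, full)), 1)

  # hand-counted 2x2 grid: pred all background, truth half background
  pred <- matrix(0L, 2, 2)
  truth <- matrix(c(0L, 0L, 2L, 2L), 2, 2)
  iou <- iou_per_class(pred, truth)
  expect_equal(unname(iou[1]), 0.5) # background: inter 2, union 4
  expect_equal(unname(iou[3]), 0)   # tuft present only in truth
  expect_true(is.na(iou[2]))        # Bowman absent from both: excluded
  expect_equal(mean_iou(iou), 0.25)

  expect_error(iou_per_class(matrix(0L, 2, 2), matrix(0L, 3, 3)), "invalid input")

  # oracle equivalence on random 64x64 pairs
  set.seed(3)
  for (i in 1:50) {
    p <- matrix(sample(0:4, 64 * 64, TRUE), 64, 64)
    t <- matrix(sample(0:4, 64 * 64, TRUE), 64, 64)
    expect_identical(unname(iou_per_class(p, t)), oracle_iou(p, t))
  }
})

test_that("pooled IoU micro-averages pixel counts across a fold", {
  p1 <- matrix(c(2L, 2L, 0L, 0L), 2, 2); t1 <- matrix(c(2L, 0L, 0L, 0L), 2, 2)
  p2 <- matrix(2L, 2, 2);                t2 <- matrix(2L, 2, 2)
  pooled <- pool_iou(list(p1, p2), list(t1, t2))
  # tuft: inter 1+4, union 2+4
  expect_equal(unname(pooled[3]), 5 / 6)
  # differs from the macro average of per-pair IoUs (0.5 and 1)
  expect_false(isTRUE(all.equal(unname(pooled[3]), mean(c(0.5, 1)))))
})

test_that("fold aggregation reports mean and standard error", {
  agg <- aggregate_folds(c(0.6, 0.8))
  expect_equal(agg$mean, 0.7)
  expect_equal(agg$se, 0.1) # SD 0.1414 / sqrt(2)

  expect_equal(aggregate_folds(rep(0.5, 4))$se, 0)
  single <- aggregate_folds(0.9)
  expect_equal(single$mean, 0.9)
  expect_true(is.na(single$se))

  m <- aggregate_folds(rbind(c(0.6, 0.9), c(0.8, 0.7)))
  expect_equal(unname(m$mean), c(0.7, 0.8))
  expect_equal(unname(m$se), c(0.1, 0.1))
})

test_that("Welch's t-test wrapper agrees with the closed-form computation", {
  a <- c(0.60, 0.66, 0.71, 0.64)
  b <- c(0.52, 0.58, 0.55, 0.61, 0.50)
  got <- welch_t_test(a, b)
  want <- oracle_welch(a, b)
  expect_equal(got$t, want$t, tolerance = 1e-10)
  expect_equal(got$df, want$df, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)

  # identical samples: t = 0, p = 1; order-invariant
  same <- welch_t_test(c(1, 2, 3), c(3, 1, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # clearly separated samples with tiny jitter
  sep <- welch_t_test(c(0, 0, 0, 0) + 1e-6 * (1:4), c(1, 1, 1, 1) + 1e-6 * (4:1))
  expect_lt(sep$p, 0.01)

  expect_error(welch_t_test(c(1), c(1, 2)), "undefined result")
  expect_error(welch_t_test(c(1, 1), c(1, 1)), "undefined result")
})

test_that("truth/prediction correlation behaves as Pearson r", {
  x <- c(10, 20, 30, 40)
  expect_equal(truth_pred_correlation(x, x), 1)
  expect_equal(truth_pred_correlation(x, 2 * x), 1) # scale-invariant
  expect_equal(truth_pred_correlation(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_error(truth_pred_correlation(c(1, 2), c(1, 2)), "undefined result")
  expect_error(truth_pred_correlation(c(1, 1, 1), c(1, 2, 3)), "undefined result")
})

test_that("report writers produce the documented table shapes", {
  dir <- withr::local_tempdir()
  folds <- rbind(c(0.99, 0.6, 0.74, 0.5, 0.52), c(0.99, 0.63, 0.77, 0.53, 0.54))
  p1 <- file.path(dir, "iou.csv")
  write_iou_report_csv(list("T to T" = folds), p1)
  tab <- read.csv(p1, check.names = FALSE)
  expect_equal(names(tab), c("direction", names(GLOM_CLASSES), "mean_iou"))
  expect_match(tab$mean_iou[1], "^0\\.\\d+ \\(0\\.\\d+\\)$")

  q <- quantify_glomeruli(list(make_mask(matrix(c(rep(4L, 30), rep(2L, 70)), 10, 10))))
  p2 <- file.path(dir, "quant.csv")
  write_quant_csv(q, p2, wsi_id = "phantom-1")
  qt <- read.csv(p2)
  expect_equal(qt$sclerotic_prop, 0.3)
  expect_equal(qt$wsi_id, "phantom-1")
})
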