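test_that("scan_wsi remaps oracle boxes exactly and clips straddlers per window", {
  ph <- lesion_phantom(seed = 21, extent = c(2000, 2000), n = 2)
  raw <- scan_wsi(ph$wsi, detector_oracle(ph$truth_boxes))
  # single-window slide: identity remap
  expect_equal(nrow(raw), 2L)
  got <- raw[order(raw$x_min), c("x_min", "y_min", "x_max", "y_max")]
  want <- ph$truth_boxes[order(ph$truth_boxes$x_min),
                         c("x_min", "y_min", "x_max", "y_max")]
  expect_equal(unname(as.matrix(got)), unname(as.matrix(want)), tolerance = 1e-9)

  # empty-output detector
  none <- function(raster, frame, window) NULL
  expect_equal(nrow(scan_wsi(ph$wsi, none)), 0L)

  # glomerulus straddling the border between two windows: one clipped
  # fragment per window
  st <- generate_phantom(phantom_spec(c(3800, 2000), n_glomeruli = 1,
                                      glom_diameter_mean = 340, seed = 42,
                                      centers = matrix(c(1900, 1000), 1)))
  raw2 <- scan_wsi(st$wsi, detector_oracle(st$truth_boxes))
  expect_equal(nrow(raw2), 2L)
  b <- st$truth_boxes[1, ]
  expect_lt(b$x_min, 1800); expect_gt(b$x_max, 2000) # spans the 200 um strip
  frag <- raw2[order(raw2$window), ]
  expect_equal(frag$x_max[1], 2000, tolerance = 1e-9) # clipped to window 1
  expect_equal(frag$x_min[2], 1800, tolerance = 1e-9) # clipped to window 2
  expect_equal(frag$x_min[1], b$x_min, tolerance = 1e-9)
  expect_equal(frag$x_max[2], b$x_max, tolerance = 1e-9)

  # detector emitting a box outside its window is a contract violation
  bad <- function(raster, frame, window) {
    data.frame(x_min = -5, y_min = 0, x_max = 10, y_max = 10, confidence = 1)
  }
  expect_error(scan_wsi(ph$wsi, bad), "contract violation.*window 1")
})

test_that("merge_boxes matches the spec examples and reaches a clean fixpoint", {
  # disjoint boxes unchanged
  raw <- data.frame(x_min = c(0, 200), y_min = c(0, 200),
                    x_max = c(100, 300), y_max = c(100, 300))
  expect_equal(nrow(merge_boxes(raw)$boxes), 2L)

  # ratio 0.5 >= 0.35: union of extremes
  raw2 <- data.frame(x_min = c(0, 50), y_min = c(0, 0),
                     x_max = c(100, 150), y_max = c(100, 100))
  m2 <- merge_boxes(raw2, 0.35)
  expect_equal(nrow(m2$boxes), 1L)
  expect_equal(as.numeric(m2$boxes[1, c("x_min", "y_min", "x_max", "y_max")]),
               c(0, 0, 150, 100))
  expect_equal(sort(m2$provenance[[1]]), c(1L, 2L))

  # transitive chain a-b-c with ratio(a,c) = 0 collapses to one box
  chain <- data.frame(x_min = c(0, 60, 120), y_min = c(0, 0, 0),
                      x_max = c(100, 160, 220), y_max = c(100, 100, 100))
  expect_equal(box_overlap_ratio(as.numeric(chain[1, ]), as.numeric(chain[2, ])), 0.4)
  expect_equal(box_overlap_ratio(as.numeric(chain[1, ]), as.numeric(chain[3, ])), 0)
  mc <- merge_boxes(chain, 0.35)
  expect_equal(nrow(mc$boxes), 1L)
  expect_equal(as.numeric(mc$boxes[1, c("x_min", "y_min", "x_max", "y_max")]),
               c(0, 0, 220, 100))

  expect_error(merge_boxes(raw, threshold = 0), "invalid parameter")
  expect_error(merge_boxes(raw, threshold = 1.5), "invalid parameter")
})

test_that("merging is idempotent, permutation-invariant and threshold-monotone", {
  set.seed(23)
  for (trial in 1:60) {
    raw <- random_box_set(sample(2:8, 1))
    m <- merge_boxes(raw, 0.35)
    # no surviving pair still exceeds the threshold
    bb <- merged_matrix(m)
    if (nrow(bb) > 1L) {
      for (i in 1:(nrow(bb) - 1)) for (j in (i + 1):nrow(bb)) {
        expect_lt(box_overlap_ratio(bb[i, ], bb[j, ]), 0.35)
      }
    }
    # idempotent
    expect_equal(merged_matrix(merge_boxes(m$boxes, 0.35)), bb)
    # permutation-invariant
    shuf <- raw[sample(nrow(raw)), ]
    expect_equal(merged_matrix(merge_boxes(shuf, 0.35)), bb)
    # merged box confidence is the max over constituents
    for (g in seq_along(m$provenance)) {
      expect_equal(m$boxes$confidence[g], max(raw$confidence[m$provenance[[g]]]))
    }
    # raising the threshold never reduces the number of boxes
    counts <- vapply(c(0.15, 0.35, 0.6, 0.9),
                     function(th) nrow(merge_boxes(raw, th)$boxes), numeric(1))
    expect_true(!is.unsorted(counts))
  }
})

test_that("strip-restricted merging only fuses boxes at window borders", {
  grid <- build_window_grid(c(3800, 2000), 2000, 0.10)
  strips <- grid_overlap_strips(grid)
  expect_equal(nrow(strips), 1L)
  expect_equal(c(strips$x_min, strips$x_max), c(1800, 2000))
  # one pair inside the strip, one far from it; both above threshold
  raw <- data.frame(x_min = c(1850, 1870, 100, 120), y_min = c(0, 0, 0, 0),
                    x_max = c(1950, 1970, 200, 220), y_max = c(100, 100, 100, 100))
  m_global <- merge_boxes(raw, 0.35)
  m_strip <- merge_boxes(raw, 0.35, strips = strips)
  expect_equal(nrow(m_global$boxes), 2L)
  expect_equal(nrow(m_strip$boxes), 3L) # far-from-strip pair left alone
})

test_that("detection evaluation implements greedy IoU matching and F1", {
  truth <- data.frame(x_min = c(0, 200, 400), y_min = 0,
                      x_max = c(100, 300, 500), y_max = 100)
  ev1 <- evaluate_detection(truth, truth)
  expect_equal(ev1$f1, 1.0)

  ev0 <- evaluate_detection(truth[0, ], truth)
  expect_equal(ev0$recall, 0); expect_equal(ev0$f1, 0)

  # 2 of 3 truths matched exactly: precision 1, recall 2/3, F1 0.8
  ev2 <- evaluate_detection(truth[1:2, ], truth)
  expect_equal(ev2$precision, 1)
  expect_equal(ev2$recall, 2 / 3)
  expect_equal(ev2$f1, 0.8)

  # a sub-threshold overlap is both a FP and a FN
  pred <- data.frame(x_min = 80, y_min = 0, x_max = 180, y_max = 100)
  ev3 <- evaluate_detection(pred, truth[1, , drop = FALSE], match_iou = 0.5)
  expect_equal(ev3$true_positives, 0L)
  expect_equal(ev3$false_positives, 1L)
  expect_equal(ev3$false_negatives, 1L)
})

test_that("oracle pipeline detection is exact on phantoms; blob detector finds all", {
  ph <- lesion_phantom(seed = 31, extent = c(4000, 2600), n = 5)
  raw <- scan_wsi(ph$wsi, detector_oracle(ph$truth_boxes))
  run <- merge_boxes(raw, 0.35)
  ev <- evaluate_detection(run, ph$truth_boxes)
  expect_equal(ev$f1, 1.0)
  got <- merged_matrix(run)
  want <- as.matrix(ph$truth_boxes[order(ph$truth_boxes$x_min, ph$truth_boxes$y_min),
                                   c("x_min", "y_min", "x_max", "y_max")])
  expect_equal(got, unname(want), tolerance = 1e-9)

  # classical blob detector, no ground truth input
  raw_b <- scan_wsi(ph$wsi, detector_blob())
  run_b <- merge_boxes(raw_b, 0.35)
  ev_b <- evaluate_detection(run_b, ph$truth_boxes, match_iou = 0.5)
  expect_equal(ev_b$true_positives, nrow(ph$truth_boxes))
  expect_equal(ev_b$false_negatives, 0L)
})

test_that("jittered detector degrades gracefully and is seed-deterministic", {
  ph <- lesion_phantom(seed = 13, extent = c(3000, 2400), n = 4)
  det <- detector_jitter(ph$truth_boxes, jitter_sd = 40, drop_rate = 0.05, seed = 77)
  raw1 <- scan_wsi(ph$wsi, det)
  raw2 <- scan_wsi(ph$wsi, det)
  expect_identical(raw1, raw2)
  run <- merge_boxes(raw1, 0.35)
  ev <- evaluate_detection(run, ph$truth_boxes, match_iou = 0.3)
  expect_gte(ev$recall, 0.5) # jitter perturbs but rarely destroys boxes
})
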