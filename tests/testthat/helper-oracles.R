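# Independent oracles used by the tests. These deliberately use different
# algorithms / code paths than the package implementation.

# transitive-closure merge oracle: union-find over the overlap graph,
# iterated to a fixpoint (a fresh union box may create new overlaps)
oracle_merge <- function(boxes, threshold) {
  b <- as.matrix(boxes[, c("x_min", "y_min", "x_max", "y_max")])
  repeat {
    n <- nrow(b)
    if (n <= 1L) break
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    merged_any <- FALSE
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (box_overlap_ratio(b[i, ], b[j, ]) >= threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) { parent[max(ri, rj)] <- min(ri, rj); merged_any <- TRUE }
      }
    }
    if (!merged_any) break
    roots <- vapply(seq_len(n), find, integer(1))
    b <- do.call(rbind, lapply(unique(roots), function(r) {
      g <- which(roots == r)
      c(min(b[g, 1]), min(b[g, 2]), max(b[g, 3]), max(b[g, 4]))
    }))
  }
  b <- b[order(b[, 1], b[, 2], b[, 3], b[, 4]), , drop = FALSE]
  unname(b)
}

# brute-force per-class IoU on label matrices, explicit set operations
oracle_iou <- function(pred, truth) {
  vapply(0:4, function(cl) {
    u <- sum(pred == cl | truth == cl)
    if (u == 0) NA_real_ else sum(pred == cl & truth == cl) / u
  }, numeric(1))
}

# Welch's t statistic, Welch-Satterthwaite df and two-sided p, by formula
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# random boxes for merge property tests
random_box_set <- function(n, extent = 1000, min_side = 40, max_side = 300) {
  x0 <- runif(n, 0, extent - max_side)
  y0 <- runif(n, 0, extent - max_side)
  w <- runif(n, min_side, max_side)
  h <- runif(n, min_side, max_side)
  data.frame(x_min = x0, y_min = y0, x_max = x0 + w, y_max = y0 + h,
             confidence = runif(n))
}

# canonical matrix form of merged boxes for comparisons
merged_matrix <- function(run) {
  unname(as.matrix(run$boxes[, c("x_min", "y_min", "x_max", "y_max")]))
}

# two-lesion phantom used by several tests
lesion_phantom <- function(seed = 11, extent = c(3000, 2400), n = 4, noise = 0) {
  generate_phantom(phantom_spec(
    extent, n_glomeruli = n, seed = seed, noise_sd = noise,
    sclerotic_fraction_dist = function(k) rep(0.5, k),
    crescent_fraction_dist = function(k) rep(0.25, k)))
}
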