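toy_cohort <- function(pat, vis) {
  structure(list(patients = pat, visits = vis, spec = NULL), class = "glom_cohort")
}

test_that("eligibility filtering applies the three exclusion criteria", {
  pat <- data.frame(patient_id = 1:4,
                    age = c(17, 40, 50, 60),
                    sex = 1, hypertension = 0,
                    egfr0 = c(80, 14.9, 70, 60),
                    upcr = 1, sclerotic_prop = 0.05)
  vis <- data.frame(patient_id = rep(1:4, each = 3),
                    visit_time_yr = rep(c(0, 0.5, 2), 4),
                    egfr = 60)
  vis$visit_time_yr[vis$patient_id == 4] <- c(0, 0.4, 0.9) # < 1 yr follow-up
  out <- filter_eligible(toy_cohort(pat, vis))
  expect_equal(out$patients$patient_id, 3L) # age 17, eGFR 14.9, 0.9 yr dropped
  excl <- attr(out, "exclusions")
  expect_equal(unname(excl["age_lt_18"]), 1L)
  expect_equal(unname(excl["end_stage"]), 1L)
  expect_equal(unname(excl["followup_lt_1yr"]), 1L)

  # explicit end-stage flag is honoured even with eGFR >= 15
  pat$end_stage <- c(0, 0, 1, 0)
  out2 <- filter_eligible(toy_cohort(pat, vis))
  expect_equal(nrow(out2$patients), 0L)
})

test_that("eGFR slope is the OLS slope within the closed 2-year window", {
  expect_equal(egfr_slope(c(0, 1, 2), c(60, 58, 56)), -2)
  # hand OLS: sum((x - 1) * (y - 51)) / sum((x - 1)^2) = -2 / 2
  expect_equal(egfr_slope(c(0, 1, 2), c(50, 55, 48)), -1)
  # t = 3 excluded by the window; remaining points define the line
  expect_equal(egfr_slope(c(0, 1, 3), c(60, 55, 0)), -5)
  # value exactly at t = 2 is included (closed interval)
  expect_equal(egfr_slope(c(0, 2), c(60, 50)), -5)
  expect_error(egfr_slope(c(0, 3), c(60, 50)), "undefined result")
  expect_error(egfr_slope(c(1, 1), c(60, 50)), "undefined result")
})

test_that("VIF matches its closed form and flags exact collinearity", {
  # predictors orthogonal to each other and to the intercept: VIF 1
  set.seed(2)
  e <- qr.Q(qr(cbind(1, matrix(rnorm(300), ncol = 3))))[, 2:4]
  expect_equal(unname(vif(e)), rep(1, 3), tolerance = 1e-10)

  # constructed sample correlation rho: VIF = 1 / (1 - rho^2)
  for (rho in c(0, 0.6, 0.9)) {
    x1 <- e[, 1]; x2 <- rho * e[, 1] + sqrt(1 - rho^2) * e[, 2]
    got <- unname(vif(cbind(x1, x2)))
    expect_equal(got, rep(1 / (1 - rho^2), 2), tolerance = 1e-8)
  }
  expect_equal(unname(vif(cbind(e[, 1], 0.6 * e[, 1] + 0.8 * e[, 2]))),
               c(1.5625, 1.5625), tolerance = 1e-8)

  # duplicate of one predictor: the collinear pair is flagged infinite
  X <- cbind(a = e[, 1], b = e[, 2], c = e[, 3], d = e[, 1])
  v <- vif(X)
  expect_true(is.infinite(v[["a"]]) && is.infinite(v[["d"]]))
  expect_false(is.infinite(v[["b"]]) || is.infinite(v[["c"]]))

  # invariant under affine rescaling of any predictor
  set.seed(4)
  Y <- matrix(rnorm(400), ncol = 4)
  v0 <- unname(vif(Y))
  Y2 <- Y; Y2[, 2] <- 3.7 * Y[, 2] - 11
  expect_equal(unname(vif(Y2)), v0, tolerance = 1e-9)

  # cross-check against the standard automotive implementation
  skip_if_not_installed("car")
  df <- as.data.frame(Y); df$y <- rnorm(100)
  fit <- lm(y ~ ., data = df)
  expect_equal(unname(vif(Y)), unname(car::vif(fit)), tolerance = 1e-8)
})

test_that("prognosis regression recovers the generating coefficients", {
  # noise-free cohort: exact recovery at machine precision
  coh <- generate_cohort(cohort_spec(n_patients = 60, slope_noise_sd = 0,
                                     egfr_measure_noise_sd = 0, seed = 31))
  rep <- fit_prognosis_model(coh)
  expect_equal(rep$table$beta[rep$table$variable == "sclerotic_prop"], -3,
               tolerance = 1e-7)
  expect_equal(rep$table$beta[rep$table$variable != "sclerotic_prop"],
               rep(0, 5), tolerance = 1e-7)
  expect_equal(rep$r_squared, 1, tolerance = 1e-7)

  # noisy n = 500 cohort: recovery within 3 SE, significant, VIF modest
  coh2 <- generate_cohort(cohort_spec(n_patients = 500, seed = 8))
  rep2 <- fit_prognosis_model(coh2)
  row <- rep2$table[rep2$table$variable == "sclerotic_prop", ]
  expect_lt(abs(row$beta - (-3)), 3 * row$se)
  expect_lt(row$p, 0.05)
  expect_true(all(rep2$table$vif < 3))

  # R^2 equals the squared correlation of fitted vs observed outcomes
  expect_equal(rep2$r_squared,
               cor(fitted(rep2$fit), fitted(rep2$fit) + resid(rep2$fit))^2,
               tolerance = 1e-10)

  # duplicated predictor column: multicollinearity error
  coh3 <- coh
  coh3$patients$sclerotic_prop <- coh3$patients$upcr
  expect_error(fit_prognosis_model(coh3), "multicollinearity")
})

test_that("fully standardized beta equals Pearson r for orthogonal predictors", {
  set.seed(12)
  n <- 200
  # columns orthogonal to each other and to the intercept (mean 0), so
  # z-scoring preserves orthogonality and each standardized coefficient
  # reduces to the predictor-outcome Pearson correlation
  e <- qr.Q(qr(cbind(1, matrix(rnorm(n * 6), ncol = 6))))[, 2:7]
  pat <- data.frame(patient_id = 1:n, age = e[, 1], sex = e[, 2],
                    hypertension = e[, 3], egfr0 = e[, 4], upcr = e[, 5],
                    sclerotic_prop = e[, 6],
                    egfr_slope = 2 * e[, 1] - 3 * e[, 6])
  rep <- suppressWarnings( # noise-free outcome: lm warns on the perfect fit
    fit_prognosis_model(toy_cohort(pat, data.frame(patient_id = integer(0),
                                                   visit_time_yr = numeric(0),
                                                   egfr = numeric(0))),
                        standardize_outcome = TRUE))
  for (v in c("age", "sclerotic_prop", "upcr")) {
    expect_equal(rep$table$beta[rep$table$variable == v],
                 cor(pat[[v]], pat$egfr_slope), tolerance = 1e-8)
  }
})

test_that("sclerosis is the dominant significant predictor across small cohorts", {
  # qualitative pattern at realistic cohort size: with only the sclerosis
  # effect truly nonzero, it is the most frequently significant predictor
  sig <- matrix(0L, 100, 6)
  for (s in 1:100) {
    coh <- generate_cohort(cohort_spec(n_patients = 46, seed = 1000 + s))
    rep <- fit_prognosis_model(coh)
    sig[s, ] <- as.integer(rep$table$p < 0.05)
  }
  counts <- colSums(sig)
  names(counts) <- c("age", "sex", "hypertension", "egfr0", "upcr", "sclerotic_prop")
  expect_equal(names(which.max(counts)), "sclerotic_prop")
  expect_gt(counts[["sclerotic_prop"]], max(counts[1:5]))
  expect_gt(counts[["sclerotic_prop"]], 50) # strong effect detected in most cohorts
})

test_that("prognosis report writers emit Table-shaped CSV and JSON", {
  coh <- generate_cohort(cohort_spec(n_patients = 40, seed = 2))
  rep <- fit_prognosis_model(coh)
  dir <- withr::local_tempdir()
  jp <- file.path(dir, "report.json")
  write_prognosis_report(rep, jp)
  obj <- jsonlite::read_json(jp)
  expect_equal(obj$n, 40)
  expect_equal(length(obj$variables), 6L)
  expect_equal(obj$variables[[6]]$variable, "sclerotic_prop")

  cp <- file.path(dir, "report.csv")
  write_prognosis_report(rep, cp)
  tab <- read.csv(cp)
  expect_equal(nrow(tab), 6L)
  expect_true(all(c("beta", "se", "p", "vif", "r_squared", "n") %in% names(tab)))
})
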