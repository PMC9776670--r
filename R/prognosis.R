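#' Apply cohort eligibility criteria
#'
#' Drops patients who were under 18 at biopsy, in end-stage renal failure
#' at biopsy (eGFR below 15 mL/min/1.73 m^2, or an explicit `end_stage`
#' flag column when present), or with less than one year of eGFR follow-up.
#' Per-criterion exclusion counts are attached as the `"exclusions"`
#' attribute.
#'
#' @param cohort A `glom_cohort` (see [generate_cohort()] /
#'   [read_cohort_csv()]).
#' @return Filtered `glom_cohort` with an `"exclusions"` attribute (named
#'   counts: `age_lt_18`, `end_stage`, `followup_lt_1yr`).
#' @export
filter_eligible <- function(cohort) {
  pat <- cohort$patients
  vis <- cohort$visits
  followup <- tapply(vis$visit_time_yr, vis$patient_id, max)
  fu <- as.numeric(followup[as.character(pat$patient_id)])
  fu[is.na(fu)] <- 0
  excl_age <- pat$age < 18
  excl_esrd <- pat$egfr0 < 15
  if ("end_stage" %in% names(pat)) excl_esrd <- excl_esrd | pat$end_stage == 1
  excl_fu <- fu < 1
  keep <- !(excl_age | excl_esrd | excl_fu)
  out <- cohort
  out$patients <- pat[keep, , drop = FALSE]
  rownames(out$patients) <- NULL
  out$visits <- vis[vis$patient_id %in% pat$patient_id[keep], , drop = FALSE]
  attr(out, "exclusions") <- c(age_lt_18 = sum(excl_age),
                               end_stage = sum(excl_esrd),
                               followup_lt_1yr = sum(excl_fu))
  out
}

#' Per-patient eGFR slope
#'
#' Slope of the univariate linear regression of eGFR on time, restricted
#' to measurements within `window_years` after biopsy (closed interval, so
#' a visit exactly at the window boundary is included).
#'
#' @param times Visit times in years since biopsy.
#' @param egfr eGFR values (mL/min/1.73 m^2).
#' @param window_years Analysis window (default 2).
#' @return Slope in mL/min/1.73 m^2 per year.
#' @examples
#' egfr_slope(c(0, 1, 2), c(60, 58, 56)) # -2
#' @export
egfr_slope <- function(times, egfr, window_years = 2) {
  stopifnot(length(times) == length(egfr))
  keep <- times <= window_years & times >= 0
  t <- times[keep]; y <- egfr[keep]
  if (length(t) < 2L || length(unique(t)) < 2L) {
    stop("undefined result: need >= 2 eGFR values at distinct times within the window",
         call. = FALSE)
  }
  unname(stats::coef(stats::lm(y ~ t))[2])
}

#' eGFR slopes for every patient in a cohort
#'
#' @param cohort A `glom_cohort`.
#' @param window_years Analysis window (default 2).
#' @return Data frame `patient_id, egfr_slope`.
#' @export
cohort_slopes <- function(cohort, window_years = 2) {
  vis <- cohort$visits
  ids <- unique(cohort$patients$patient_id)
  slopes <- vapply(ids, function(id) {
    v <- vis[vis$patient_id == id, ]
    egfr_slope(v$visit_time_yr, v$egfr, window_years)
  }, numeric(1))
  data.frame(patient_id = ids, egfr_slope = slopes)
}

PROGNOSTIC_VARS <- c("age", "sex", "hypertension", "egfr0", "upcr", "sclerotic_prop")

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)`, with `R^2_j` from regressing predictor `j`
#' on the remaining predictors (with intercept). A predictor that is an
#' exact linear combination of the others gets `Inf`.
#'
#' @param predictor_matrix Numeric matrix or data frame, >= 2 columns,
#'   each with positive variance.
#' @return Named numeric vector of VIFs (each >= 1).
#' @examples
#' x <- matrix(rnorm(200), ncol = 2)
#' vif(x)
#' @export
vif <- function(predictor_matrix) {
  X <- as.matrix(predictor_matrix)
  p <- ncol(X)
  if (p < 2L) stop("need >= 2 predictors", call. = FALSE)
  if (any(apply(X, 2, stats::sd) == 0)) {
    stop("each predictor needs positive variance", call. = FALSE)
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  out <- vapply(seq_len(p), function(j) {
    fit <- stats::lm(X[, j] ~ X[, -j, drop = FALSE])
    # summary warns on an essentially perfect fit; that case is exactly the
    # infinite-VIF flag below
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(X)
  out
}

#' Multivariate eGFR-slope prognosis regression
#'
#' Regresses the per-patient eGFR slope on the six prognostic variables:
#' age at biopsy, sex (male = 1), hypertension (present = 1), eGFR at
#' biopsy, UPCR at biopsy, and the WSI sclerotic proportion. Predictors —
#' binaries included — are z-scored, so each coefficient is a standardized
#' partial regression coefficient: the slope change
#' (mL/min/1.73 m^2 per year) per within-cohort SD of the predictor. Set
#' `standardize_outcome = TRUE` to z-score the outcome as well (fully
#' standardized, unitless coefficients). Raw-scale coefficients are also
#' reported.
#'
#' @param cohort A `glom_cohort` whose `patients` table carries the six
#'   variables; slopes are computed from the visit series via
#'   [cohort_slopes()] unless the patients table already has an
#'   `egfr_slope` column.
#' @param window_years Slope window in years (default 2).
#' @param standardize_outcome Also z-score the slope (default `FALSE`).
#' @return An object of class `prognosis_report`: list with `table` (data
#'   frame `variable, beta, se, t, p, vif, beta_raw`), `r_squared`, `n`,
#'   and `fit` (the underlying `lm`).
#' @examples
#' coh <- generate_cohort(cohort_spec(n_patients = 60, seed = 11))
#' rep <- fit_prognosis_model(coh)
#' rep$table
#' @export
fit_prognosis_model <- function(cohort, window_years = 2, standardize_outcome = FALSE) {
  pat <- cohort$patients
  if (!all(PROGNOSTIC_VARS %in% names(pat))) {
    stop("patients table must carry: ", paste(PROGNOSTIC_VARS, collapse = ", "),
         call. = FALSE)
  }
  if ("egfr_slope" %in% names(pat)) {
    y <- pat$egfr_slope
  } else {
    sl <- cohort_slopes(cohort, window_years)
    y <- sl$egfr_slope[match(pat$patient_id, sl$patient_id)]
  }
  n <- length(y)
  if (n <= length(PROGNOSTIC_VARS) + 1L) {
    stop("need n > number of predictors + 1", call. = FALSE)
  }
  X <- pat[, PROGNOSTIC_VARS]
  sds <- vapply(X, stats::sd, numeric(1))
  if (any(sds == 0)) {
    stop("constant predictor(s): ", paste(PROGNOSTIC_VARS[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  Z <- as.data.frame(scale(X))
  M <- cbind("(Intercept)" = 1, as.matrix(Z))
  qrz <- qr(M)
  if (qrz$rank < ncol(M)) {
    dep <- colnames(M)[qrz$pivot[-seq_len(qrz$rank)]]
    stop("multicollinearity error: linearly dependent predictors: ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  yz <- if (standardize_outcome) as.numeric(scale(y)) else y
  dat <- cbind(data.frame(.slope = yz), Z)
  fit <- stats::lm(.slope ~ ., data = dat)
  sm <- summary(fit)
  co <- sm$coefficients[-1, , drop = FALSE]
  vifs <- vif(as.matrix(Z))
  raw <- co[, 1] / sds * (if (standardize_outcome) stats::sd(y) else 1)
  tab <- data.frame(variable = PROGNOSTIC_VARS,
                    beta = co[, 1], se = co[, 2], t = co[, 3], p = co[, 4],
                    vif = vifs[PROGNOSTIC_VARS], beta_raw = raw)
  rownames(tab) <- NULL
  structure(list(table = tab, r_squared = sm$r.squared, n = n, fit = fit,
                 standardize_outcome = standardize_outcome,
                 window_years = window_years),
            class = "prognosis_report")
}

#' @export
print.prognosis_report <- function(x, ...) {
  cat(sprintf("Multivariate eGFR-slope regression (n = %d, R^2 = %.2f, %g-yr window)\n",
              x$n, x$r_squared, x$window_years))
  tab <- x$table
  labels <- c(age = "Age", sex = "Sex (male = 1)",
              hypertension = "Hypertension (presence = 1)",
              egfr0 = "eGFR at renal biopsy", upcr = "UPCR at renal biopsy",
              sclerotic_prop = "Proportion of sclerotic regions")
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-32s beta %7.3f (%.3f)  p = %-7.3g VIF %.1f%s\n",
                labels[tab$variable[i]], tab$beta[i], tab$se[i], tab$p[i],
                tab$vif[i], if (tab$p[i] < 0.05) " *" else ""))
  }
  invisible(x)
}

#' Write a prognosis report
#'
#' JSON (or CSV) shaped like a multivariate-regression results table: one
#' row per variable with standardized beta (SE), p and VIF; header carries
#' R^2 and n.
#'
#' @param report A `prognosis_report`.
#' @param path Output path ending in `.json` or `.csv`.
#' @return `path`, invisibly.
#' @export
write_prognosis_report <- function(report, path) {
  stopifnot(inherits(report, "prognosis_report"))
  if (grepl("\\.csv$", path)) {
    hdr <- report$table
    hdr$r_squared <- report$r_squared
    hdr$n <- report$n
    utils::write.csv(hdr, path, row.names = FALSE)
  } else {
    obj <- list(r_squared = report$r_squared, n = report$n,
                window_years = report$window_years,
                variables = report$table)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(path)
}
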