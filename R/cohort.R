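#' Specification of a synthetic IgAN cohort
#'
#' Generates patients whose eGFR decline depends on the sclerotic proportion
#' of their biopsy. Covariates are drawn from distributions spanning the
#' ranges typical of an adult IgAN biopsy cohort (ages centred in the 40s,
#' eGFR at biopsy centred near 65 mL/min/1.73 m^2, UPCR around 1 g/g,
#' sclerotic proportions mostly below 10%). Effects are specified on the
#' standardized scale: `betas[j]` is the change in the true eGFR slope
#' (mL/min/1.73 m^2 per year) per within-cohort SD of covariate `j`.
#'
#' The true per-patient slope is
#' `sum_j betas[j] * z_ij + Normal(0, slope_noise_sd)`, and the observed
#' eGFR series is `egfr0 + slope * t + Normal(0, egfr_measure_noise_sd)` at
#' `visits_per_patient` evenly spaced visits in `[0, followup_years]`.
#' True slopes are stored for parameter-recovery tests.
#'
#' @param n_patients Number of patients (default 46, a realistic
#'   single-facility IgAN cohort size).
#' @param betas Named length-6 numeric: effects of
#'   `(age, sex, hypertension, egfr0, upcr, sclerotic_prop)` on the slope,
#'   per covariate SD. Default: only sclerosis acts, at -3.
#' @param slope_noise_sd SD of unexplained between-patient slope variation
#'   (default 3 mL/min/1.73 m^2/yr).
#' @param egfr_measure_noise_sd SD of per-visit eGFR measurement noise
#'   (default 2 mL/min/1.73 m^2).
#' @param visits_per_patient Number of eGFR measurements (default 8).
#' @param followup_years Follow-up span in years (default 2).
#' @param seed Integer seed; fully determines the output.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 46,
                        betas = c(age = 0, sex = 0, hypertension = 0,
                                  egfr0 = 0, upcr = 0, sclerotic_prop = -3),
                        slope_noise_sd = 3,
                        egfr_measure_noise_sd = 2,
                        visits_per_patient = 8,
                        followup_years = 2,
                        seed = 1L) {
  stopifnot(n_patients >= 2, length(betas) == 6L, slope_noise_sd >= 0,
            egfr_measure_noise_sd >= 0, visits_per_patient >= 2,
            followup_years > 0)
  names(betas) <- c("age", "sex", "hypertension", "egfr0", "upcr", "sclerotic_prop")
  structure(
    list(n_patients = as.integer(n_patients), betas = betas,
         slope_noise_sd = slope_noise_sd,
         egfr_measure_noise_sd = egfr_measure_noise_sd,
         visits_per_patient = as.integer(visits_per_patient),
         followup_years = followup_years, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a synthetic IgAN cohort
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `glom_cohort`: list with
#'   \describe{
#'     \item{patients}{data.frame `patient_id, age, sex, hypertension,
#'       egfr0, upcr, sclerotic_prop, true_slope`}
#'     \item{visits}{long data.frame `patient_id, visit_time_yr, egfr`}
#'   }
#' @examples
#' coh <- generate_cohort(cohort_spec(n_patients = 10, seed = 3))
#' head(coh$patients)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_patients
    patients <- data.frame(
      patient_id = seq_len(n),
      age = round(pmin(85, pmax(18, stats::rnorm(n, 46, 15)))),
      sex = stats::rbinom(n, 1, 25 / 46),           # 1 = male
      hypertension = stats::rbinom(n, 1, 28 / 46),  # 1 = present
      egfr0 = pmin(120, pmax(16, stats::rnorm(n, 65, 25))),
      upcr = pmin(12, stats::rlnorm(n, log(1.18), 0.8)),
      sclerotic_prop = stats::rbeta(n, 1, 20)
    )
    z <- scale_predictors(patients[, names(spec$betas)])
    true_slope <- as.numeric(as.matrix(z) %*% spec$betas) +
      stats::rnorm(n, 0, spec$slope_noise_sd)
    patients$true_slope <- true_slope

    times <- seq(0, spec$followup_years, length.out = spec$visits_per_patient)
    visits <- data.frame(
      patient_id = rep(patients$patient_id, each = length(times)),
      visit_time_yr = rep(times, n)
    )
    visits$egfr <- patients$egfr0[visits$patient_id] +
      patients$true_slope[visits$patient_id] * visits$visit_time_yr +
      stats::rnorm(nrow(visits), 0, spec$egfr_measure_noise_sd)

    structure(list(patients = patients, visits = visits, spec = spec),
              class = "glom_cohort")
  })
}

# z-score columns; constant columns map to 0 rather than NaN
scale_predictors <- function(df) {
  out <- df
  for (nm in names(df)) {
    s <- stats::sd(df[[nm]])
    out[[nm]] <- if (s > 0) (df[[nm]] - mean(df[[nm]])) / s else rep(0, nrow(df))
  }
  out
}

#' @export
print.glom_cohort <- function(x, ...) {
  cat(sprintf("<glom_cohort> %d patients, %d visits each over %g yr, seed %d\n",
              nrow(x$patients), x$spec$visits_per_patient,
              x$spec$followup_years, x$spec$seed))
  invisible(x)
}

#' Read / write cohort tables
#'
#' Long CSV dialect with header
#' `patient_id,age,sex,hypertension,egfr0,upcr,sclerotic_prop,visit_time_yr,egfr`
#' (one row per visit; patient covariates repeated).
#'
#' @param cohort A `glom_cohort` or a list with `patients` / `visits` data
#'   frames.
#' @param path File path.
#' @return `read_cohort_csv` returns a `glom_cohort`-shaped list (without
#'   `true_slope`, which is not part of the interchange dialect);
#'   `write_cohort_csv` returns `path` invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  pat <- cohort$patients
  vis <- cohort$visits
  covars <- c("age", "sex", "hypertension", "egfr0", "upcr", "sclerotic_prop")
  long <- merge(vis, pat[, c("patient_id", covars)], by = "patient_id", sort = FALSE)
  long <- long[order(long$patient_id, long$visit_time_yr),
               c("patient_id", covars, "visit_time_yr", "egfr")]
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  covars <- c("age", "sex", "hypertension", "egfr0", "upcr", "sclerotic_prop")
  need <- c("patient_id", covars, "visit_time_yr", "egfr")
  if (!all(need %in% names(long))) {
    stop("not a cohort table: missing columns", call. = FALSE)
  }
  patients <- unique(long[, c("patient_id", covars)])
  rownames(patients) <- NULL
  visits <- long[, c("patient_id", "visit_time_yr", "egfr")]
  structure(list(patients = patients, visits = visits, spec = NULL),
            class = "glom_cohort")
}
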