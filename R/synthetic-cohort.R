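#' Specification of a simulated patient cohort
#'
#' Emulates a resected-PDAC tissue-microarray cohort: each patient carries
#' 2-5 tumor cores (regions low_grade, high_grade, core, edge, plus an
#' optional normal core), 1-2 ROIs per core with alignment values around a
#' patient-level latent alignment, clinicopathological covariates, and
#' exponential overall-survival times under a proportional-hazards effect
#' of high (>= cutoff) alignment with independent censoring.
#'
#' @param n_patients cohort size (default 114).
#' @param frac_high fraction of patients whose aggregated alignment lies at
#'   or above the cutoff (default 0.12); realized count is
#'   `round(frac_high * n_patients)`.
#' @param cutoff alignment dichotomization threshold (default 0.60).
#' @param log_hr_alignment natural-log hazard ratio of high vs low
#'   alignment (default `log(2.25)`).
#' @param baseline_median_os_months median OS of the low-alignment group
#'   (default 26.9).
#' @param censor_fraction per-patient probability of censoring in
#'   `[0, 1)` (default 0.4).
#' @param covariate_effects named list of log HRs for covariate indicators
#'   (names among `gender_female`, `age_gt65`, `pT_t34`, `pN_n1`,
#'   `grade_g23`, `margin_r1`, `adjuvant_no`); default all zero.
#' @param within_patient_sd sd of ROI alignment values around the patient
#'   latent value (the within-patient dispersion is not constrained by any
#'   study design; it is an exposed parameter, default 0.02).
#' @param seed integer seed.
#' @export
cohort_spec <- function(n_patients = 114, frac_high = 0.12, cutoff = 0.60,
                        log_hr_alignment = log(2.25),
                        baseline_median_os_months = 26.9,
                        censor_fraction = 0.4, covariate_effects = list(),
                        within_patient_sd = 0.02, seed = 1) {
  if (frac_high < 0 || frac_high > 1) stop("frac_high must lie in [0, 1]")
  if (baseline_median_os_months <= 0) stop("baseline median OS must be > 0")
  if (censor_fraction < 0 || censor_fraction >= 1)
    stop("censor_fraction must lie in [0, 1)")
  known <- c("gender_female", "age_gt65", "pT_t34", "pN_n1", "grade_g23",
             "margin_r1", "adjuvant_no")
  if (length(covariate_effects) && !all(names(covariate_effects) %in% known))
    stop("unknown covariate effect name(s): ",
         paste(setdiff(names(covariate_effects), known), collapse = ", "))
  structure(list(n_patients = as.integer(n_patients), frac_high = frac_high,
                 cutoff = cutoff, log_hr_alignment = log_hr_alignment,
                 baseline_median_os_months = baseline_median_os_months,
                 censor_fraction = censor_fraction,
                 covariate_effects = covariate_effects,
                 within_patient_sd = within_patient_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

#' Simulate a patient cohort with known survival ground truth
#'
#' Latent patient alignment is drawn below the cutoff for low patients
#' (normal, mean 0.47, sd 0.06, truncated to `[0.29, cutoff - 0.03]`) and
#' above it for high patients (mean `cutoff + 0.04`, sd 0.025, truncated to
#' `[cutoff + 0.01, 0.72]`), matching the observed inter-patient range
#' 0.29-0.71. ROI values add Gaussian within-patient noise. The hazard is
#' `log(2) / baseline_median * exp(log_hr * 1[aggregate >= cutoff] +
#' sum(covariate effects))`; censoring times are exponential with the rate
#' chosen so each patient is censored with probability `censor_fraction`.
#' Covariate margins loosely follow the reference cohort (46% female, 65%
#' over 65, 71% T3/T4, 71% N1, 78% G2/G3, 25% R1 margin, 61% adjuvant).
#'
#' @param spec a [cohort_spec()].
#' @return list: `patients` (one row per patient: indicators, aggregated
#'   `alignment`, `high_alignment`, `os_months`, `event`), `rois` (one row
#'   per ROI: `patient_id`, `core_id`, `region`, `alignment`), `spec`.
#' @examples
#' ch <- make_cohort(cohort_spec(n_patients = 40, seed = 7))
#' table(ch$patients$high_alignment)
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  n_high <- round(spec$frac_high * n)
  hi <- rep(FALSE, n); if (n_high > 0) hi[sample.int(n, n_high)] <- TRUE
  lat <- numeric(n)
  lat[!hi] <- rnorm_trunc(sum(!hi), 0.47, 0.06, 0.29, spec$cutoff - 0.03)
  if (n_high > 0)
    lat[hi] <- rnorm_trunc(sum(hi), spec$cutoff + 0.04, 0.025,
                           spec$cutoff + 0.01, 0.72)
  tumor_regions <- c("low_grade", "high_grade", "core", "edge")
  roi_rows <- vector("list", n)
  agg <- numeric(n)
  for (i in seq_len(n)) {
    n_cores <- sample(2:4, 1, prob = c(0.25, 0.4, 0.35))
    regions <- sample(tumor_regions, n_cores)
    if (runif(1) < 0.73) regions <- c(regions, "normal")
    rws <- lapply(seq_along(regions), function(k) {
      n_roi <- 1 + rbinom(1, 1, 0.8)
      base <- if (regions[k] == "normal")
        rnorm_trunc(1, 0.35, 0.05, 0.2, 0.55) else lat[i]
      data.frame(patient_id = i, core_id = sprintf("p%03d_c%d", i, k),
                 region = regions[k],
                 alignment = pmin(pmax(
                   rnorm(n_roi, base, spec$within_patient_sd), 0.05), 0.95))
    })
    rws <- do.call(rbind, rws)
    roi_rows[[i]] <- rws
    agg[i] <- mean(rws$alignment[rws$region != "normal"])
  }
  rois <- do.call(rbind, roi_rows)
  high <- agg >= spec$cutoff
  pats <- data.frame(
    patient_id = seq_len(n),
    gender_female = rbinom(n, 1, 0.46),
    age_gt65 = rbinom(n, 1, 0.65),
    pT_t34 = rbinom(n, 1, 0.71),
    pN_n1 = rbinom(n, 1, 0.71),
    grade_g23 = rbinom(n, 1, 0.78),
    margin_r1 = rbinom(n, 1, 0.25),
    adjuvant_no = rbinom(n, 1, 0.39),
    alignment = agg,
    high_alignment = as.integer(high))
  lp <- spec$log_hr_alignment * high
  for (nm in names(spec$covariate_effects))
    lp <- lp + spec$covariate_effects[[nm]] * pats[[nm]]
  lambda <- log(2) / spec$baseline_median_os_months * exp(lp)
  t_event <- rexp(n, lambda)
  cf <- spec$censor_fraction
  t_cens <- if (cf == 0) rep(Inf, n) else rexp(n, lambda * cf / (1 - cf))
  pats$os_months <- pmax(pmin(t_event, t_cens), 1e-6)
  pats$event <- as.integer(t_event <= t_cens)
  list(patients = pats, rois = rois, spec = spec)
}

#' Write the two cohort tables as CSV
#'
#' @param cohort result of [make_cohort()].
#' @param dir output directory (created if needed).
#' @return paths of the written files, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pp <- file.path(dir, "patients.csv"); rp <- file.path(dir, "rois.csv")
  write.csv(cohort$patients, pp, row.names = FALSE)
  write.csv(cohort$rois, rp, row.names = FALSE)
  invisible(c(patients = pp, rois = rp))
}
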