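#' Patient-level alignment aggregation
#'
#' A patient value is the unweighted mean of all available ROI alignment
#' values from the tumor regions (low_grade, high_grade, core, edge);
#' normal-region ROIs are ignored. Patients represented by fewer than two
#' tumor cores are excluded (sampling-bias guard), with the reason recorded.
#'
#' @param rois data.frame with columns `patient_id`, `core_id`, `region`,
#'   `alignment` (one row per ROI).
#' @param min_cores minimum number of distinct tumor cores (default 2).
#' @return data.frame, one row per patient: `patient_id`, `alignment`
#'   (NA when excluded), `n_tumor_cores`, `n_tumor_rois`, `included`,
#'   `reason`.
#' @examples
#' rois <- data.frame(patient_id = 1,
#'                    core_id = c("c1", "c1", "c2"),
#'                    region = c("core", "core", "edge"),
#'                    alignment = c(0.5, 0.6, 0.7))
#' aggregate_patient_alignment(rois)
#' @export
aggregate_patient_alignment <- function(rois, min_cores = 2) {
  stopifnot(all(c("patient_id", "core_id", "region", "alignment") %in% names(rois)))
  tumor <- rois[rois$region != "normal", , drop = FALSE]
  ids <- unique(rois$patient_id)
  out <- lapply(ids, function(id) {
    tr <- tumor[tumor$patient_id == id, , drop = FALSE]
    nc <- length(unique(tr$core_id))
    if (nc < min_cores)
      return(data.frame(patient_id = id, alignment = NA_real_,
                        n_tumor_cores = nc, n_tumor_rois = nrow(tr),
                        included = FALSE,
                        reason = sprintf("cores<%d", min_cores)))
    data.frame(patient_id = id, alignment = mean(tr$alignment),
               n_tumor_cores = nc, n_tumor_rois = nrow(tr),
               included = TRUE, reason = NA_character_)
  })
  do.call(rbind, out)
}

#' Dichotomize alignment at a cutoff
#'
#' Values at or above the cutoff are "high" (the >= 0.60 rule).
#'
#' @param values numeric vector.
#' @param cutoff threshold, default 0.60.
#' @return factor with levels `low`, `high`.
#' @export
dichotomize <- function(values, cutoff = 0.60) {
  factor(ifelse(values >= cutoff, "high", "low"), levels = c("low", "high"))
}

#' Optimal survival cutpoint by exhaustive log-rank scan
#'
#' Reimplementation of the training-cohort cutpoint search: every candidate
#' cutoff (unique observed values, or a percentile grid, restricted to the
#' 10th-90th percentile window) is scored by the two-group log-rank
#' chi-square; the argmax subject to a minimum group size is returned.
#' Because the maximally selected statistic is optimistic, an optional
#' permutation adjustment re-runs the scan on label-permuted survival data
#' and reports the fraction of permuted maxima at or above the observed one.
#'
#' @param values patient-level alignment values (training cohort).
#' @param times,events OS months and event indicators (1 = death).
#' @param grid `"unique"` (default) or `"percentile"` (41 equally spaced
#'   percentiles).
#' @param min_group_frac minimum group size as a fraction of the cohort;
#'   the absolute floor is `max(5, min_group_frac * n)`.
#' @param n_permutations permutations for the adjusted p (0 to skip).
#' @return list of class `cutoff_result`: `cutoff`, `chisq`, `p`
#'   (uncorrected), `p_adjusted` (permutation, NA when skipped),
#'   `candidates` (data.frame cutoff/chisq/n_high), `n_low`, `n_high`,
#'   `no_significant_cutpoint`.
#' @export
find_cutoff <- function(values, times, events, grid = c("unique", "percentile"),
                        min_group_frac = 0.10, n_permutations = 0) {
  grid <- match.arg(grid)
  n <- length(values)
  stopifnot(length(times) == n, length(events) == n)
  if (n < 2 / min_group_frac) stop("training cohort too small for the group-size constraint")
  qs <- quantile(values, c(0.10, 0.90), names = FALSE)
  cand <- if (grid == "unique") sort(unique(values)) else
    sort(unique(quantile(values, seq(0.10, 0.90, length.out = 41), names = FALSE)))
  cand <- cand[cand >= qs[1] & cand <= qs[2]]
  if (length(cand) < 2) stop("degenerate candidate grid (alignment values identical)")
  min_size <- max(5, ceiling(min_group_frac * n))
  scan <- function(tm, ev) {
    chis <- rep(NA_real_, length(cand)); nh <- integer(length(cand))
    for (k in seq_along(cand)) {
      g <- values >= cand[k]
      nh[k] <- sum(g)
      if (nh[k] < min_size || n - nh[k] < min_size) next
      sd <- survival::survdiff(survival::Surv(tm, ev) ~ g)
      chis[k] <- sd$chisq
    }
    list(chisq = chis, n_high = nh)
  }
  obs <- scan(times, events)
  if (all(is.na(obs$chisq))) stop("no candidate cutoff satisfies the group-size constraint")
  best <- which.max(obs$chisq)
  chisq <- obs$chisq[best]
  p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  p_adj <- NA_real_
  if (n_permutations > 0) {
    exceed <- 0L
    for (b in seq_len(n_permutations)) {
      pi <- sample.int(n)
      mx <- suppressWarnings(max(scan(times[pi], events[pi])$chisq, na.rm = TRUE))
      if (mx >= chisq) exceed <- exceed + 1L
    }
    p_adj <- (exceed + 1) / (n_permutations + 1)
  }
  structure(list(cutoff = cand[best], chisq = chisq, p = p, p_adjusted = p_adj,
                 candidates = data.frame(cutoff = cand, chisq = obs$chisq,
                                         n_high = obs$n_high),
                 n_low = n - obs$n_high[best], n_high = obs$n_high[best],
                 no_significant_cutpoint = p > 0.05),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("optimal cutoff %.4g (chi-square %.3f, p %.4g%s); groups %d low / %d high\n",
              x$cutoff, x$chisq, x$p,
              if (!is.na(x$p_adjusted)) sprintf(", permutation-adjusted p %.4g", x$p_adjusted) else "",
              x$n_low, x$n_high))
  if (x$no_significant_cutpoint) cat("no significant cutpoint (min p > 0.05)\n")
  invisible(x)
}

#' Kaplan-Meier estimate and median overall survival
#'
#' Product-limit estimator; the median is the smallest time at which the
#' survival function drops to 0.5 or below, NA when it never does.
#'
#' @param times,events survival times and event indicators.
#' @return list of class `km_fit`: `curve` (data.frame time, n_risk,
#'   n_event, n_censor, surv), `median`, `n`.
#' @export
km_estimate <- function(times, events) {
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, n_censor = fit$n.censor,
                      surv = fit$surv)
  med <- if (any(fit$surv <= 0.5)) min(fit$time[fit$surv <= 0.5]) else NA_real_
  structure(list(curve = curve, median = med, n = length(times)),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("Kaplan-Meier fit, n = %d, median OS = %s\n", x$n,
              if (is.na(x$median)) "not reached" else sprintf("%.3g", x$median)))
  invisible(x)
}

#' Two-group log-rank test
#'
#' @param times,events pooled survival data.
#' @param group two-level grouping vector.
#' @return list: `chisq`, `p`, `n` per group, `observed`, `expected`.
#' @export
logrank_test <- function(times, events, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) stop("log-rank test needs exactly two groups")
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  list(chisq = sd$chisq, p = pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       n = as.numeric(sd$n), observed = as.numeric(sd$obs),
       expected = as.numeric(sd$exp))
}

#' Cox proportional hazards fit
#'
#' Thin wrapper over the partial-likelihood Newton fit with Efron tie
#' handling, returning hazard ratios with Wald 95% confidence intervals in
#' a tidy per-covariate table. Non-convergence, infinite coefficients
#' (separation) or constant covariates raise errors.
#'
#' @param design data.frame of covariates (numeric indicators or factors).
#' @param times,events survival data.
#' @param ties ties method, default "efron".
#' @return list of class `cox_model_fit`: `coefficients` (data.frame term,
#'   log_hr, hr, se, ci_low, ci_high, p), `loglik`, `iterations`, `ties`,
#'   `n`, `n_events`, `model` (the underlying `coxph` object).
#' @export
cox_fit <- function(design, times, events, ties = "efron") {
  stopifnot(is.data.frame(design), nrow(design) == length(times))
  if (sum(events) < 1) stop("no events in the data")
  const <- vapply(design, function(v) length(unique(v[!is.na(v)])) < 2, logical(1))
  if (any(const)) stop("constant covariate(s): ", paste(names(design)[const], collapse = ", "))
  dat <- cbind(design, .time = times, .event = events)
  dat <- dat[complete.cases(dat), , drop = FALSE]
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(sprintf("`%s`", names(design)), collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite", conditionMessage(w)))
        stop("Cox fit failed: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (any(!is.finite(fit$coefficients)))
    stop("Cox fit produced non-finite coefficients (separation?)")
  s <- summary(fit)
  co <- data.frame(term = gsub("`", "", rownames(s$coefficients)),
                   log_hr = s$coefficients[, "coef"],
                   hr = s$coefficients[, "exp(coef)"],
                   se = s$coefficients[, "se(coef)"],
                   ci_low = s$conf.int[, "lower .95"],
                   ci_high = s$conf.int[, "upper .95"],
                   p = s$coefficients[, "Pr(>|z|)"],
                   row.names = NULL)
  structure(list(coefficients = co, loglik = fit$loglik[2],
                 iterations = fit$iter, ties = ties,
                 n = s$n, n_events = s$nevent, model = fit),
            class = "cox_model_fit")
}

#' @export
print.cox_model_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit (%s ties), n = %d, events = %d\n", x$ties, x$n, x$n_events))
  df <- x$coefficients
  df$hr <- sprintf("%.2f (%.2f-%.2f)", df$hr, df$ci_low, df$ci_high)
  print(df[, c("term", "hr", "p")], row.names = FALSE)
  invisible(x)
}

#' Backward covariate selection for the multivariate Cox model
#'
#' Candidate covariates enter the initial model only when their univariate
#' Cox p-value is below `threshold` (default 0.25); forced clinical
#' covariates always enter and are never dropped. The highest-p non-forced
#' covariate with p >= threshold is then dropped iteratively until all
#' remaining non-forced covariates fall below the threshold.
#'
#' @param design data.frame holding all candidate and forced covariates.
#' @param times,events survival data.
#' @param candidates names of covariates subject to selection.
#' @param forced names of covariates kept regardless of p.
#' @param threshold selection p-value cutoff, default 0.25.
#' @return list of class `backward_selection`: `fit` (final
#'   [cox_fit()]), `univariate` (data.frame term/p), `initial`, `dropped`,
#'   `kept`.
#' @export
backward_select <- function(design, times, events, candidates,
                            forced = character(0), threshold = 0.25) {
  stopifnot(all(c(candidates, forced) %in% names(design)))
  uni <- vapply(candidates, function(nm) {
    cox_fit(design[, nm, drop = FALSE], times, events)$coefficients$p[1]
  }, numeric(1))
  initial <- union(candidates[uni < threshold], forced)
  current <- initial
  dropped <- character(0)
  repeat {
    fit <- cox_fit(design[, current, drop = FALSE], times, events)
    co <- fit$coefficients
    co$var <- vapply(co$term, function(tt) {
      hit <- current[vapply(current, function(v) startsWith(tt, v), logical(1))]
      hit[which.max(nchar(hit))]
    }, character(1))
    free <- co[!(co$var %in% forced), , drop = FALSE]
    # factors contribute several terms; a variable is droppable when its
    # best term p is still above threshold
    if (nrow(free) == 0) break
    pv <- tapply(free$p, free$var, min)
    worst <- names(pv)[which.max(pv)]
    if (max(pv) < threshold) break
    current <- setdiff(current, worst)
    dropped <- c(dropped, worst)
    if (length(current) == 0) stop("all covariates dropped; nothing to fit")
  }
  structure(list(fit = fit, univariate = data.frame(term = candidates, p = uni),
                 initial = initial, dropped = dropped, kept = current),
            class = "backward_selection")
}

#' @export
print.backward_selection <- function(x, ...) {
  cat("backward selection: kept", paste(x$kept, collapse = ", "), "\n")
  if (length(x$dropped)) cat("dropped:", paste(x$dropped, collapse = ", "), "\n")
  print(x$fit)
  invisible(x)
}

#' Fisher exact test on a 2 x 2 table
#'
#' Exact two-sided p by summing hypergeometric probabilities of all tables
#' (with the observed margins) no more probable than the observed one.
#' Rows with unknown category membership must be excluded upstream.
#'
#' @param table 2 x 2 integer matrix.
#' @return list: `p`, `odds_ratio`, `table`.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2 x 2 table")
  ft <- fisher.test(table)
  list(p = ft$p.value, odds_ratio = unname(ft$estimate), table = table)
}

#' Spearman rank correlation
#'
#' Midranks for ties; p from the t approximation when ties are present,
#' exact otherwise (the behaviour of the standard rank-correlation test).
#'
#' @param x,y numeric vectors.
#' @return list: `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  ok <- complete.cases(x, y)
  ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Rank-based group comparison gated on normality
#'
#' Shapiro-Wilk normality per group is computed and reported; following
#' the analysis plan the comparison itself is rank-based regardless:
#' Mann-Whitney U for two groups, Kruskal-Wallis for three or more.
#'
#' @param groups list of >= 2 numeric vectors.
#' @return list: `test`, `statistic`, `p`, `shapiro` (data.frame group,
#'   n, W, p; NA where n < 3).
#' @export
group_compare <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need a list of at least two groups")
  sw <- do.call(rbind, lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    if (length(g) >= 3 && length(g) <= 5000 && length(unique(g)) > 1) {
      s <- shapiro.test(g)
      data.frame(group = i, n = length(g), W = unname(s$statistic), p = s$p.value)
    } else data.frame(group = i, n = length(g), W = NA_real_, p = NA_real_)
  }))
  if (length(groups) == 2) {
    ht <- suppressWarnings(wilcox.test(groups[[1]], groups[[2]]))
    list(test = "mann-whitney", statistic = unname(ht$statistic),
         p = ht$p.value, shapiro = sw)
  } else {
    ht <- kruskal.test(groups)
    list(test = "kruskal-wallis", statistic = unname(ht$statistic),
         p = ht$p.value, shapiro = sw)
  }
}
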