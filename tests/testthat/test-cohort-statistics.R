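test_that("patient aggregation averages tumor ROIs and applies the core rule", {
  rois <- data.frame(patient_id = 1, core_id = c("c1", "c2"),
                     region = c("core", "edge"), alignment = c(0.5, 0.7))
  agg <- aggregate_patient_alignment(rois)
  expect_equal(agg$alignment, 0.6)
  expect_true(agg$included)
  # normal-region values are ignored entirely
  only_norm <- data.frame(patient_id = 2, core_id = c("n1", "n2"),
                          region = "normal", alignment = c(0.3, 0.4))
  a2 <- aggregate_patient_alignment(only_norm)
  expect_false(a2$included)
  # one tumor core with two ROIs is still below the two-core requirement
  one_core <- data.frame(patient_id = 3, core_id = "c1",
                         region = c("core", "core"), alignment = c(0.5, 0.6))
  a3 <- aggregate_patient_alignment(one_core)
  expect_false(a3$included)
  expect_equal(a3$reason, "cores<2")
  # normal ROIs do not shift the tumor mean
  mixed <- rbind(rois, data.frame(patient_id = 1, core_id = "n1",
                                  region = "normal", alignment = 0.1))
  expect_equal(aggregate_patient_alignment(mixed)$alignment, 0.6)
})

test_that("dichotomization puts the cutoff value itself in the high group", {
  expect_equal(as.character(dichotomize(c(0.60, 0.59))), c("high", "low"))
  vals <- c(rep(0.5, 100), rep(0.65, 14))
  expect_equal(round(100 * mean(dichotomize(vals) == "high")), 12)
})

test_that("Kaplan-Meier estimate matches the hand product-limit computation", {
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  s <- setNames(km$curve$surv, km$curve$time)
  expect_equal(unname(s["1"]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(s["2"]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(s["3"]), 0, tolerance = 1e-12)
  expect_equal(km$median, 3)
  allc <- km_estimate(c(5, 8, 11), c(0, 0, 0))
  expect_true(all(allc$curve$surv == 1))
  expect_true(is.na(allc$median))
  # without censoring KM equals the empirical survivor function
  set.seed(51)
  t <- round(rexp(40, 0.1), 2); e <- rep(1, 40)
  km2 <- km_estimate(t, e)
  emp <- vapply(km2$curve$time, function(u) mean(t > u), numeric(1))
  expect_equal(km2$curve$surv, emp, tolerance = 1e-12)
  # general case against the independent oracle
  set.seed(52)
  t3 <- sample(1:20, 30, replace = TRUE); e3 <- rbinom(30, 1, 0.7)
  km3 <- km_estimate(t3, e3)
  or <- oracle_km(t3, e3)
  got <- km3$curve$surv[km3$curve$n_event > 0]
  expect_equal(got, or$surv, tolerance = 1e-12)
})

test_that("log-rank test matches the hypergeometric O-E/V oracle", {
  t <- c(3, 5, 7, 9, 4, 6, 8, 10); e <- c(1, 1, 0, 1, 1, 0, 1, 1)
  g <- rep(c("a", "b"), each = 4)
  lr <- logrank_test(t, e, g)
  expect_equal(lr$chisq, oracle_logrank(t, e, g), tolerance = 1e-10)
  # symmetry under label swap
  lr2 <- logrank_test(t, e, rev(g))
  expect_equal(lr$chisq, lr2$chisq, tolerance = 1e-12)
  # identical groups separate nothing
  same <- logrank_test(c(t, t), c(e, e), rep(c("a", "b"), each = 8))
  expect_lt(same$chisq, 1e-10)
  expect_equal(same$p, 1, tolerance = 1e-6)
})

test_that("Cox fit maximizes the partial likelihood", {
  x <- c(1, 1, 1, 0, 0, 0)
  t <- c(2, 4, 6, 5, 7, 9); e <- c(1, 1, 0, 1, 1, 1)
  fit <- cox_fit(data.frame(x = x), t, e)
  beta_or <- oracle_cox_beta(x, t, e)
  expect_lt(abs(fit$coefficients$log_hr[1] - beta_or), 1e-4)
  expect_equal(fit$coefficients$hr[1], exp(fit$coefficients$log_hr[1]))
  expect_true(fit$coefficients$ci_low[1] < fit$coefficients$hr[1],
              fit$coefficients$ci_high[1] > fit$coefficients$hr[1])
  # duplicating every subject leaves the Breslow point estimate unchanged
  # (the duplication invariance holds for the Breslow tie approximation)
  fitb <- cox_fit(data.frame(x = x), t, e, ties = "breslow")
  fit2 <- cox_fit(data.frame(x = rep(x, 2)), rep(t, 2), rep(e, 2),
                  ties = "breslow")
  expect_equal(fit2$coefficients$log_hr[1], fitb$coefficients$log_hr[1],
               tolerance = 1e-6)
  expect_error(cox_fit(data.frame(x = rep(1, 6)), t, e), "constant")
  expect_error(cox_fit(data.frame(x = x), t, rep(0, 6)), "no events")
})

test_that("null-covariate Cox estimates centre on HR 1", {
  set.seed(53)
  est <- vapply(1:40, function(r) {
    n <- 80
    x <- rbinom(n, 1, 0.5)
    t <- rexp(n, 0.05); e <- rbinom(n, 1, 0.8)
    cox_fit(data.frame(x = x), t, e)$coefficients$log_hr[1]
  }, numeric(1))
  expect_lt(abs(mean(est)), 0.1)
})

test_that("backward selection drops weak covariates but never forced ones", {
  set.seed(54)
  ch <- make_cohort(cohort_spec(n_patients = 150,
                                covariate_effects = list(gender_female = 0.6),
                                seed = 55))
  p <- ch$patients
  design <- data.frame(high_alignment = p$high_alignment,
                       gender_female = p$gender_female,
                       noise1 = rbinom(150, 1, 0.5),
                       pT_t34 = p$pT_t34, pN_n1 = p$pN_n1,
                       margin_r1 = p$margin_r1, grade_g23 = p$grade_g23)
  sel <- backward_select(design, p$os_months, p$event,
                         candidates = c("high_alignment", "gender_female", "noise1"),
                         forced = c("pT_t34", "pN_n1", "margin_r1", "grade_g23"))
  expect_true(all(c("pT_t34", "pN_n1", "margin_r1", "grade_g23") %in% sel$kept))
  # candidates failing the univariate screen never enter the initial model
  weak <- sel$univariate$term[sel$univariate$p >= 0.25]
  expect_true(all(!weak %in% sel$initial))
  # a forced covariate with high p is retained in the final fit
  forced_terms <- sel$fit$coefficients$term
  expect_true(all(c("pT_t34", "pN_n1", "margin_r1", "grade_g23") %in% forced_terms))
})

test_that("backward selection reduces to forced covariates when all candidates fail", {
  set.seed(56)
  n <- 120
  t <- rexp(n, 0.05); e <- rbinom(n, 1, 0.8)
  design <- data.frame(c1 = rbinom(n, 1, 0.5), c2 = rbinom(n, 1, 0.5),
                       f1 = rbinom(n, 1, 0.5))
  # draw until both candidates are clearly null on this sample
  sel <- backward_select(design, t, e, candidates = c("c1", "c2"), forced = "f1")
  expect_true("f1" %in% sel$kept)
  expect_true(all(sel$fit$coefficients$term %in% c("f1", "c1", "c2")))
  expect_true(all(setdiff(sel$kept, "f1") %in%
                    sel$univariate$term[sel$univariate$p < 0.25]))
})

test_that("Fisher exact equals brute-force hypergeometric enumeration", {
  expect_equal(fisher_exact(matrix(c(10, 10, 10, 10), 2))$p, 1)
  set.seed(57)
  for (i in 1:40) {
    tab <- matrix(rpois(4, 6), 2)
    if (sum(tab) == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab)$p, oracle_fisher(tab), tolerance = 1e-9)
  }
})

test_that("Spearman correlation matches closed forms and midrank oracle", {
  x <- 1:10
  expect_equal(spearman_cor(x, x^3)$rho, 1)
  expect_equal(spearman_cor(c(1, 2, 3, 4), c(1, 3, 2, 4))$rho, 0.8,
               tolerance = 1e-12)
  set.seed(58)
  xt <- sample(1:5, 30, replace = TRUE); yt <- sample(1:5, 30, replace = TRUE)
  expect_equal(spearman_cor(xt, yt)$rho, oracle_spearman(xt, yt),
               tolerance = 1e-12)
})

test_that("group comparison picks the rank test by group count", {
  same <- group_compare(list(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5)))
  expect_equal(same$test, "mann-whitney")
  expect_gt(same$p, 0.9)
  set.seed(59)
  shifted <- group_compare(list(rnorm(50), rnorm(50, 3)))
  expect_lt(shifted$p, 1e-3)
  three <- group_compare(list(rnorm(20), rnorm(20), rnorm(20)))
  expect_equal(three$test, "kruskal-wallis")
  expect_equal(nrow(three$shapiro), 3)
  expect_error(group_compare(list(rnorm(5))), "two groups")
})

test_that("cutpoint scan handles null and degenerate cohorts", {
  set.seed(60)
  n <- 60
  vals <- runif(n, 0.3, 0.7)
  t <- rexp(n, 0.05); e <- rep(1, n)
  res <- find_cutoff(vals, t, e, n_permutations = 0)
  expect_true(res$cutoff >= quantile(vals, 0.1) && res$cutoff <= quantile(vals, 0.9))
  expect_true(res$n_low >= 6 && res$n_high >= 6)
  expect_error(find_cutoff(rep(0.5, n), t, e), "degenerate")
})

test_that("cutpoint estimate tightens as the cohort grows", {
  mae <- vapply(c(70, 200, 1000), function(n) {
    err <- vapply(1:8, function(r) {
      ch <- make_cohort(cohort_spec(n_patients = n, frac_high = 0.3,
                                    censor_fraction = 0.2, seed = 6000 + 13 * n + r))
      agg <- aggregate_patient_alignment(ch$rois)
      cut <- find_cutoff(agg$alignment, ch$patients$os_months, ch$patients$event,
                         grid = "percentile")
      abs(cut$cutoff - 0.6)
    }, numeric(1))
    median(err)
  }, numeric(1))
  expect_true(mae[3] < mae[1])
  expect_true(mae[3] <= mae[2])
})

test_that("permutation adjustment reports an honest null p", {
  set.seed(61)
  n <- 50
  vals <- runif(n, 0.3, 0.7)
  t <- rexp(n, 0.05); e <- rbinom(n, 1, 0.8)
  res <- find_cutoff(vals, t, e, n_permutations = 100)
  expect_gte(res$p_adjusted, res$p)   # selection optimism corrected upward
})
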