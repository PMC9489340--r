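make_hazard_cohort <- function(seed, n_i = 400L, n_c = 400L, hr = 0.322,
                               dropout = 0.10) {
  generate_cohort(truth_params(
    n_per_arm = c(integrative = n_i, conventional = n_c),
    seed = seed, mode = "hazard", true_hr = hr, dropout_rate_year = dropout,
    inhosp_death_rate = c(integrative = 0, conventional = 0)))
}

test_that("make_survival_dataset applies the first-CVE rule", {
  fu <- data.frame(patient_id = c("a", "a", "b", "b", "b"),
                   month = c(6, 12, 6, 12, 18),
                   state = c("III", "CVE", "II", "II", "II"),
                   censored = c(0, 0, 0, 0, 1))
  pts <- tiny_cohort()$patients[1:3, ]
  pts$patient_id <- c("a", "b", "c")
  expect_warning(make_survival_dataset(fu, pts, tier = NULL), "without follow-up")
  ds <- suppressWarnings(make_survival_dataset(fu, pts, tier = NULL))
  expect_equal(ds$time[ds$patient_id == "a"], 12)
  expect_true(ds$event[ds$patient_id == "a"])
  expect_equal(ds$time[ds$patient_id == "b"], 18)
  expect_false(ds$event[ds$patient_id == "b"])
  expect_equal(nrow(ds), 2L)
  fu$patient_id[1] <- "zz"
  expect_error(suppressWarnings(make_survival_dataset(fu, pts, tier = NULL)),
               "unknown patient")
})

test_that("KM estimator equals the brute-force product-limit oracle", {
  set.seed(10)
  # exhaustive small instances with ties and censoring
  for (rep in 1:30) {
    n <- sample(3:20, 1)
    time <- sample(c(6, 12, 18, 24, 30, 36), n, replace = TRUE)
    event <- stats::runif(n) < 0.7
    if (!any(event)) event[1] <- TRUE
    ds <- data.frame(time = time, event = event,
                     arm = rep("conventional", n))
    km <- km_fit(ds)
    oracle <- km_oracle(time, event)
    got <- km$curves[km$curves$time %in% oracle$time & km$curves$group == "conventional", ]
    got <- got[match(oracle$time, got$time), ]
    expect_equal(got$surv, oracle$surv, tolerance = 1e-12)
  }
})

test_that("KM without censoring equals the empirical survival function", {
  time <- c(6, 12, 18, 24, 30)
  ds <- data.frame(time = time, event = TRUE, arm = "conventional")
  km <- km_fit(ds)
  sf <- km$curves[km$curves$time > 0, ]
  expect_equal(sf$surv, 1 - seq_along(time) / length(time), tolerance = 1e-12)
  # restricted mean equals the area under the empirical step function
  rmst_oracle <- sum(c(1, head(sf$surv, -1)) * diff(c(0, time)))
  expect_equal(km$table$rmean[1], rmst_oracle, tolerance = 1e-9)
})

test_that("log-rank: identical duplicated arms give p = 1; single arm is n/a", {
  base <- data.frame(time = c(6, 12, 12, 18, 24, 36),
                     event = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))
  two <- rbind(cbind(base, arm = "integrative"), cbind(base, arm = "conventional"))
  km <- km_fit(two)
  expect_equal(km$logrank$p, 1, tolerance = 1e-9)
  one <- cbind(base, arm = "conventional")
  km1 <- km_fit(one)
  expect_true(is.na(km1$logrank$p))
  expect_error(km_fit(data.frame(time = 6, event = FALSE, arm = "a")),
               "at least one event")
})

test_that("cox_fit recovers a known hazard ratio and flags degeneracies", {
  syn <- make_hazard_cohort(101, n_i = 1500L, n_c = 1500L)
  ds <- make_survival_dataset(syn$followup, syn$patients, tier = NULL)
  fit <- suppressWarnings(cox_fit(ds, tier = NULL))
  expect_gt(fit$hr, 0.25); expect_lt(fit$hr, 0.42)
  expect_lt(fit$ci95[["low"]], fit$hr); expect_gt(fit$ci95[["high"]], fit$hr)
  expect_gt(fit$omnibus_chi2, 0)
  expect_equal(fit$minus2loglik,
               -2 * fit$fit$loglik[2], tolerance = 1e-9)
  # degenerate design: single-arm data
  ds1 <- ds[ds$arm == "integrative", ]
  expect_error(cox_fit(ds1, tier = NULL), "constant")
})

test_that("events-per-variable shortfall warns but does not error", {
  syn <- make_hazard_cohort(7, n_i = 60L, n_c = 60L)
  ds <- make_survival_dataset(syn$followup, syn$patients, tier = "III")
  expect_warning(cox_fit(ds), "10 events per covariate")
})

test_that("C-statistic and AUC are invariant under monotone transforms", {
  syn <- make_hazard_cohort(55, n_i = 500L, n_c = 500L)
  ds <- make_survival_dataset(syn$followup, syn$patients, tier = "I")
  fit <- cox_fit(ds, tier = "I")
  lp <- stats::predict(fit$fit, type = "lp")
  roc1 <- time_dependent_roc(ds, lp, horizon = 12)
  roc2 <- time_dependent_roc(ds, exp(3 * lp) + 5, horizon = 12)
  expect_equal(roc1$auc, roc2$auc, tolerance = 1e-12)
  expect_true(roc1$auc >= 0 && roc1$auc <= 1)
  # monotone transform leaves the Cox risk ranking (hence C) unchanged:
  # concordance computed on lp matches the model's C
  conc <- survival::concordance(survival::Surv(ds$time, ds$event) ~ lp,
                                reverse = TRUE)
  expect_equal(fit$c_statistic, unname(conc$concordance), tolerance = 1e-9)
})

test_that("time-dependent ROC hits closed-form anchors", {
  # perfect score, no censoring -> AUC 1
  ds <- data.frame(time = c(6, 6, 12, 24, 30, 36), event = c(T, T, T, F, F, F),
                   arm = "conventional")
  risk <- c(9, 8, 7, 1, 2, 3)
  expect_equal(time_dependent_roc(ds, risk, 12)$auc, 1)
  # anti-perfect score -> AUC 0
  expect_equal(time_dependent_roc(ds, -risk, 12)$auc, 0)
  # random score independent of outcome at n = 2000 -> AUC ~ 0.5
  syn <- make_hazard_cohort(31, n_i = 1000L, n_c = 1000L)
  dsr <- make_survival_dataset(syn$followup, syn$patients, tier = NULL)
  set.seed(99)
  auc <- time_dependent_roc(dsr, stats::rnorm(nrow(dsr)), 12)$auc
  expect_lt(abs(auc - 0.5), 0.03)
  expect_error(time_dependent_roc(dsr, rnorm(nrow(dsr)), 999), "horizon")
  dse <- data.frame(time = c(24, 36), event = c(F, F), arm = "a")
  expect_error(time_dependent_roc(dse, 1:2, 12), "no events")
})

test_that("subgroup analysis partitions the cohort and matches the full fit", {
  syn <- make_hazard_cohort(61, n_i = 700L, n_c = 700L)
  ds <- make_survival_dataset(syn$followup, syn$patients, tier = "III")
  # identity partition: a constant stratifier reproduces the tier-III fit
  ds$whole <- 1L
  sg <- suppressWarnings(subgroup_analysis(ds, strata_spec = list(whole = NULL)))
  full <- suppressWarnings(cox_fit(ds, tier = "III"))
  expect_equal(nrow(sg), 1L)
  expect_equal(sg$hr, full$hr, tolerance = 1e-9)
  expect_equal(sg$n, nrow(ds))
  # default strata: every row accounted for within each variable
  sg2 <- suppressWarnings(subgroup_analysis(ds))
  for (v in unique(sg2$variable)) {
    expect_equal(sum(sg2$n[sg2$variable == v]), nrow(ds), label = v)
  }
  # homogeneous dynamics: stratum HRs bracket the shared truth
  age_rows <- sg2[sg2$variable == "age", ]
  expect_true(all(age_rows$ci_low < 0.322 & age_rows$ci_high > 0.322))
  expect_error(subgroup_analysis(ds, strata_spec = list(nope = 1)), "unknown")
})

test_that("log-rank p-values are uniform under the null", {
  pv <- vapply(1:120, function(s) {
    syn <- generate_cohort(truth_params(
      n_per_arm = c(integrative = 150L, conventional = 150L),
      seed = 4000L + s, mode = "hazard", true_hr = 1,
      inhosp_death_rate = c(integrative = 0, conventional = 0)))
    ds <- make_survival_dataset(syn$followup, syn$patients, tier = NULL)
    km_fit(ds)$logrank$p
  }, 0)
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
  # type-I error near nominal 5%
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.06)
})
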