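test_that("transition matrices are validated strictly", {
  P <- diag(5)
  expect_s3_class(transition_matrix(P), "hf_transition_matrix")
  bad <- diag(5); bad[1, 1] <- 0.9
  expect_error(transition_matrix(bad), "sum to 1")
  bad2 <- diag(5); bad2[5, ] <- c(0.5, 0, 0, 0, 0.5)
  expect_error(transition_matrix(bad2), "absorbing")
  expect_error(transition_matrix(matrix(1, 4, 4)), "5x5")
  neg <- diag(5); neg[1, 1] <- 1.5; neg[1, 2] <- -0.5
  expect_error(transition_matrix(neg), "\\[0, 1\\]")
})

test_that("estimate_transitions is the row-normalised count matrix", {
  # counting oracle: {(III,III) x8, (III,II) x1, (III,CVE) x1}
  from <- rep("III", 10)
  to <- c(rep("III", 8), "II", "CVE")
  est <- suppressWarnings(estimate_transitions(from, to))
  expect_equal(unname(unclass(est$matrix)["III", ]), c(0, 0.1, 0.8, 0, 0.1))
  expect_equal(unname(est$counts["III", ]), c(0L, 1L, 8L, 0L, 1L))
  # all self-transitions -> identity on observed rows
  est2 <- suppressWarnings(estimate_transitions(c("I", "II"), c("I", "II")))
  expect_equal(unname(diag(unclass(est2$matrix))), rep(1, 5))
  # zero-row policies
  expect_warning(estimate_transitions("I", "II"), "zero-row policy")
  estu <- suppressWarnings(estimate_transitions("I", "II", zero_row_policy = "uniform"))
  expect_equal(unname(unclass(estu$matrix)["III", ]), rep(0.2, 5))
  # errors
  expect_error(estimate_transitions(character(0), character(0)), "no paired")
  expect_error(estimate_transitions("CVE", "CVE"), "absorbing")
  # integer-coded states accepted
  est3 <- suppressWarnings(estimate_transitions(c(1, 1), c(2, "CVE")))
  expect_equal(unname(unclass(est3$matrix)["I", ]), c(0, 0.5, 0, 0, 0.5))
})

test_that("sampling recovery: estimated matrix converges to the truth", {
  set.seed(123)
  P <- transition_matrix(rbind(
    c(0.6, 0.2, 0.1, 0.05, 0.05),
    c(0.15, 0.5, 0.2, 0.05, 0.1),
    c(0.05, 0.2, 0.45, 0.15, 0.15),
    c(0.02, 0.08, 0.25, 0.4, 0.25),
    c(0, 0, 0, 0, 1)))
  n_row <- 10000
  from <- rep(hf_states()[1:4], each = n_row)
  to <- unlist(lapply(1:4, function(s)
    hf_states()[sample.int(5, n_row, TRUE, prob = unclass(P)[s, ])]))
  est <- estimate_transitions(from, to)
  expect_lt(max(abs(unclass(est$matrix) - unclass(P))), 0.02)
})

test_that("run_cohort equals the matrix-power oracle and conserves mass", {
  set.seed(42)
  for (rep in 1:25) {
    P <- random_stochastic()
    init <- stats::rexp(5); init <- init / sum(init)
    k <- sample(0:10, 1)
    traj <- run_cohort(init, P, n_cycles = k)
    expect_equal(unname(unclass(traj)[k + 1, ]),
                 as.numeric(init %*% matpow_oracle(P, k)), tolerance = 1e-12)
    expect_true(all(abs(rowSums(traj) - 1) < 1e-9))
    # absorbing monotonicity, per cycle
    expect_true(all(diff(unclass(traj)[, 5]) >= -1e-15))
  }
  # identity matrix freezes any distribution
  traj <- run_cohort(c(0.4, 0.3, 0.2, 0.1, 0), diag(5), 10)
  expect_equal(unname(unclass(traj)[11, ]), c(0.4, 0.3, 0.2, 0.1, 0))
  # fully absorbed stays absorbed
  traj2 <- run_cohort(c(0, 0, 0, 0, 1), random_stochastic(), 5)
  expect_true(all(unclass(traj2)[, 5] == 1))
  expect_error(run_cohort(c(1, 0, 0, 0, 0), matrix(1, 5, 5)), "sum to 1")
  expect_error(run_cohort(c(2, 0, 0, 0, 0), diag(5)), "probability vector")
})

test_that("predict_at_years maps years to cycles without interpolation", {
  set.seed(8)
  P <- random_stochastic()
  init <- c(0.1, 0.3, 0.4, 0.2, 0)
  pred <- predict_at_years(init, P, years = c(1, 3, 5), percent = FALSE)
  full <- run_cohort(init, P, 10)
  expect_equal(unname(pred), unname(unclass(full)[c(3, 7, 11), ]))
  expect_error(predict_at_years(init, P, years = 1.2), "whole number")
  # identity matrix: year-5 distribution equals init
  pred5 <- predict_at_years(init, diag(5), years = 5, percent = FALSE)
  expect_equal(unname(pred5[1, ]), init)
  # percentage presentation: one decimal, rows sum to ~100
  predp <- predict_at_years(init, P, years = c(1, 3, 5))
  expect_true(all(abs(rowSums(predp) - 100) < 0.11))
  expect_equal(predp, round(predp, 1))
})

test_that("half-up rounding matches the reporting convention", {
  expect_equal(hfmarkov:::round_half_up(c(0.05, 0.15, 0.25) * 10, 0), c(1, 2, 3))
  expect_equal(hfmarkov:::round_half_up(42.25, 1), 42.3)
  expect_equal(hfmarkov:::round_half_up(-1.5), -2)
})

test_that("goodness-of-fit statistic matches hand arithmetic", {
  # observed exactly proportional to predicted -> statistic 0, p 1
  g0 <- gof_test(c(0.2, 0.3, 0.4, 0.05, 0.05), c(20, 30, 40, 5, 5))
  expect_equal(g0$statistic, 0)
  expect_equal(g0$p, 1)
  # two live categories, observed (60, 40), N = 100: X2 = (10^2/50)*2 = 4, df 1
  g1 <- gof_test(c(0.5, 0.5, 0, 0, 0), c(60, 40, 0, 0, 0))
  expect_equal(g1$statistic, 4)
  expect_equal(g1$df, 1L)
  expect_equal(g1$p, stats::pchisq(4, 1, lower.tail = FALSE))
  # oracle equivalence on a random instance
  set.seed(2)
  p <- c(0.1, 0.2, 0.3, 0.25, 0.15)
  obs <- as.integer(stats::rmultinom(1, 200, p))
  g2 <- gof_test(p, obs)
  expect_equal(g2$statistic, sum((obs - 200 * p)^2 / (200 * p)), tolerance = 1e-12)
  # zero-expected category with observations is an explicit error
  expect_error(gof_test(c(1, 0, 0, 0, 0), c(5, 1, 0, 0, 0)), "merge")
  expect_error(gof_test(c(0.5, 0.5, 0, 0, 0), c(0, 0, 0, 0, 0)), "positive")
  expect_warning(gof_test(c(0.5, 0.45, 0.05, 0, 0), c(30, 30, 2, 0, 0)), "below 5")
})

test_that("arm-distribution homogeneity test matches the 2xk oracle", {
  # identical distributions -> p 1
  d <- c(0.2, 0.2, 0.2, 0.2, 0.2)
  cmp <- compare_arm_distributions(d, d, 100, 100)
  expect_equal(cmp$p, 1)
  # disjoint degenerate distributions: statistic 200, df 1 after merging
  cmp2 <- compare_arm_distributions(c(1, 0, 0, 0, 0), c(0, 0, 0, 0, 1), 100, 100)
  expect_equal(cmp2$statistic, 200)
  expect_equal(cmp2$df, 1L)
  # random instance vs oracle
  set.seed(3)
  a <- stats::rexp(5); a <- a / sum(a)
  b <- stats::rexp(5); b <- b / sum(b)
  cmp3 <- compare_arm_distributions(a, b, 181, 213)
  tab <- rbind(round(181 * a), round(213 * b))
  expect_equal(cmp3$statistic, chisq_oracle(tab), tolerance = 1e-12)
  # both degenerate on the same state
  cmp4 <- compare_arm_distributions(c(0, 0, 0, 0, 1), c(0, 0, 0, 0, 1), 50, 50)
  expect_true(cmp4$degenerate)
  expect_equal(cmp4$p, 1)
  expect_error(compare_arm_distributions(d, d, 0, 10), "positive")
})

test_that("observed_distribution applies carry-forward and exclusion rules", {
  fu <- data.frame(
    patient_id = c("a", "b", "c"),
    month = c(12L, 6L, 6L),
    state = c("II", "CVE", "III"),
    censored = c(0L, 0L, 1L))
  od <- observed_distribution(fu, 12)
  expect_equal(od$n, 2L)
  expect_equal(unname(od$counts), c(0L, 1L, 0L, 0L, 1L))
  expect_error(observed_distribution(fu, 7), "multiple of 6")
  expect_error(observed_distribution(fu[3, ], 24), "determinate")
})

test_that("gof p-values are uniform when observations follow the prediction", {
  set.seed(77)
  p <- c(0.15, 0.25, 0.3, 0.1, 0.2)
  pv <- replicate(400, {
    obs <- as.integer(stats::rmultinom(1, 300, p))
    gof_test(p, obs)$p
  })
  # multinomial counts tie occasionally; KS remains a valid uniformity check
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("pre-tabulated transition counts reproduce patient-level estimation", {
  set.seed(12)
  syn <- generate_cohort(truth_params(seed = 12L))
  res <- suppressWarnings(markov_stage(syn))   # small-cell GOF warning expected
  dir <- withr::local_tempdir()
  f <- file.path(dir, "transitions.csv")
  write_transition_counts(res$per_arm$integrative$counts, f)
  rt <- read_transition_counts(f)
  expect_equal(rt, unclass(res$per_arm$integrative$counts),
               ignore_attr = TRUE)
  est <- transitions_from_counts(rt)
  expect_equal(unclass(est$matrix), unclass(res$per_arm$integrative$matrix),
               ignore_attr = TRUE)
  expect_error(read_transition_counts(withr::local_tempfile(lines = "a,b\n1,2",
                                                            fileext = ".csv")),
               "missing column")
})

test_that("end-to-end: estimated dynamics reproduce analytic truth at scale", {
  p <- truth_params(n_per_arm = c(integrative = 8000L, conventional = 1000L),
                    seed = 5L, dropout_rate_year = 0,
                    inhosp_death_rate = c(integrative = 0, conventional = 0))
  syn <- generate_cohort(p)
  res <- suppressWarnings(markov_stage(syn))
  a <- res$per_arm$integrative
  # estimated matrix near truth
  expect_lt(max(abs(unclass(a$matrix) - unclass(p$true_transition$integrative))),
            0.05)
  # predicted 1-year distribution near analytic init . P^2
  truthP <- unclass(p$true_transition$integrative)
  analytic <- as.numeric(a$init %*% matpow_oracle(truthP, 2))
  expect_lt(max(abs(unclass(a$trajectory)[3, ] - analytic)), 0.03)
  # and near the observed 12-month distribution
  expect_lt(max(abs(unclass(a$trajectory)[3, ] - a$observed_12mo$proportions)), 0.05)
})
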