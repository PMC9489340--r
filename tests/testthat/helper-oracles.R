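# Independent brute-force oracles; these deliberately avoid the package's
# own code paths (and the survival package) so they can arbitrate.

# product-limit estimator from first principles
km_oracle <- function(time, event) {
  tt <- sort(unique(time[event]))
  surv <- numeric(length(tt))
  s <- 1
  for (i in seq_along(tt)) {
    at_risk <- sum(time >= tt[i])
    d <- sum(time == tt[i] & event)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = tt, surv = surv)
}

# Pearson chi-square on a count table from margins
chisq_oracle <- function(tab) {
  tab <- as.matrix(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# matrix power by repeated squaring (independent of run_cohort's iteration)
matpow_oracle <- function(P, k) {
  out <- diag(nrow(P))
  base <- P
  while (k > 0) {
    if (k %% 2 == 1) out <- out %*% base
    base <- base %*% base
    k <- k %/% 2
  }
  out
}

# random row-stochastic 5x5 matrix with absorbing CVE (row 5)
random_stochastic <- function() {
  P <- matrix(stats::rexp(25), 5, 5)
  P <- P / rowSums(P)
  P[5, ] <- c(0, 0, 0, 0, 1)
  P
}

# small deterministic two-arm cohort for I/O and table tests
tiny_cohort <- function(n = 6L) {
  arm <- rep(c("integrative", "conventional"), length.out = n)
  height <- seq(160, 175, length.out = n)
  weight <- seq(60, 85, length.out = n)
  lvidd <- seq(4.5, 6.0, length.out = n)
  pwtd <- rep(1.0, n); swtd <- rep(1.1, n)
  lvm <- compute_lvm(lvidd, pwtd, swtd)
  bsa <- compute_bsa(height, weight)
  patients <- data.frame(
    patient_id = sprintf("T%02d", seq_len(n)), arm = arm,
    age = seq(50, 74, length.out = n), gender = rep(c("male", "female"), length.out = n),
    height_cm = height, weight_kg = weight,
    hypertension = rep(c(1L, 0L), length.out = n),
    coronary_artery_disease = rep(c(0L, 1L), length.out = n),
    arrhythmia = 0L, heart_valve_disease = 0L, diabetes = 1L,
    renal_insufficiency = 0L, diuretics = 1L, acei_arb = 1L,
    beta_blocker = 0L, mra = 1L, smoking = 0L,
    hb = seq(110, 140, length.out = n), cr = seq(70, 120, length.out = n),
    tg = 1.5, ldl_c = seq(1.8, 3.6, length.out = n), hs_crp = 4,
    nt_probnp = seq(500, 4000, length.out = n), hcy = 16,
    k = 4.1, na = 139, cl = 103, mg = 0.9,
    lvef = seq(35, 55, length.out = n), lvidd_cm = lvidd,
    pwtd_cm = pwtd, swtd_cm = swtd, lvm = lvm, bsa = bsa,
    lvmi = compute_lvmi(lvm, bsa),
    nyha_admission = rep(c(2L, 3L, 4L), length.out = n),
    nyha_discharge = rep(c(2L, 3L), length.out = n),
    died_in_hospital = 0L,
    hospital_days = 8L, entry_month = seq(0, 25, length.out = n)
  )
  followup <- data.frame(
    patient_id = rep(patients$patient_id, each = 2L),
    month = rep(c(6L, 12L), n),
    state = rep(c("III", "II"), n),
    censored = rep(c(0L, 1L), n)
  )
  # make one patient an event at 12 months
  followup$state[followup$patient_id == "T01" & followup$month == 12] <- "CVE"
  followup$censored[followup$patient_id == "T01"] <- 0L
  list(patients = patients, followup = followup)
}
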