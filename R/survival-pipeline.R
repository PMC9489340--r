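#' Covariate tiers for the nested Cox models
#'
#' Tier I adjusts for age and gender; tier II additionally for BMI, the four
#' medication classes, the six comorbidity flags, smoking history and the
#' in-hospital (admission) NYHA class; tier III further adds the continuous
#' laboratory values, LVEF and LVMI.
#'
#' @param tier "I", "II" or "III".
#' @return Character vector of covariate column names (excluding `arm`).
#' @export
tier_covariates <- function(tier = c("I", "II", "III")) {
  tier <- match.arg(tier)
  t1 <- c("age", "gender")
  t2 <- c(t1, "bmi", "diuretics", "acei_arb", "beta_blocker", "mra",
          "hypertension", "coronary_artery_disease", "arrhythmia",
          "heart_valve_disease", "diabetes", "renal_insufficiency",
          "smoking", "nyha_admission")
  t3 <- c(t2, "hb", "cr", "tg", "ldl_c", "hs_crp", "nt_probnp", "hcy",
          "k", "na", "cl", "mg", "lvef", "lvmi")
  switch(tier, I = t1, II = t2, III = t3)
}

#' Build the per-patient survival dataset from follow-up records
#'
#' Event time is the month of the first CVE record; CVE-free patients are
#' censored at their last observed visit month. Events sit on the 6-month
#' visit grid by design (interval censoring is not modelled). Patients with
#' no follow-up records (e.g. in-hospital deaths) are excluded with a
#' warning. Covariates are selected per tier; the admission NYHA class enters
#' as a factor.
#'
#' @param followup follow-up data frame.
#' @param patients patients data frame.
#' @param tier Cox adjustment tier ("I", "II", "III") or `NULL` for the
#'   unadjusted arm-only dataset.
#' @return Data frame of class `hf_survival_dataset` with columns `time`,
#'   `event`, `arm`, plus the tier covariates; attribute `tier`.
#' @export
make_survival_dataset <- function(followup, patients, tier = "III") {
  fu <- followup
  fu$state <- normalize_states(fu$state)
  cve_month <- tapply(ifelse(fu$state == "CVE", fu$month, Inf), fu$patient_id, min)
  last_month <- tapply(fu$month, fu$patient_id, max)
  ids <- names(last_month)
  missing_fu <- setdiff(patients$patient_id, ids)
  if (length(missing_fu) > 0L) {
    warning(length(missing_fu), " patient(s) without follow-up records excluded",
            call. = FALSE)
  }
  orphan <- setdiff(ids, patients$patient_id)
  if (length(orphan) > 0L) {
    stop("follow-up records for unknown patient(s): ",
         paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
  }
  event <- is.finite(cve_month[ids])
  time <- ifelse(event, cve_month[ids], last_month[ids])
  pt <- patients[match(ids, patients$patient_id), , drop = FALSE]
  ds <- data.frame(patient_id = ids, time = as.numeric(time),
                   event = as.logical(event), arm = pt$arm)
  if (!is.null(tier)) {
    covs <- tier_covariates(tier)
    if (!"bmi" %in% names(pt)) {
      pt$bmi <- pt$weight_kg / (pt$height_cm / 100)^2
    }
    for (v in covs) ds[[v]] <- pt[[v]]
    ds$gender <- factor(ds$gender, levels = c("female", "male"))
    if ("nyha_admission" %in% covs) {
      ds$nyha_admission <- factor(ds$nyha_admission, levels = 1:4)
    }
  }
  ds$arm <- factor(ds$arm, levels = c("conventional", "integrative"))
  rownames(ds) <- NULL
  structure(ds, class = c("hf_survival_dataset", "data.frame"), tier = tier)
}

#' Kaplan-Meier survival tables and log-rank comparison
#'
#' Fits the product-limit estimator per arm (Greenwood variance, log-scale
#' confidence intervals), reports the restricted mean survival time over
#' \[0, max observed time\] and the median survival time with confidence
#' intervals, overall and per arm, and compares the arms with the log-rank
#' test. "Average survival time" is the restricted mean: under heavy
#' censoring the unrestricted mean is undefined.
#'
#' @param ds an [make_survival_dataset()] data frame (columns `time`,
#'   `event`, `arm`).
#' @param rmean horizon for the restricted mean (default: largest observed
#'   time).
#' @return List of class `hf_km_table`: `table` (per-group RMST and median
#'   with CIs), `curves` (step coordinates per arm), `logrank`
#'   (`chisq`, `df`, `p`; `NA` if only one arm is present).
#' @export
km_fit <- function(ds, rmean = NULL) {
  if (sum(ds$event) < 1L) stop("at least one event is required", call. = FALSE)
  if (is.null(rmean)) rmean <- max(ds$time)
  one_group <- function(sub, label) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = sub,
                             conf.type = "log")
    s <- summary(fit, rmean = rmean)$table
    q <- stats::quantile(fit, probs = 0.5)
    data.frame(group = label, n = nrow(sub), events = sum(sub$event),
               rmean = unname(s[["rmean"]]), rmean_se = unname(s[["se(rmean)"]]),
               rmean_lcl = unname(s[["rmean"]] - 1.96 * s[["se(rmean)"]]),
               rmean_ucl = unname(s[["rmean"]] + 1.96 * s[["se(rmean)"]]),
               median = unname(q$quantile), median_lcl = unname(q$lower),
               median_ucl = unname(q$upper))
  }
  curves_group <- function(sub, label) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = sub)
    data.frame(group = label, time = c(0, fit$time), surv = c(1, fit$surv),
               lower = c(1, fit$lower), upper = c(1, fit$upper),
               n_risk = c(fit$n, fit$n.risk))
  }
  arms <- levels(droplevels(factor(ds$arm)))
  tab <- do.call(rbind, c(list(one_group(ds, "all")),
                          lapply(arms, function(a) one_group(ds[ds$arm == a, ], a))))
  curves <- do.call(rbind, lapply(arms, function(a) curves_group(ds[ds$arm == a, ], a)))
  logrank <- list(chisq = NA_real_, df = NA_integer_, p = NA_real_)
  if (length(arms) >= 2L) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ arm, data = ds)
    logrank <- list(chisq = unname(sd$chisq), df = length(sd$n) - 1L,
                    p = stats::pchisq(sd$chisq, length(sd$n) - 1L, lower.tail = FALSE))
  }
  structure(list(table = tab, curves = curves, logrank = logrank, rmean_horizon = rmean),
            class = "hf_km_table")
}

#' @export
print.hf_km_table <- function(x, ...) {
  cat("Kaplan-Meier survival (restricted mean over [0, ",
      x$rmean_horizon, "] months)\n", sep = "")
  print(x$table, digits = 4)
  if (!is.na(x$logrank$p)) {
    cat(sprintf("Log-rank: chisq = %.2f, df = %d, p = %.4g\n",
                x$logrank$chisq, x$logrank$df, x$logrank$p))
  }
  invisible(x)
}

#' Nested Cox proportional-hazards models
#'
#' Fits the tiered Cox model (Efron tie handling; the 6-month visit grid
#' produces heavy ties) and reports the hazard ratio of the integrative vs
#' conventional arm with Wald 95% CI and p-value, -2 log-likelihood, the
#' omnibus likelihood-ratio chi-square, and Harrell's C computed on the
#' fitted risk scores. Constant covariate columns are dropped with a message;
#' an arm column with a single level, non-convergence, or an infinite
#' coefficient raises an error. When events fall below 10 per covariate the
#' function warns (events-per-variable heuristic) but proceeds.
#'
#' @param ds an [make_survival_dataset()] built with the matching tier.
#' @param tier "I", "II" or "III"; `NULL` fits the unadjusted arm-only model.
#' @return List of class `hf_cox_result`: `tier`, `hr`, `ci95`, `p`,
#'   `covariates`, `n`, `n_events`, `minus2loglik`, `omnibus_chi2`,
#'   `omnibus_p`, `c_statistic`, `fit` (the `coxph` object).
#' @export
cox_fit <- function(ds, tier = attr(ds, "tier")) {
  if (length(unique(ds$arm[!is.na(ds$arm)])) < 2L) {
    stop("arm is constant: hazard ratio undefined (degenerate design)", call. = FALSE)
  }
  covs <- if (is.null(tier)) character(0) else intersect(tier_covariates(tier), names(ds))
  keep <- character(0)
  for (v in covs) {
    x <- ds[[v]]
    if (length(unique(x[!is.na(x)])) > 1L) keep <- c(keep, v)
    else message("dropping constant covariate: ", v)
  }
  n_events <- sum(ds$event)
  if (n_events < 10 * (length(keep) + 1L)) {
    warning("fewer than 10 events per covariate (", n_events, " events, ",
            length(keep) + 1L, " covariates)", call. = FALSE)
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~ arm",
                                 paste(c("", keep), collapse = " + ")))
  fit <- survival::coxph(fml, data = ds, ties = "efron", x = FALSE)
  if (any(is.na(stats::coef(fit)[1L]))) {
    stop("Cox model failed to estimate the arm coefficient", call. = FALSE)
  }
  co <- summary(fit)
  arm_row <- grep("^arm", rownames(co$coefficients))[1]
  beta <- co$coefficients[arm_row, "coef"]
  se <- co$coefficients[arm_row, "se(coef)"]
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 15) {
    stop("arm coefficient unstable (possible complete separation)", call. = FALSE)
  }
  structure(list(
    tier = if (is.null(tier)) "unadjusted" else tier,
    hr = exp(beta),
    ci95 = c(low = exp(beta - 1.96 * se), high = exp(beta + 1.96 * se)),
    p = co$coefficients[arm_row, "Pr(>|z|)"],
    covariates = keep, n = co$n, n_events = n_events,
    minus2loglik = -2 * fit$loglik[2L],
    omnibus_chi2 = unname(2 * (fit$loglik[2L] - fit$loglik[1L])),
    omnibus_p = unname(co$logtest["pvalue"]),
    c_statistic = unname(co$concordance["C"]),
    fit = fit
  ), class = "hf_cox_result")
}

#' @export
print.hf_cox_result <- function(x, ...) {
  cat(sprintf("Cox model (tier %s): HR %.3f (%.3f, %.3f), p = %.4g\n",
              x$tier, x$hr, x$ci95[["low"]], x$ci95[["high"]], x$p))
  cat(sprintf("  n = %d, events = %d, -2logL = %.3f, omnibus chi2 = %.3f, C = %.3f\n",
              x$n, x$n_events, x$minus2loglik, x$omnibus_chi2, x$c_statistic))
  invisible(x)
}

#' Time-dependent ROC at a fixed horizon (IPCW, cumulative/dynamic)
#'
#' Treats event-by-horizon status as the label: cases are subjects with an
#' observed event at or before `horizon`, controls those still event-free
#' beyond it. Censoring is handled by inverse-probability-of-censoring
#' weighting with the Kaplan-Meier estimate of the censoring distribution
#' (Uno-style cumulative/dynamic estimator). Both the AUC and the curve are
#' invariant under strictly monotone transforms of the risk score.
#'
#' @param ds survival dataset (`time`, `event`).
#' @param risk_score numeric vector, higher = higher risk.
#' @param horizon months; must not exceed the maximum follow-up.
#' @return List of class `hf_tdroc`: `auc`, `horizon`, `curve` (data frame of
#'   FPR/TPR coordinates), `n_cases`, `n_controls`.
#' @export
time_dependent_roc <- function(ds, risk_score, horizon) {
  if (horizon > max(ds$time)) stop("horizon exceeds maximum follow-up", call. = FALSE)
  if (length(risk_score) != nrow(ds)) stop("risk_score length mismatch", call. = FALSE)
  is_case <- ds$time <= horizon & ds$event
  is_control <- ds$time > horizon
  if (sum(is_case) == 0L) stop("no events before the horizon: AUC undefined", call. = FALSE)
  if (sum(is_control) == 0L) stop("no controls beyond the horizon: AUC undefined", call. = FALSE)
  # KM of the censoring distribution G(t) = P(C > t)
  cfit <- survival::survfit(survival::Surv(time, !event) ~ 1, data = ds)
  G <- function(t) {
    # left-continuous evaluation G(t-)
    idx <- findInterval(t - 1e-9, cfit$time)
    ifelse(idx == 0L, 1, cfit$surv[pmax(idx, 1L)])
  }
  w <- numeric(nrow(ds))
  w[is_case] <- 1 / pmax(G(ds$time[is_case]), 1e-12)
  w[is_control] <- 1 / pmax(G(horizon), 1e-12)
  m_case <- risk_score[is_case]; w_case <- w[is_case]
  m_ctrl <- risk_score[is_control]; w_ctrl <- w[is_control]
  # weighted concordance of cases over controls
  ord <- order(m_ctrl)
  m_ctrl <- m_ctrl[ord]; w_ctrl <- w_ctrl[ord]
  cw <- cumsum(w_ctrl)
  tot_ctrl <- cw[length(cw)]
  lt <- findInterval(m_case - 1e-12, m_ctrl)       # controls strictly below
  le <- findInterval(m_case + 1e-12, m_ctrl)       # controls <= case
  below <- ifelse(lt == 0L, 0, cw[pmax(lt, 1L)])
  upto <- ifelse(le == 0L, 0, cw[pmax(le, 1L)])
  ties <- upto - below
  auc <- sum(w_case * (below + 0.5 * ties)) / (sum(w_case) * tot_ctrl)
  # ROC coordinates over unique thresholds
  thr <- sort(unique(risk_score[is_case | is_control]), decreasing = TRUE)
  tpr <- vapply(thr, function(c) sum(w_case[m_case >= c]) / sum(w_case), 0)
  fpr <- vapply(thr, function(c) sum(w_ctrl[m_ctrl >= c]) / tot_ctrl, 0)
  structure(list(auc = auc, horizon = horizon,
                 curve = data.frame(threshold = thr, fpr = c(fpr), tpr = c(tpr)),
                 n_cases = sum(is_case), n_controls = sum(is_control)),
            class = "hf_tdroc")
}

#' @export
print.hf_tdroc <- function(x, ...) {
  cat(sprintf("Time-dependent ROC at %g months: AUC = %.3f (%d cases, %d controls)\n",
              x$horizon, x$auc, x$n_cases, x$n_controls))
  invisible(x)
}

#' Subgroup sensitivity analysis
#'
#' Refits the tier-III Cox model within each stratum of each stratifying
#' variable (the stratifier itself is removed from the covariate list;
#' covariates constant within a stratum are dropped automatically). Strata
#' with fewer than 5 events are flagged low-information; strata with no
#' events, or where the model cannot be fit, report `NA` rather than raising.
#'
#' @param ds tier-III survival dataset.
#' @param strata_spec named list; each element either a numeric cut-point
#'   vector (continuous variable split at cut-points, right-open bins) or
#'   `NULL`/`"levels"` to stratify on the variable's observed levels.
#' @return Data frame: variable, stratum, n, n integrative, events, HR, CI,
#'   p, low_information flag.
#' @export
subgroup_analysis <- function(ds, strata_spec = list(
                                age = 65, nyha_admission = NULL,
                                renal_insufficiency = NULL,
                                coronary_artery_disease = NULL)) {
  rows <- list()
  for (v in names(strata_spec)) {
    if (!v %in% names(ds)) stop("unknown stratifying variable: ", v, call. = FALSE)
    spec <- strata_spec[[v]]
    if (is.numeric(spec)) {
      cuts <- sort(spec)
      g <- cut(as.numeric(ds[[v]]), breaks = c(-Inf, cuts, Inf), right = FALSE,
               labels = if (length(cuts) == 1L) {
                 c(paste0("<", cuts), paste0(">=", cuts))
               } else NULL)
    } else {
      g <- factor(ds[[v]])
    }
    for (lev in levels(droplevels(g))) {
      sub <- ds[!is.na(g) & g == lev, , drop = FALSE]
      sub[[v]] <- NULL                       # stratifier leaves the model
      attr(sub, "tier") <- attr(ds, "tier")
      ev <- sum(sub$event)
      res <- tryCatch(
        suppressWarnings(suppressMessages(cox_fit(sub, tier = attr(ds, "tier")))),
        error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, stratum = lev, n = nrow(sub),
        n_integrative = sum(sub$arm == "integrative"), events = ev,
        hr = if (is.null(res)) NA_real_ else res$hr,
        ci_low = if (is.null(res)) NA_real_ else res$ci95[["low"]],
        ci_high = if (is.null(res)) NA_real_ else res$ci95[["high"]],
        p = if (is.null(res)) NA_real_ else res$p,
        low_information = ev < 5
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
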