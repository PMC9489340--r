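#' Derived echocardiographic indices
#'
#' Left ventricular mass by the Devereux formula,
#' `LVM (g) = 0.8 * 1.04 * ((LVIDd + PWTd + SWTd)^3 - LVIDd^3) + 0.6`,
#' body surface area from the linear height/weight formula
#' `BSA (m^2) = 0.0061 * height_cm + 0.0128 * weight_kg - 0.1529`,
#' and the left ventricular mass index `LVMI = LVM / BSA`.
#'
#' Echo dimensions are in centimetres; values of LVIDd outside the
#' plausibility window `[2, 9]` cm (e.g. inputs accidentally supplied in mm)
#' are rejected unless `check_units = FALSE`.
#'
#' @param lvidd left ventricular end-diastolic diameter, cm.
#' @param pwtd posterior wall thickness (diastole), cm.
#' @param swtd septal wall thickness (diastole), cm.
#' @param check_units apply the LVIDd plausibility gate?
#' @return `compute_lvm`: left ventricular mass in grams.
#' @export
compute_lvm <- function(lvidd, pwtd, swtd, check_units = TRUE) {
  for (nm in c("lvidd", "pwtd", "swtd")) {
    v <- get(nm)
    if (any(!is.finite(v)) || any(v <= 0)) {
      stop("echo dimension '", nm, "' must be positive and finite", call. = FALSE)
    }
  }
  if (check_units && any(lvidd < 2 | lvidd > 9)) {
    stop("LVIDd outside plausible range [2, 9] cm; dimensions must be in cm ",
         "(set check_units = FALSE to override)", call. = FALSE)
  }
  0.8 * 1.04 * ((lvidd + pwtd + swtd)^3 - lvidd^3) + 0.6
}

#' @rdname compute_lvm
#' @param height_cm height in cm.
#' @param weight_kg weight in kg.
#' @return `compute_bsa`: body surface area in m^2.
#' @export
compute_bsa <- function(height_cm, weight_kg) {
  if (any(!is.finite(height_cm)) || any(height_cm <= 0)) {
    stop("height_cm must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(weight_kg)) || any(weight_kg <= 0)) {
    stop("weight_kg must be positive and finite", call. = FALSE)
  }
  bsa <- 0.0061 * height_cm + 0.0128 * weight_kg - 0.1529
  if (any(bsa <= 0)) {
    stop("computed BSA is non-positive; check height/weight units", call. = FALSE)
  }
  bsa
}

#' @rdname compute_lvm
#' @param lvm left ventricular mass, g.
#' @param bsa body surface area, m^2.
#' @return `compute_lvmi`: LVM indexed to BSA, g m^-2.
#' @export
compute_lvmi <- function(lvm, bsa) {
  if (any(!is.finite(bsa)) || any(bsa <= 0)) {
    stop("bsa must be positive and finite", call. = FALSE)
  }
  lvm / bsa
}

# columns every patients table must carry
.patient_required_cols <- c(
  "patient_id", "arm", "age", "gender", "height_cm", "weight_kg",
  "hypertension", "coronary_artery_disease", "arrhythmia",
  "heart_valve_disease", "diabetes", "renal_insufficiency",
  "diuretics", "acei_arb", "beta_blocker", "mra", "smoking",
  "hb", "cr", "tg", "ldl_c", "hs_crp", "nt_probnp", "hcy",
  "k", "na", "cl", "mg",
  "lvef", "lvidd_cm", "pwtd_cm", "swtd_cm", "lvm", "bsa", "lvmi",
  "nyha_admission", "nyha_discharge", "died_in_hospital",
  "hospital_days", "entry_month"
)

.flag_cols <- c("hypertension", "coronary_artery_disease", "arrhythmia",
                "heart_valve_disease", "diabetes", "renal_insufficiency",
                "diuretics", "acei_arb", "beta_blocker", "mra", "smoking",
                "died_in_hospital")

#' Validate a patients table
#'
#' Checks the schema and the record invariants: arm labels, age within the
#' 18--75 inclusion window, positive anthropometry, boolean flags, NYHA codes
#' in 1--4 (discharge 0 only for in-hospital deaths), and agreement of the
#' stored derived indices (LVM, BSA, LVMI) with recomputation from the raw
#' dimensions to within 1e-9.
#'
#' @param patients data frame, one row per patient.
#' @return `patients`, invisibly.
#' @export
validate_patients <- function(patients) {
  miss <- setdiff(.patient_required_cols, names(patients))
  if (length(miss) > 0L) {
    stop("patients table missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad_row <- function(cond, what) {
    if (any(cond, na.rm = TRUE)) {
      stop(what, " (row(s) ", paste(utils::head(which(cond), 5), collapse = ", "),
           ")", call. = FALSE)
    }
  }
  bad_row(!patients$arm %in% c("integrative", "conventional"),
          "arm must be 'integrative' or 'conventional'")
  bad_row(duplicated(patients$patient_id), "duplicated patient_id")
  bad_row(patients$age < 18 | patients$age > 75, "age outside inclusion window [18, 75]")
  bad_row(!patients$gender %in% c("male", "female"), "gender must be 'male' or 'female'")
  bad_row(patients$height_cm <= 0 | patients$weight_kg <= 0,
          "height and weight must be positive")
  bad_row(patients$hospital_days < 0, "hospital_days must be non-negative")
  for (fc in .flag_cols) {
    bad_row(!patients[[fc]] %in% c(0L, 1L, TRUE, FALSE),
            paste0("flag column '", fc, "' must be 0/1"))
  }
  bad_row(!patients$nyha_admission %in% 1:4, "nyha_admission must be in 1..4")
  ok_dis <- patients$nyha_discharge %in% 1:4 |
    (patients$nyha_discharge == 0 & patients$died_in_hospital == 1)
  bad_row(!ok_dis, "nyha_discharge must be 1..4, or 0 with died_in_hospital = 1")
  lvm <- compute_lvm(patients$lvidd_cm, patients$pwtd_cm, patients$swtd_cm)
  bsa <- compute_bsa(patients$height_cm, patients$weight_kg)
  bad_row(abs(lvm - patients$lvm) > 1e-9, "stored LVM disagrees with recomputation")
  bad_row(abs(bsa - patients$bsa) > 1e-9, "stored BSA disagrees with recomputation")
  bad_row(abs(compute_lvmi(lvm, bsa) - patients$lvmi) > 1e-9,
          "stored LVMI disagrees with recomputation")
  invisible(patients)
}

#' Validate a follow-up table
#'
#' Months must be multiples of 6 in \[6, 36\] and strictly increasing per
#' patient; no record may follow a CVE (the absorbing state); states are
#' coded 1--4 or "CVE"; `censored` is 0/1.
#'
#' @param followup data frame with columns `patient_id`, `month`, `state`,
#'   `censored`.
#' @return `followup`, invisibly.
#' @export
validate_followup <- function(followup) {
  miss <- setdiff(c("patient_id", "month", "state", "censored"), names(followup))
  if (length(miss) > 0L) {
    stop("followup table missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- which(followup$month %% 6 != 0 | followup$month < 6 | followup$month > 36)
  if (length(bad) > 0L) {
    stop("follow-up month must be a multiple of 6 in [6, 36] (row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), ")", call. = FALSE)
  }
  st <- normalize_states(followup$state)
  assert_states(st)
  if (!all(followup$censored %in% c(0L, 1L, TRUE, FALSE))) {
    stop("censored must be 0/1", call. = FALSE)
  }
  ord <- order(followup$patient_id, followup$month)
  fu <- followup[ord, , drop = FALSE]
  by_id <- split(seq_len(nrow(fu)), fu$patient_id)
  for (idx in by_id) {
    m <- fu$month[idx]
    if (anyDuplicated(m)) stop("duplicate visit month for patient ",
                               fu$patient_id[idx[1]], call. = FALSE)
    s <- normalize_states(fu$state[idx])
    cve <- which(s == "CVE")
    if (length(cve) > 0L && cve[1L] < length(idx)) {
      stop("records after first CVE for patient ", fu$patient_id[idx[1]],
           call. = FALSE)
    }
  }
  invisible(followup)
}

#' Read and write a cohort as delimited text
#'
#' `read_cohort` loads `patients.csv` and `followup.csv`, validates both
#' tables, and returns them as a list. `write_cohort` is its inverse;
#' write-then-read round-trips every field.
#'
#' @param patients_path,followup_path CSV paths.
#' @return `read_cohort`: list with elements `patients` and `followup`.
#' @export
read_cohort <- function(patients_path, followup_path) {
  patients <- utils::read.csv(patients_path, stringsAsFactors = FALSE)
  followup <- utils::read.csv(followup_path, stringsAsFactors = FALSE)
  validate_patients(patients)
  validate_followup(followup)
  followup$state <- normalize_states(followup$state)
  list(patients = patients, followup = followup)
}

#' @rdname read_cohort
#' @param cohort list with `patients` and `followup` data frames.
#' @param dir output directory (created if absent).
#' @return `write_cohort`: named character vector of the files written.
#' @export
write_cohort <- function(cohort, dir) {
  validate_patients(cohort$patients)
  validate_followup(cohort$followup)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pp <- file.path(dir, "patients.csv")
  fp <- file.path(dir, "followup.csv")
  utils::write.csv(cohort$patients, pp, row.names = FALSE)
  utils::write.csv(cohort$followup, fp, row.names = FALSE)
  c(patients = pp, followup = fp)
}

#' Default categorization thresholds
#'
#' Clinically conventional cut-points for turning continuous labs and echo
#' indices into categorical covariates. These defaults are reference-range
#' style placeholders chosen by this package, not values taken from any
#' particular study's supplementary materials; override them freely via the
#' `thresholds` argument or a YAML/JSON config file.
#'
#' @return Named list mapping variable name to an ordered numeric vector of
#'   cut-points.
#' @export
default_thresholds <- function() {
  list(
    ldl_c = 3.4,            # mmol/L
    hcy = 15,               # umol/L
    hs_crp = 3,             # mg/L
    nt_probnp = 1800,       # pg/mL
    k = c(3.5, 5.5),        # mmol/L
    na = c(135, 145),       # mmol/L
    cl = c(96, 106),        # mmol/L
    mg = c(0.75, 1.02),     # mmol/L
    lvef = c(40, 50),       # %
    lvmi = 115              # g/m^2
  )
}

#' Load a thresholds config file (YAML or JSON)
#'
#' @param path config path; keys are variable names, values ordered cut-points.
#' @return Named list of numeric cut-point vectors.
#' @export
read_thresholds <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  lapply(cfg, as.numeric)
}

#' Add categorical companions for continuous variables
#'
#' Each configured variable `v` gains a column `v_cat` binning its values by
#' the half-open convention `[low, cut) / [cut, high)`: a value exactly at a
#' cut-point falls in the upper bin. The binning is a partition: every finite
#' value falls in exactly one bin; `NA` stays `NA`.
#'
#' @param cohort patients data frame.
#' @param thresholds named list of ordered cut-point vectors (default:
#'   [default_thresholds()]). An empty list returns the cohort unchanged.
#' @return The cohort with added `<var>_cat` factor columns.
#' @export
categorize_covariates <- function(cohort, thresholds = default_thresholds()) {
  if (length(thresholds) == 0L) return(cohort)
  unknown <- setdiff(names(thresholds), names(cohort))
  if (length(unknown) > 0L) {
    stop("thresholds config names unknown variable(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (v in names(thresholds)) {
    cuts <- sort(as.numeric(thresholds[[v]]))
    breaks <- c(-Inf, cuts, Inf)
    labs <- if (length(cuts) == 1L) {
      c("low", "high")
    } else {
      paste0("bin", seq_len(length(cuts) + 1L))
    }
    cohort[[paste0(v, "_cat")]] <- cut(cohort[[v]], breaks = breaks,
                                       labels = labs, right = FALSE)
  }
  cohort
}

#' Default variable spec for the baseline table
#'
#' Declares each baseline variable's type: `normal` (mean +/- SD, t-test),
#' `nonnormal` (median (Q1, Q3), Kruskal-Wallis), or `count` (n (%),
#' chi-square). Skewed labs (Cr, Hs-CRP, NT-proBNP) default to nonnormal;
#' there is no automatic normality testing in the default path.
#'
#' @return Data frame with columns `variable`, `type`.
#' @export
default_baseline_spec <- function() {
  rbind(
    data.frame(variable = c("age", "weight_kg", "bmi", "hb", "tg", "ldl_c",
                            "hcy", "k", "na", "cl", "mg", "lvef", "lvmi",
                            "hospital_days"),
               type = "normal"),
    data.frame(variable = c("cr", "hs_crp", "nt_probnp"), type = "nonnormal"),
    data.frame(variable = c("gender", "diuretics", "acei_arb", "beta_blocker",
                            "mra", "hypertension", "coronary_artery_disease",
                            "arrhythmia", "heart_valve_disease", "diabetes",
                            "renal_insufficiency", "smoking", "nyha_admission"),
               type = "count")
  )
}

# Pearson chi-square on an r x c count table; no continuity correction.
chisq_stat <- function(tab) {
  tab <- as.matrix(tab)
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  tab <- tab[keep_r, keep_c, drop = FALSE]
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df,
       p = if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Baseline characteristics comparison (Table-1 style)
#'
#' Compares the two arms variable by variable with automatic test dispatch:
#' the independent-samples t-test for variables declared normal, the
#' Kruskal-Wallis rank-sum test for non-normal ones, and the Pearson
#' chi-square test (no continuity correction) for count variables. Summaries
#' follow the matching convention: mean +/- SD, median (Q1, Q3), or n (%).
#' Missing values are handled variable-wise (complete-case per row of the
#' table); arms with fewer than 2 non-missing observations for a continuous
#' variable flag that row `untestable` rather than dropping it.
#'
#' @param patients patients data frame (both arms present). A `bmi` column is
#'   derived from height/weight if absent.
#' @param spec variable spec (see [default_baseline_spec()]).
#' @return Data frame of class `hf_baseline_table`: one row per variable (or
#'   per level for multi-level count variables) with the arm summaries, test
#'   name, statistic and p-value.
#' @export
baseline_table <- function(patients, spec = default_baseline_spec()) {
  if (!all(c("integrative", "conventional") %in% patients$arm)) {
    stop("both arms must be present in the cohort", call. = FALSE)
  }
  if (!"bmi" %in% names(patients)) {
    patients$bmi <- patients$weight_kg / (patients$height_cm / 100)^2
  }
  gi <- patients$arm == "integrative"
  rows <- vector("list", nrow(spec))
  for (k in seq_len(nrow(spec))) {
    v <- spec$variable[k]; type <- spec$type[k]
    if (!v %in% names(patients)) {
      stop("baseline spec names unknown variable: ", v, call. = FALSE)
    }
    x <- patients[[v]]
    if (type %in% c("normal", "nonnormal")) {
      xi <- x[gi & !is.na(x)]; xc <- x[!gi & !is.na(x)]
      if (length(xi) < 2L || length(xc) < 2L) {
        rows[[k]] <- data.frame(variable = v, level = NA, type = type,
                                integrative = NA, conventional = NA,
                                test = NA, statistic = NA_real_, p = NA_real_,
                                untestable = TRUE)
        next
      }
      if (type == "normal") {
        tt <- stats::t.test(xi, xc, var.equal = TRUE)
        summi <- sprintf("%.2f ± %.2f", mean(xi), stats::sd(xi))
        summc <- sprintf("%.2f ± %.2f", mean(xc), stats::sd(xc))
        rows[[k]] <- data.frame(variable = v, level = NA, type = type,
                                integrative = summi, conventional = summc,
                                test = "t-test", statistic = unname(tt$statistic),
                                p = tt$p.value, untestable = FALSE)
      } else {
        kw <- stats::kruskal.test(list(xi, xc))
        qs <- function(z) sprintf("%.2f (%.2f, %.2f)", stats::median(z),
                                  stats::quantile(z, 0.25), stats::quantile(z, 0.75))
        rows[[k]] <- data.frame(variable = v, level = NA, type = type,
                                integrative = qs(xi), conventional = qs(xc),
                                test = "kruskal-wallis",
                                statistic = unname(kw$statistic),
                                p = kw$p.value, untestable = FALSE)
      }
    } else {
      xt <- x[!is.na(x)]
      gt <- gi[!is.na(x)]
      tab <- table(factor(gt, levels = c(TRUE, FALSE)), xt)
      ct <- chisq_stat(tab)
      lev <- colnames(tab)
      pct <- function(n, tot) sprintf("%d (%.1f)", n, 100 * n / tot)
      sub <- data.frame(
        variable = v, level = lev, type = type,
        integrative = pct(as.integer(tab["TRUE", ]), sum(gt)),
        conventional = pct(as.integer(tab["FALSE", ]), sum(!gt)),
        test = "chi-square", statistic = ct$statistic, p = ct$p,
        untestable = FALSE
      )
      # binary 0/1 flags: keep only the positive level
      if (identical(sort(lev), c("0", "1"))) sub <- sub[sub$level == "1", ]
      rows[[k]] <- sub
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("hf_baseline_table", "data.frame")
  out
}
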