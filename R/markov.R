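#' Construct a validated 5x5 transition matrix
#'
#' A transition matrix over the states `hf_states()` must be row-stochastic
#' (each row sums to 1 within 1e-12) and have CVE absorbing, i.e. the CVE row
#' is the unit vector on CVE.
#'
#' @param P numeric 5x5 matrix of transition probabilities; rows index the
#'   source state, columns the destination.
#' @param provenance "estimated" or "specified"; recorded for reporting.
#' @param zero_row_policy policy string recorded by [estimate_transitions()];
#'   `NA` for specified matrices.
#' @return An object of class `hf_transition_matrix` (a matrix with
#'   attributes).
#' @export
transition_matrix <- function(P, provenance = c("specified", "estimated"),
                              zero_row_policy = NA_character_) {
  provenance <- match.arg(provenance)
  P <- as.matrix(P)
  if (!is.numeric(P) || any(dim(P) != 5L)) {
    stop("transition matrix must be a numeric 5x5 matrix", call. = FALSE)
  }
  if (any(P < -1e-12) || any(P > 1 + 1e-12)) {
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  }
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-12)) {
    stop("transition matrix rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")", call. = FALSE)
  }
  if (abs(P[.CVE, .CVE] - 1) > 1e-12) {
    stop("CVE must be absorbing: P[CVE, CVE] must equal 1", call. = FALSE)
  }
  dimnames(P) <- list(from = hf_states(), to = hf_states())
  structure(P, class = c("hf_transition_matrix", "matrix", "array"),
            provenance = provenance, zero_row_policy = zero_row_policy)
}

#' @export
print.hf_transition_matrix <- function(x, digits = 4, ...) {
  cat("6-month transition matrix (", attr(x, "provenance"), ")\n", sep = "")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Estimate 6-month transition probabilities from paired observations
#'
#' Each paired observation records a patient's state at discharge (baseline)
#' and at the 6-month visit. The maximum-likelihood estimate of the
#' transition probability is the row-normalised count matrix:
#' `P[i, j] = n[i, j] / n[i]`. The CVE row is forced to the unit vector
#' (absorbing); no pair may start in CVE.
#'
#' Source states with zero observations are handled by `zero_row_policy`:
#' `"inert"` (default) assigns self-transition probability 1 with a warning,
#' so the model never invents transitions that were never observed;
#' `"uniform"` spreads mass evenly over all five destinations.
#'
#' @param from,to character (or integer 1--4 coded) vectors of equal length:
#'   state at discharge and state at 6 months.
#' @param zero_row_policy "inert" or "uniform".
#' @return A list with elements `counts` (5x5 integer matrix with class
#'   `hf_transition_counts`) and `matrix` (an [transition_matrix()] object).
#' @export
estimate_transitions <- function(from, to, zero_row_policy = c("inert", "uniform")) {
  zero_row_policy <- match.arg(zero_row_policy)
  if (length(from) != length(to)) stop("from and to must have equal length", call. = FALSE)
  if (length(from) == 0L) stop("no paired observations to estimate from", call. = FALSE)
  from <- normalize_states(from); to <- normalize_states(to)
  assert_states(to)
  assert_states(from)
  if (any(from == "CVE")) {
    stop("pairs starting in the absorbing state (CVE) are invalid", call. = FALSE)
  }
  st <- hf_states()
  counts <- table(factor(from, levels = st), factor(to, levels = st))
  counts <- matrix(as.integer(counts), 5, 5,
                   dimnames = list(from = st, to = st))
  P <- matrix(0, 5, 5, dimnames = dimnames(counts))
  ntot <- rowSums(counts)
  zero_rows <- character(0)
  for (i in 1:4) {
    if (ntot[i] > 0) {
      P[i, ] <- counts[i, ] / ntot[i]
    } else {
      zero_rows <- c(zero_rows, st[i])
      if (zero_row_policy == "inert") P[i, i] <- 1 else P[i, ] <- 0.2
    }
  }
  P[.CVE, ] <- c(0, 0, 0, 0, 1)
  if (length(zero_rows) > 0L) {
    warning("no observations starting in state(s) ",
            paste(zero_rows, collapse = ", "), "; applied '",
            zero_row_policy, "' zero-row policy", call. = FALSE)
  }
  list(counts = structure(counts, class = c("hf_transition_counts", "matrix", "array")),
       matrix = transition_matrix(P, provenance = "estimated",
                                  zero_row_policy = zero_row_policy))
}

#' Read / write transition counts as delimited text
#'
#' The long format has columns `from_state,to_state,count`, so tabulated
#' transfer-frequency tables can be fed to the model directly, bypassing
#' patient-level estimation.
#'
#' @param path file path.
#' @return `read_transition_counts`: a 5x5 integer count matrix.
#' @export
read_transition_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("from_state", "to_state", "count")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("transition-count file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  from <- normalize_states(df$from_state); to <- normalize_states(df$to_state)
  assert_states(from, allow_cve = FALSE); assert_states(to)
  if (any(df$count < 0) || any(df$count != round(df$count))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  st <- hf_states()
  m <- matrix(0L, 5, 5, dimnames = list(from = st, to = st))
  for (k in seq_len(nrow(df))) {
    m[from[k], to[k]] <- m[from[k], to[k]] + as.integer(df$count[k])
  }
  m
}

#' @rdname read_transition_counts
#' @param counts 5x5 count matrix.
#' @export
write_transition_counts <- function(counts, path) {
  st <- hf_states()
  idx <- which(counts > 0, arr.ind = TRUE)
  df <- data.frame(from_state = st[idx[, 1]], to_state = st[idx[, 2]],
                   count = counts[idx])
  utils::write.csv(df[order(df$from_state, df$to_state), ], path, row.names = FALSE)
  invisible(path)
}

#' Estimate a transition matrix from a pre-tabulated count matrix
#'
#' @param counts 5x5 non-negative count matrix (CVE row must be all zero).
#' @inheritParams estimate_transitions
#' @return As [estimate_transitions()].
#' @export
transitions_from_counts <- function(counts, zero_row_policy = c("inert", "uniform")) {
  zero_row_policy <- match.arg(zero_row_policy)
  if (any(counts[.CVE, ] != 0)) {
    stop("no patient may start in the absorbing state: CVE row must be zero",
         call. = FALSE)
  }
  st <- hf_states()
  idx <- which(counts > 0, arr.ind = TRUE)
  from <- rep(st[idx[, 1]], counts[idx])
  to <- rep(st[idx[, 2]], counts[idx])
  estimate_transitions(from, to, zero_row_policy = zero_row_policy)
}

#' Cycle a cohort distribution through the Markov model
#'
#' Propagates an initial probability distribution over the five states by
#' repeated right-multiplication with the transition matrix:
#' `v[k + 1] = v[k] %*% P`. One cycle is 6 months; the default 10 cycles
#' cover 60 months.
#'
#' @param init numeric length-5 probability vector over `hf_states()`
#'   (the discharge-state distribution, CVE mass usually 0).
#' @param P a [transition_matrix()] (or coercible matrix).
#' @param n_cycles non-negative integer number of 6-month cycles.
#' @return A `(n_cycles + 1) x 5` matrix of class `hf_state_distribution`;
#'   row `k + 1` is the distribution after `k` cycles, with attribute
#'   `months = 6 * (0:n_cycles)`.
#' @export
run_cohort <- function(init, P, n_cycles = 10L) {
  if (!inherits(P, "hf_transition_matrix")) P <- transition_matrix(P)
  init <- as.numeric(init)
  if (length(init) != 5L || any(init < -1e-12) || abs(sum(init) - 1) > 1e-9) {
    stop("init must be a length-5 probability vector summing to 1", call. = FALSE)
  }
  n_cycles <- as.integer(n_cycles)
  if (is.na(n_cycles) || n_cycles < 0L) stop("n_cycles must be >= 0", call. = FALSE)
  out <- matrix(NA_real_, n_cycles + 1L, 5L,
                dimnames = list(cycle = 0:n_cycles, state = hf_states()))
  v <- init
  out[1L, ] <- v
  Pm <- unclass(P)
  if (n_cycles > 0L) for (k in seq_len(n_cycles)) {
    v <- as.numeric(v %*% Pm)
    out[k + 1L, ] <- v
  }
  structure(out, class = c("hf_state_distribution", "matrix", "array"),
            months = 6L * (0:n_cycles))
}

#' Predicted state distributions at whole years of therapy
#'
#' Reports the cohort distribution after 2y cycles for each requested year y
#' (one cycle = 6 months; no interpolation between cycles is performed).
#'
#' @inheritParams run_cohort
#' @param years integer years; each must map to a whole number of cycles.
#' @param percent if `TRUE` (default) return percentages rounded half-up to
#'   one decimal, the conventional presentation; internal math is always full
#'   precision.
#' @return A `length(years) x 5` matrix (rows named by year).
#' @export
predict_at_years <- function(init, P, years = c(1, 3, 5), percent = TRUE) {
  cycles <- years * 2
  if (any(abs(cycles - round(cycles)) > 1e-9)) {
    stop("each year must correspond to a whole number of 6-month cycles",
         call. = FALSE)
  }
  cycles <- as.integer(round(cycles))
  traj <- run_cohort(init, P, n_cycles = max(cycles))
  out <- unclass(traj)[cycles + 1L, , drop = FALSE]
  rownames(out) <- paste0("year_", years)
  if (percent) out <- round_half_up(100 * out, 1)
  out
}

# round half away from zero (half-up for positives), matching the
# conventional presentation of percentages; base round() is banker's rounding
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Chi-square goodness-of-fit test of predicted vs observed state frequencies
#'
#' Compares the model-predicted distribution at a cycle against observed
#' per-state counts: `X2 = sum((O - N p)^2 / (N p))` over the compared
#' states, `df = k - 1`, with the p-value from the chi-square upper tail.
#' States with predicted probability 0 and observed count 0 are dropped from
#' the comparison; a state with predicted probability 0 but positive observed
#' count makes the statistic infinite and raises an error advising a category
#' merge. Expected counts below 5 trigger a warning (`small_cells`).
#'
#' @param predicted numeric length-5 probability vector (or any length k).
#' @param observed_counts non-negative integer vector of the same length.
#' @return A list of class `hf_gof` with elements `statistic`, `df`, `p`,
#'   `expected`, `observed`, `small_cells`.
#' @export
gof_test <- function(predicted, observed_counts) {
  predicted <- as.numeric(predicted)
  observed_counts <- as.numeric(observed_counts)
  if (length(predicted) != length(observed_counts)) {
    stop("predicted and observed_counts must have equal length", call. = FALSE)
  }
  if (any(observed_counts < 0)) stop("observed counts must be non-negative", call. = FALSE)
  N <- sum(observed_counts)
  if (N <= 0) stop("observed total must be positive", call. = FALSE)
  if (abs(sum(predicted) - 1) > 1e-9 || any(predicted < -1e-12)) {
    stop("predicted must be a probability vector summing to 1", call. = FALSE)
  }
  if (any(predicted <= 0 & observed_counts > 0)) {
    stop("observed counts fall in a category with predicted probability 0; ",
         "merge categories before testing", call. = FALSE)
  }
  keep <- predicted > 0
  p <- predicted[keep] / sum(predicted[keep])
  O <- observed_counts[keep]
  E <- N * p
  stat <- sum((O - E)^2 / E)
  df <- length(O) - 1L
  small <- E < 5
  if (any(small)) {
    warning(sum(small), " expected cell(s) below 5; consider merging adjacent ",
            "NYHA categories", call. = FALSE)
  }
  structure(list(statistic = stat, df = df,
                 p = stats::pchisq(stat, df, lower.tail = FALSE),
                 expected = E, observed = O, small_cells = sum(small)),
            class = "hf_gof")
}

#' @export
print.hf_gof <- function(x, ...) {
  cat(sprintf("Chi-square goodness of fit: X2 = %.3f, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p))
  invisible(x)
}

#' Chi-square homogeneity test between two arms' predicted distributions
#'
#' Converts the two probability vectors to counts (`round(n * p)`), drops
#' states empty in both arms, and runs a chi-square test of homogeneity on
#' the resulting 2 x k table (no continuity correction).
#'
#' @param dist_a,dist_b probability vectors over the same state space.
#' @param n_a,n_b positive cohort sizes.
#' @return List with `statistic`, `df`, `p`, `table`, `degenerate` flag.
#' @export
compare_arm_distributions <- function(dist_a, dist_b, n_a, n_b) {
  if (length(dist_a) != length(dist_b)) stop("state spaces differ", call. = FALSE)
  if (n_a <= 0 || n_b <= 0) stop("cohort sizes must be positive", call. = FALSE)
  tab <- rbind(a = round(n_a * as.numeric(dist_a)),
               b = round(n_b * as.numeric(dist_b)))
  keep <- colSums(tab) > 0
  tab <- tab[, keep, drop = FALSE]
  if (ncol(tab) <= 1L) {
    return(list(statistic = 0, df = 0L, p = 1, table = tab, degenerate = TRUE))
  }
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       table = tab, degenerate = FALSE)
}

#' Observed state distribution at a follow-up month
#'
#' Tabulates the states of patients with a determinate status at `month`:
#' either a visit record at exactly that month, or a CVE at or before it
#' (CVE is absorbing, so a prior event is carried forward). Patients censored
#' before the month contribute nothing to the denominator.
#'
#' @param followup follow-up data frame (columns `patient_id`, `month`,
#'   `state`, see [read_cohort()]).
#' @param month visit month, a positive multiple of 6.
#' @return List with `counts` (named length-5 integer vector), `proportions`,
#'   and `n` (the determinate denominator).
#' @export
observed_distribution <- function(followup, month) {
  if (month <= 0 || month %% 6 != 0) stop("month must be a positive multiple of 6", call. = FALSE)
  st <- hf_states()
  fu <- followup
  fu$state <- normalize_states(fu$state)
  assert_states(fu$state)
  cve_by <- tapply(ifelse(fu$state == "CVE", fu$month, Inf), fu$patient_id, min)
  state_at <- tapply(seq_len(nrow(fu)), fu$patient_id, function(idx) {
    hit <- idx[fu$month[idx] == month & fu$state[idx] != "CVE"]
    if (length(hit) > 0L) fu$state[hit[1L]] else NA_character_
  })
  ids <- names(cve_by)
  resolved <- ifelse(cve_by[ids] <= month, "CVE", state_at[ids])
  resolved <- resolved[!is.na(resolved)]
  if (length(resolved) == 0L) {
    stop("no patient has a determinate status at month ", month, call. = FALSE)
  }
  counts <- table(factor(resolved, levels = st))
  counts <- stats::setNames(as.integer(counts), st)
  list(counts = counts, proportions = counts / sum(counts), n = sum(counts))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
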