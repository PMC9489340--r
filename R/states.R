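#' Model state space
#'
#' The five-state space used throughout the package: NYHA functional classes
#' I--IV plus the composite cardiovascular event state ("CVE", pooling
#' heart-failure readmission, acute coronary syndrome, stroke and
#' cardiovascular death). CVE is the unique absorbing state: once a patient
#' enters it the trajectory terminates.
#'
#' @return Character vector of the five ordered state labels.
#' @export
hf_states <- function() c("I", "II", "III", "IV", "CVE")

#' @rdname hf_states
#' @export
hf_absorbing_state <- function() "CVE"

# index of the absorbing state in hf_states()
.CVE <- 5L

#' Validate a state label vector
#'
#' @param x character vector of state labels.
#' @param allow_cve should "CVE" be accepted?
#' @return `x`, invisibly, after validation.
#' @keywords internal
assert_states <- function(x, allow_cve = TRUE) {
  valid <- if (allow_cve) hf_states() else setdiff(hf_states(), "CVE")
  bad <- setdiff(unique(as.character(x)), valid)
  if (length(bad) > 0L) {
    stop("invalid state label(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(valid, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

# Coerce integer-coded NYHA (1-4) or labels to the canonical labels.
normalize_states <- function(x) {
  x <- as.character(x)
  map <- c("1" = "I", "2" = "II", "3" = "III", "4" = "IV")
  hit <- x %in% names(map)
  x[hit] <- map[x[hit]]
  x
}
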