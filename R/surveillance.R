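## Post-polypectomy surveillance scheme ----------------------------------
##
## Persons with intermediate- or high-risk adenomas at the colonoscopy after
## a positive FIT enter colonoscopic surveillance: high-risk findings get a
## first exam after 1 year, intermediate-risk after 3 years. Adherence is
## 100% for the first exam and a run-constant probability afterwards; a
## missed exam is (by default) rescheduled one recall interval later. After
## an attended exam the default scheme recalls at 3 years for any non-cancer
## finding; two consecutive negative exams discharge the person back to
## routine screening, invasive cancer exits the model, and no exam is ever
## performed at age 80 or older. The whole transition table (intervals,
## actions, discharge rule, miss policy) is configuration-driven.

#' Schedule the first surveillance exam after an index finding
#'
#' @param category Finding at the colonoscopy after a positive FIT:
#'   `"intermediate_risk"` or `"high_risk"` (other categories do not enter
#'   surveillance and are a contract error).
#' @param age Age in years at the index colonoscopy.
#' @param params A `crc_parameters` set.
#' @return Years until the first surveillance exam, or `NA` when the person
#'   would already have reached the age cap at the scheduled time (no exam;
#'   the person exits).
#' @export
#' @examples
#' p <- sample_parameters(fix_parameters(load_config()))
#' schedule_surveillance("high_risk", age = 69, p)   # exam at age 70
#' schedule_surveillance("intermediate_risk", 78, p) # NA: would be 81
schedule_surveillance <- function(category, age, params) {
  if (!all(category %in% c("intermediate_risk", "high_risk"))) {
    stop("schedule_surveillance: only intermediate_risk and high_risk ",
         "findings enter surveillance")
  }
  offset <- unname(params$surv_entry[category])
  ifelse(age + offset < params$surv_age_cap, offset, NA_real_)
}

#' Surveillance routing after an attended exam
#'
#' Looks up the configured transition for an exam finding and applies the
#' consecutive-negative discharge rule.
#'
#' @param category Finding at the surveillance exam: one of `"negative"`,
#'   `"low_risk"`, `"intermediate_high"`, `"cancer"`.
#' @param consec_negatives Consecutive negative exams *including* this one
#'   when `category == "negative"`.
#' @param params A `crc_parameters` set.
#' @return List with `action` (`"reschedule"`, `"discharge"`, or `"exit"`)
#'   and `interval` (years to the next surveillance exam or to the routine
#'   re-entry).
#' @export
surveillance_transition <- function(category, consec_negatives, params) {
  i <- match(category, params$surv_table$outcome)
  if (is.na(i)) stop("unknown surveillance outcome: ", category)
  if (category == "negative" && params$surv_discharge_negatives > 0L &&
      consec_negatives >= params$surv_discharge_negatives) {
    return(list(action = "discharge",
                interval = params$surv_discharge_interval))
  }
  list(action = params$surv_table$action[i],
       interval = params$surv_table$interval[i])
}
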