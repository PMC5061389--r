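# Shared fixtures: configurations are built in code, scaled down from the
# packaged defaults where a test does not need the full 100,000 persons.

# Default configuration with the population scaled by `scale`.
small_config <- function(scale = 0.05) {
  cfg <- crcdemand::load_config()
  cfg$demography$initial_size <-
    as.integer(round(cfg$demography$initial_size * scale))
  cfg$demography$entrants <- round(cfg$demography$entrants * scale)
  cfg
}

# Point-mass configuration: every prior collapsed to a constant, with
# optional field overrides (see crcdemand::fix_parameters).
point_config <- function(overrides = list(), scale = 0.05) {
  crcdemand::fix_parameters(small_config(scale), overrides)
}

# A one-person deterministic configuration: fixed starting age, immortal,
# no entrants, and a fully deterministic screening chain ending in the
# supplied index colonoscopy result. Used for scheduler walk-throughs.
walkthrough_config <- function(age, index_result = "high_risk",
                               surveillance_result = "negative",
                               adherence = 1) {
  cfg <- crcdemand::load_config()
  cfg$demography$initial_size <- 1L
  cfg$demography$age_range <- c(age, age + 1e-9)
  cfg$demography$entrants[] <- 0
  cfg$demography$mortality$male[] <- 0
  cfg$demography$mortality$female[] <- 0
  idx <- c(negative = 1, low_risk = 2, intermediate_risk = 3,
           high_risk = 4, cancer = 5)[[index_result]]
  sv <- c(negative = 1, low_risk = 2, intermediate_high = 3,
          cancer = 4)[[surveillance_result]]
  dist5 <- numeric(5); dist5[idx] <- 1
  dist4 <- numeric(4); dist4[sv] <- 1
  crcdemand::fix_parameters(cfg, list(
    exclusion_initial = 0, exclusion_successive = 0, opportunistic = 0,
    participation_initial = 1, participation_prev_participant = 1,
    participation_prev_nonparticipant = 1,
    positivity_initial = 1, positivity_successive = 1,
    refusal = 0, second_look = 0,
    result_initial = dist5, result_successive = dist5,
    surveillance_result = dist4, adherence = adherence))
}

# Independent table-driven scheduler: replays one person's surveillance
# episode(s) by hand from a parameter set, for a fully deterministic
# screening chain (participation/positivity 1, fixed outcomes, immortal
# person). Counts index colonoscopies and attended surveillance exams over
# the horizon. Written without reference to the engine's event loop.
replay_walkthrough <- function(params, entry_time, age_at_entry,
                               index_result = "high_risk",
                               surveillance_result = "negative",
                               adherence = 1, horizon = 20) {
  index_exams <- 0L
  surv_exams <- 0L
  t <- entry_time
  repeat {
    if (t >= horizon || age_at_entry + (t - entry_time) >= 70) break
    # routine round: participate, FIT+, colonoscopy with the fixed finding
    index_exams <- index_exams + 1L
    if (!index_result %in% c("intermediate_risk", "high_risk")) break
    entry <- unname(params$surv_entry[[index_result]])
    texam <- t + entry
    consec <- 0L
    repeat {
      if (texam >= horizon) return(list(index = index_exams,
                                        surveillance = surv_exams))
      if (age_at_entry + (texam - entry_time) >= params$surv_age_cap) {
        # exam would fall at or past the age cap: episode ends, person exits
        return(list(index = index_exams, surveillance = surv_exams))
      }
      first <- consec == 0L && surv_exams == 0L  # crude: per-episode first
      # attended? (adherence is 0 or 1 in walk-throughs)
      attended <- first || adherence >= 1
      if (!attended) {
        # missed exams are rescheduled one recall interval forever;
        # nothing more is attended in an all-or-nothing walk-through
        return(list(index = index_exams, surveillance = surv_exams))
      }
      surv_exams <- surv_exams + 1L
      if (surveillance_result == "negative") consec <- consec + 1L else
        consec <- 0L
      tr <- crcdemand::surveillance_transition(surveillance_result, consec,
                                               params)
      if (tr$action == "exit") return(list(index = index_exams,
                                           surveillance = surv_exams))
      if (tr$action == "discharge") {
        t <- texam + tr$interval
        break
      }
      texam <- texam + tr$interval
    }
    if (age_at_entry + (t - entry_time) >= params$surv_age_cap) break
  }
  list(index = index_exams, surveillance = surv_exams)
}
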