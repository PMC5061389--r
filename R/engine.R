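## Discrete-event engine ------------------------------------------------
##
## Persons are mutually independent, so the event calendar can be processed
## in vectorized passes: each pass handles every person's next pending event
## (routine invitation or surveillance exam), whatever its time stamp, and
## schedules the following one. Per-person event sequences are strictly
## ordered; cross-person order is irrelevant to every tally, which is keyed
## only by the calendar year of the event. A run over 100,000 persons and 20
## years completes in ~20-25 passes.

.tally_fields <- c("invited", "participants", "successive_participants",
                   "fit_positives", "index_total", "index_first",
                   "index_negative", "index_low_risk",
                   "index_intermediate_risk", "index_high_risk",
                   "index_cancer",
                   "surveillance", "surv_negative", "surv_low_risk",
                   "surv_intermediate_high", "surv_cancer")

# Vectorized categorical draw: u ~ U(0,1) against per-row cumulative
# probabilities (rows of `cum`), returning integer categories 1..k.
.draw_category <- function(u, cum) {
  k <- ncol(cum)
  cat <- rep(1L, length(u))
  for (j in seq_len(k - 1L)) cat <- cat + (u > cum[, j])
  cat
}

#' Route one invitation through exclusion and opportunistic screening
#'
#' The invitation process first applies exclusion (full stratified probability
#' at a person's initial screening round, medical-reasons-only probability at
#' successive rounds), then opportunistic screening (the invitee reports a
#' colonoscopy within the previous five years and is deferred 4 years if it
#' was within 3 years, else 2 years); everyone else is invited and proceeds
#' to the participation decision.
#'
#' @param age,gender Vectors of ages (in [50, 70)) and genders (1/2).
#' @param initial Logical vector: is this the person's initial screening
#'   round?
#' @param params A `crc_parameters` set.
#' @return Factor with levels `excluded`, `deferred_4y`, `deferred_2y`,
#'   `invited`.
#' @export
process_invitation <- function(age, gender, initial, params) {
  if (any(age < 50 | age >= 70)) {
    stop("process_invitation: age at a routine invitation must be in [50, 70)")
  }
  s <- stratum_index(gender, age)
  n <- length(age)
  p_ex <- ifelse(initial, params$exclusion_initial[s],
                 params$exclusion_successive)
  out <- rep("invited", n)
  excl <- stats::runif(n) < p_ex
  opp <- !excl & stats::runif(n) < params$opportunistic[s]
  recent <- stats::runif(n) < params$opportunistic_recent_share
  out[excl] <- "excluded"
  out[opp & recent] <- "deferred_4y"
  out[opp & !recent] <- "deferred_2y"
  factor(out, levels = c("excluded", "deferred_4y", "deferred_2y", "invited"))
}

#' Draw the participation decision
#'
#' Initial screening rounds use the stratified participation probability;
#' successive rounds use the probability conditioned on whether the person
#' participated in their previous round. Not picking up the FIT kit and not
#' returning it are both non-participation.
#'
#' @param age,gender Vectors of ages and genders.
#' @param initial Logical: first time the person faces the participation
#'   decision?
#' @param prev_participant Logical: did the person participate in the
#'   previous round (ignored when `initial`)?
#' @inheritParams process_invitation
#' @return Logical vector: participates this round.
#' @export
draw_participation <- function(age, gender, initial, prev_participant,
                               params) {
  s <- stratum_index(gender, age)
  p <- ifelse(initial, params$participation_initial[s],
              ifelse(prev_participant, params$participation_prev_participant,
                     params$participation_prev_nonparticipant))
  stats::runif(length(p)) < p
}

#' Draw the FIT result
#'
#' Positivity (hemoglobin at or above the program cut-off) uses the
#' stratified probability at a person's first-ever screen and the pooled
#' successive-screen probability afterwards.
#'
#' @param initial_screen Logical: is this the person's first returned kit?
#' @inheritParams draw_participation
#' @return Logical vector: FIT positive.
#' @export
draw_fit_result <- function(age, gender, initial_screen, params) {
  s <- stratum_index(gender, age)
  p <- ifelse(initial_screen, params$positivity_initial[s],
              params$positivity_successive)
  stats::runif(length(p)) < p
}

#' Perform index colonoscopies for FIT-positive persons
#'
#' Applies stratified colonoscopy refusal, then draws the result category
#' (normal, low-risk adenomas, intermediate-risk adenomas, high-risk
#' adenomas, invasive cancer) from the initial- or successive-screen
#' empirical distribution, and flags second-look exams (repeat colonoscopy
#' within one year, same result category) with the configured probability.
#'
#' @inheritParams draw_fit_result
#' @return A data frame with columns `refused` (logical), `category` (integer
#'   1..5 into `negative, low_risk, intermediate_risk, high_risk, cancer`;
#'   `NA` when refused), `second_look` (logical) and `second_look_delay`
#'   (uniform on (0, 1] years; `NA` unless a second look is indicated).
#' @export
perform_index_colonoscopy <- function(age, gender, initial_screen, params) {
  s <- stratum_index(gender, age)
  n <- length(age)
  refused <- stats::runif(n) < params$refusal[s]
  category <- rep(NA_integer_, n)
  second_look <- rep(FALSE, n)
  delay <- rep(NA_real_, n)
  att <- which(!refused)
  if (length(att)) {
    cum <- matrix(rep(cumsum(params$result_successive), each = length(att)),
                  nrow = length(att))
    ini <- initial_screen[att]
    if (any(ini)) {
      cum[ini, ] <- matrix(rep(cumsum(params$result_initial),
                               each = sum(ini)), nrow = sum(ini))
    }
    category[att] <- .draw_category(stats::runif(length(att)), cum)
    sl <- stats::runif(length(att)) < params$second_look
    second_look[att] <- sl
    delay[att[sl]] <- stats::runif(sum(sl))
  }
  data.frame(refused = refused, category = category,
             second_look = second_look, second_look_delay = delay)
}

## Full run --------------------------------------------------------------

# Process the pending routine invitations at indices `ids` (all alive, times
# within horizon). Mutates the person-state environment `st` and adds to the
# tally matrix stored there.
.step_invitations <- function(st, ids, params) {
  t <- st$next_time[ids]
  age <- st$age0[ids] + t
  yr <- floor(t) + 1L

  # ageing out of the target population (surveillance persons never get here)
  keep <- age < 70
  st$next_kind[ids[!keep]] <- 0L
  ids <- ids[keep]; t <- t[keep]; age <- age[keep]; yr <- yr[keep]
  if (!length(ids)) return(invisible())
  s <- stratum_index(st$gender[ids], age)

  # exclusion before invitation
  initial_round <- !st$invited_ever[ids]
  st$invited_ever[ids] <- TRUE
  p_ex <- ifelse(initial_round, params$exclusion_initial[s],
                 params$exclusion_successive)
  excl <- stats::runif(length(ids)) < p_ex
  st$next_kind[ids[excl]] <- 0L
  ids <- ids[!excl]; t <- t[!excl]; yr <- yr[!excl]; s <- s[!excl]
  if (!length(ids)) return(invisible())

  # opportunistic screening: deferred, not invited this round
  opp <- stats::runif(length(ids)) < params$opportunistic[s]
  if (any(opp)) {
    recent <- stats::runif(sum(opp)) < params$opportunistic_recent_share
    defer <- ifelse(recent, params$reinvite[["opportunistic_recent"]],
                    params$reinvite[["opportunistic_old"]])
    st$next_time[ids[opp]] <- t[opp] + defer
  }
  ids <- ids[!opp]; t <- t[!opp]; yr <- yr[!opp]; s <- s[!opp]
  if (!length(ids)) return(invisible())
  .add_tally(st, "invited", yr)
  .trace(st, "invitation", ids, t)

  # participation (pick-up and kit return collapsed into one stage)
  first_decision <- !st$part_stage[ids]
  p_part <- ifelse(first_decision, params$participation_initial[s],
                   ifelse(st$prev_part[ids],
                          params$participation_prev_participant,
                          params$participation_prev_nonparticipant))
  st$part_stage[ids] <- TRUE
  part <- stats::runif(length(ids)) < p_part
  np <- ids[!part]
  st$prev_part[np] <- FALSE
  st$next_time[np] <- t[!part] + params$reinvite[["non_participation"]]
  ids <- ids[part]; t <- t[part]; yr <- yr[part]; s <- s[part]
  if (!length(ids)) return(invisible())
  st$prev_part[ids] <- TRUE
  initial_screen <- !st$has_screened[ids]
  .add_tally(st, "participants", yr)
  .add_tally(st, "successive_participants", yr[!initial_screen])

  # FIT result
  p_pos <- ifelse(initial_screen, params$positivity_initial[s],
                  params$positivity_successive)
  st$has_screened[ids] <- TRUE
  pos <- stats::runif(length(ids)) < p_pos
  neg <- ids[!pos]
  st$next_time[neg] <- t[!pos] + params$reinvite[["negative_fit"]]
  ids <- ids[pos]; t <- t[pos]; yr <- yr[pos]; s <- s[pos]
  initial_screen <- initial_screen[pos]
  if (!length(ids)) return(invisible())
  .add_tally(st, "fit_positives", yr)

  # colonoscopy refusal
  ref <- stats::runif(length(ids)) < params$refusal[s]
  st$next_time[ids[ref]] <- t[ref] + params$reinvite[["refusal"]]
  ids <- ids[!ref]; t <- t[!ref]; yr <- yr[!ref]
  initial_screen <- initial_screen[!ref]
  if (!length(ids)) return(invisible())

  # index colonoscopy (first exam)
  .add_tally(st, "index_first", yr)
  .add_tally(st, "index_total", yr)
  .trace(st, "index_colonoscopy", ids, t)

  # second look within 1 year, counted in the calendar year it occurs
  sl <- stats::runif(length(ids)) < params$second_look
  if (any(sl)) {
    ts <- t[sl] + stats::runif(sum(sl))
    ok <- ts < st$horizon & ts < st$death[ids[sl]]
    .add_tally(st, "index_total", floor(ts[ok]) + 1L)
    .trace(st, "second_look", ids[sl][ok], ts[ok])
  }

  # result category
  cum <- matrix(rep(cumsum(params$result_successive), each = length(ids)),
                nrow = length(ids))
  if (any(initial_screen)) {
    cum[initial_screen, ] <- matrix(rep(cumsum(params$result_initial),
                                        each = sum(initial_screen)),
                                    nrow = sum(initial_screen))
  }
  cat <- .draw_category(stats::runif(length(ids)), cum)
  for (k in 1:5) {
    .add_tally(st, paste0("index_", .result_categories[k]), yr[cat == k])
  }

  # routing
  st$next_time[ids[cat == 1L]] <-
    t[cat == 1L] + params$reinvite[["negative_colonoscopy"]]
  st$next_time[ids[cat == 2L]] <- t[cat == 2L] + params$reinvite[["low_risk"]]
  st$next_kind[ids[cat == 5L]] <- 0L  # invasive cancer: exit from the model
  for (k in 3:4) {
    sel <- which(cat == k)
    if (!length(sel)) next
    entry <- params$surv_entry[[c("intermediate_risk", "high_risk")[k - 2L]]]
    texam <- t[sel] + entry
    ok <- st$age0[ids[sel]] + texam < params$surv_age_cap
    st$next_kind[ids[sel][!ok]] <- 0L
    enter <- ids[sel][ok]
    st$next_kind[enter] <- 2L
    st$next_time[enter] <- texam[ok]
    st$surv_first[enter] <- TRUE
    st$surv_intv[enter] <- entry
    st$consec_neg[enter] <- 0L
  }
  invisible()
}

# Process pending surveillance exams at indices `ids`.
.step_surveillance <- function(st, ids, params) {
  t <- st$next_time[ids]
  yr <- floor(t) + 1L

  # adherence: 100% for the first surveillance exam, the run-constant
  # probability afterwards; a missed exam either ends the surveillance
  # episode (default) or is rescheduled one recall interval later,
  # depending on the configured miss policy (always subject to the age cap)
  attend <- st$surv_first[ids] | stats::runif(length(ids)) < params$adherence
  miss <- ids[!attend]
  if (length(miss)) {
    if (identical(params$surv_on_miss, "reschedule")) {
      tnext <- t[!attend] + st$surv_intv[miss]
      ok <- st$age0[miss] + tnext < params$surv_age_cap
      st$next_time[miss[ok]] <- tnext[ok]
      st$next_kind[miss[!ok]] <- 0L
    } else {
      # exit surveillance; persons still of screening age rejoin the
      # routine program at the next scheduled round (age is re-checked
      # when that invitation is processed)
      st$next_kind[miss] <- 1L
      st$next_time[miss] <- t[!attend] + params$reinvite[["non_participation"]]
    }
  }
  ids <- ids[attend]; t <- t[attend]; yr <- yr[attend]
  if (!length(ids)) return(invisible())
  st$surv_first[ids] <- FALSE
  .add_tally(st, "surveillance", yr)
  .trace(st, "surveillance_colonoscopy", ids, t)

  cum <- matrix(rep(cumsum(params$surveillance_result), each = length(ids)),
                nrow = length(ids))
  cat <- .draw_category(stats::runif(length(ids)), cum)
  for (k in 1:4) {
    .add_tally(st, paste0("surv_", .surv_categories[k]), yr[cat == k])
  }

  # consecutive-negative bookkeeping and guideline discharge: after the
  # configured number of consecutive negative exams the person is discharged
  # from surveillance back to routine screening (age re-checked there)
  st$consec_neg[ids[cat == 1L]] <- st$consec_neg[ids[cat == 1L]] + 1L
  st$consec_neg[ids[cat %in% 2:3]] <- 0L
  discharged <- rep(FALSE, length(ids))
  if (params$surv_discharge_negatives > 0L) {
    discharged <- cat == 1L &
      st$consec_neg[ids] >= params$surv_discharge_negatives
    back <- ids[discharged]
    st$next_kind[back] <- 1L
    st$next_time[back] <- t[discharged] + params$surv_discharge_interval
  }

  action <- params$surv_table$action[cat]
  st$next_kind[ids[action == "exit"]] <- 0L
  res <- which(action == "reschedule" & !discharged)
  if (length(res)) {
    intv <- params$surv_table$interval[cat[res]]
    tnext <- t[res] + intv
    ok <- st$age0[ids[res]] + tnext < params$surv_age_cap
    keep <- ids[res][ok]
    st$next_time[keep] <- tnext[ok]
    st$surv_intv[keep] <- intv[ok]
    st$next_kind[ids[res][!ok]] <- 0L
  }
  invisible()
}

.trace <- function(st, kind, ids, t) {
  if (!isTRUE(st$do_trace) || !length(ids)) return(invisible())
  st$trace_rows[[length(st$trace_rows) + 1L]] <-
    data.frame(person = ids, event = kind, time = t,
               age = st$age0[ids] + t)
  invisible()
}

.add_tally <- function(st, field, yrs) {
  if (!length(yrs)) return(invisible())
  st$tally[, field] <- st$tally[, field] +
    tabulate(yrs, nbins = nrow(st$tally))
  invisible()
}

#' Run one 20-year microsimulation replication
#'
#' Samples one parameter set from the configured priors (unless a realised
#' `crc_parameters` is supplied), builds the initial population and yearly
#' entrants, and processes every screening and surveillance event through the
#' simulated horizon. Persons exit at death, at detection of invasive cancer,
#' on permanent exclusion, or by ageing out (over 69 for routine screening,
#' over 79 for surveillance).
#'
#' @param config A `crc_config` from [load_config()].
#' @param seed Optional integer; when given, the run is seeded (and therefore
#'   fully reproducible) via its own L'Ecuyer-CMRG stream.
#' @param params Optional realised `crc_parameters`; by default one set is
#'   sampled from the priors at the start of the run.
#' @param demography Optional [demography()] override.
#' @param trace Collect a per-event log (person, event, time, age); slow on
#'   large populations, intended for audits and invariant checks.
#' @return An object of class `crc_run`: list with `yearly` (data frame of
#'   per-calendar-year tallies), `mean_participation` and `mean_positivity`
#'   (20-year ratio-of-sums summaries), `adherence`, and `params`.
#' @export
#' @examples
#' cfg <- load_config()
#' cfg$demography$initial_size <- 2000L
#' cfg$demography$entrants <- round(cfg$demography$entrants * 0.02)
#' r <- run_simulation(cfg, seed = 1)
#' head(r$yearly)
run_simulation <- function(config, seed = NULL, params = NULL,
                           demography = NULL, trace = FALSE) {
  stopifnot(inherits(config, "crc_config"))
  if (!is.null(seed)) {
    old <- .set_rng_stream(seed)
    on.exit(.restore_rng(old), add = TRUE)
  }
  demo <- if (is.null(demography)) config$demography else demography
  if (is.null(params)) params <- sample_parameters(config)
  horizon <- demo$horizon

  persons <- init_population(demo)
  for (y in as.integer(names(demo$entrants))) {
    if (y >= demo$start_year + horizon) next
    persons <- .bind_persons(persons, annual_entrants(demo, y))
  }

  st <- as.environment(persons)
  st$horizon <- horizon
  st$do_trace <- isTRUE(trace)
  st$trace_rows <- list()
  st$tally <- matrix(0L, nrow = horizon, ncol = length(.tally_fields),
                     dimnames = list(NULL, .tally_fields))

  repeat {
    pending <- st$next_kind > 0L & st$next_time < horizon
    if (!any(pending)) break
    ids <- which(pending)
    dead <- st$death[ids] <= st$next_time[ids]
    st$next_kind[ids[dead]] <- 0L    # death silently cancels pending events
    ids <- ids[!dead]
    if (!length(ids)) next
    inv <- ids[st$next_kind[ids] == 1L]
    srv <- ids[st$next_kind[ids] == 2L]
    if (length(inv)) .step_invitations(st, inv, params)
    if (length(srv)) .step_surveillance(st, srv, params)
  }

  yearly <- data.frame(year = demo$start_year + seq_len(horizon) - 1L,
                       st$tally)
  tot <- colSums(st$tally)
  structure(list(
    yearly = yearly,
    mean_participation = unname(tot["participants"] / tot["invited"]),
    mean_positivity = unname(tot["fit_positives"] / tot["participants"]),
    adherence = params$adherence,
    seed = seed,
    params = params,
    trace = if (isTRUE(trace)) {
      tr <- do.call(rbind, st$trace_rows)
      tr <- tr[order(tr$time, tr$person), ]
      tr$death <- st$death[tr$person]
      rownames(tr) <- NULL
      tr
    },
    n_persons = st$n
  ), class = "crc_run")
}

#' @export
print.crc_run <- function(x, ...) {
  yr <- x$yearly
  cat(sprintf("Screening-program run, %d-%d\n", min(yr$year), max(yr$year)))
  cat(sprintf("  20-year mean participation %.1f%%, positivity %.2f%%, adherence %.1f%%\n",
              100 * x$mean_participation, 100 * x$mean_positivity,
              100 * x$adherence))
  cat(sprintf("  colonoscopies after positive FIT: %d (first year) -> %d (last year)\n",
              yr$index_total[1], yr$index_total[nrow(yr)]))
  cat(sprintf("  surveillance colonoscopies:       %d (first year) -> %d (last year)\n",
              yr$surveillance[1], yr$surveillance[nrow(yr)]))
  invisible(x)
}

## Seeding ---------------------------------------------------------------

# Independent reproducible streams: run (or ensemble member) i uses the
# L'Ecuyer-CMRG stream obtained by seeding with the base seed and advancing
# i-1 times with parallel::nextRNGStream. State is restored afterwards.
.set_rng_stream <- function(seed, index = 1L) {
  old <- list(kind = RNGkind(),
              state = if (exists(".Random.seed", globalenv()))
                get(".Random.seed", globalenv()) else NULL)
  suppressWarnings(RNGkind("L'Ecuyer-CMRG"))
  set.seed(as.integer(seed))
  s <- get(".Random.seed", globalenv())
  if (index > 1L) {
    for (i in seq_len(index - 1L)) s <- parallel::nextRNGStream(s)
  }
  assign(".Random.seed", s, globalenv())
  old
}

.restore_rng <- function(old) {
  suppressWarnings(RNGkind(old$kind[1L]))
  if (!is.null(old$state)) {
    assign(".Random.seed", old$state, globalenv())
  }
  invisible()
}
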