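## Cohort: population creation, ageing and time-to-death -----------------

.build_demography <- function(d) {
  start_year <- as.integer(d$start_year)
  horizon <- as.integer(d$horizon_years)
  years <- seq(start_year + 1L, start_year + horizon - 1L)
  entrants <- round(seq(as.numeric(d$entrants_start),
                        as.numeric(d$entrants_end), length.out = length(years)))
  names(entrants) <- years
  ages <- 50:109
  gz <- function(p) as.numeric(p$a) * exp(as.numeric(p$b) * ages)
  mortality <- data.frame(age = ages,
                          male = gz(d$gompertz$male),
                          female = gz(d$gompertz$female))
  demography(initial_size = as.integer(d$initial_size),
             age_range = c(as.numeric(d$age_min), as.numeric(d$age_max)),
             male_share = as.numeric(d$male_share),
             start_year = start_year, horizon = horizon,
             entrants = entrants, mortality = mortality)
}

#' Construct a demography object
#'
#' Describes the dynamic target population: its initial size and age range,
#' gender split, the number of 50-year-olds entering each calendar year, and
#' the mortality hazard table used to assign time to death.
#'
#' @param initial_size Number of persons aged 50-69 at simulation start.
#' @param age_range Initial ages are uniform on `[age_range[1], age_range[2])`.
#' @param male_share Probability that a person is male.
#' @param start_year First simulated calendar year.
#' @param horizon Number of simulated years.
#' @param entrants Named integer vector of yearly 50-year-old entrant counts;
#'   names are calendar years `start_year + 1` onwards.
#' @param mortality Data frame with columns `age`, `male`, `female` giving the
#'   piecewise-constant yearly mortality hazard from each integer age. All
#'   hazards must be non-negative; a gender column that is zero everywhere
#'   yields immortal persons (infinite time to death).
#' @return An object of class `crc_demography`.
#' @export
demography <- function(initial_size = 100000L, age_range = c(50, 70),
                       male_share = 0.5, start_year = 2015L, horizon = 20L,
                       entrants = integer(), mortality) {
  stopifnot(initial_size >= 0, length(age_range) == 2L,
            age_range[1] < age_range[2],
            male_share >= 0, male_share <= 1, horizon >= 1)
  stopifnot(all(entrants >= 0))
  stopifnot(is.data.frame(mortality),
            all(c("age", "male", "female") %in% names(mortality)))
  if (any(mortality$male < 0) || any(mortality$female < 0)) {
    stop("mortality hazards must be non-negative")
  }
  structure(list(initial_size = as.integer(initial_size),
                 age_range = age_range, male_share = male_share,
                 start_year = as.integer(start_year),
                 horizon = as.integer(horizon),
                 entrants = entrants, mortality = mortality),
            class = "crc_demography")
}

#' @export
print.crc_demography <- function(x, ...) {
  cat(sprintf(
    "Demography: %d initial persons aged [%g, %g), %d-%d, ~%s entrants/year\n",
    x$initial_size, x$age_range[1], x$age_range[2], x$start_year,
    x$start_year + x$horizon - 1L,
    if (length(x$entrants)) format(round(mean(x$entrants))) else "0"))
  invisible(x)
}

# Piecewise-constant hazard machinery: cumulative hazard is piecewise linear
# on the age grid, extended beyond the last tabulated age at the final rate.
.cum_hazard <- function(mortality, gender_col) {
  ages <- mortality$age
  h <- mortality[[gender_col]]
  breaks <- c(ages, ages[length(ages)] + 1)
  H <- c(0, cumsum(h))
  list(breaks = breaks, H = H, tail_rate = h[length(h)])
}

.eval_cum_hazard <- function(ch, age) {
  n <- length(ch$breaks)
  out <- numeric(length(age))
  inside <- age <= ch$breaks[n]
  out[inside] <- stats::approx(ch$breaks, ch$H, xout = age[inside],
                               rule = 2)$y
  out[!inside] <- ch$H[n] + (age[!inside] - ch$breaks[n]) * ch$tail_rate
  out[age < ch$breaks[1]] <- 0
  out
}

# Invert H(x) = target for piecewise-linear H; target beyond the table uses
# the constant tail rate (or +Inf when the tail rate is zero).
.invert_cum_hazard <- function(ch, target) {
  n <- length(ch$breaks)
  out <- numeric(length(target))
  inside <- target <= ch$H[n]
  if (any(inside)) {
    # approx() needs strictly increasing H where we invert; flat spans
    # (zero hazard) are handled by taking the left-most age via ties = min
    out[inside] <- stats::approx(ch$H, ch$breaks, xout = target[inside],
                                 ties = min, rule = 2)$y
  }
  if (any(!inside)) {
    out[!inside] <- if (ch$tail_rate > 0) {
      ch$breaks[n] + (target[!inside] - ch$H[n]) / ch$tail_rate
    } else Inf
  }
  out
}

#' Draw time to death from the mortality table
#'
#' Samples survival times by inverse transform of the piecewise-constant
#' hazard: draw `E ~ Exp(1)` and solve `H(age + t) - H(age) = E`, where `H` is
#' the cumulative hazard from the demography's mortality table for the
#' person's gender. A table of all-zero hazards yields `Inf` (no deaths
#' within any horizon).
#'
#' @param age Numeric vector of current ages (years), all `>= 50`.
#' @param gender Integer vector (1 = male, 2 = female), recycled against
#'   `age`.
#' @param demography A [demography()] object.
#' @return Numeric vector of strictly positive times to death, in years.
#' @export
draw_time_to_death <- function(age, gender, demography) {
  stopifnot(inherits(demography, "crc_demography"))
  if (any(age < 50)) stop("draw_time_to_death: ages must be >= 50")
  n <- length(age)
  gender <- rep_len(as.integer(gender), n)
  e <- stats::rexp(n)
  out <- numeric(n)
  for (g in 1:2) {
    idx <- which(gender == g)
    if (!length(idx)) next
    ch <- .cum_hazard(demography$mortality, c("male", "female")[g])
    if (all(demography$mortality[[c("male", "female")[g]]] == 0)) {
      out[idx] <- Inf
      next
    }
    H0 <- .eval_cum_hazard(ch, age[idx])
    death_age <- .invert_cum_hazard(ch, H0 + e[idx])
    out[idx] <- pmax(death_age - age[idx], .Machine$double.eps)
  }
  out
}

# Internal: allocate the state arrays for a batch of persons.
.new_persons <- function(age0, gender, death, inv_time) {
  n <- length(age0)
  list(n = n, age0 = age0, gender = as.integer(gender), death = death,
       next_time = inv_time,
       next_kind = rep(1L, n),       # 1 = routine invitation, 2 = surveillance
       prev_part = rep(FALSE, n),    # participated in the previous round?
       part_stage = rep(FALSE, n),   # ever reached a participation decision?
       invited_ever = rep(FALSE, n), # ever went through the invitation process?
       has_screened = rep(FALSE, n), # ever returned a FIT kit?
       surv_first = rep(FALSE, n),   # next surveillance exam is the first one?
       surv_intv = rep(NA_real_, n), # current surveillance recall interval
       consec_neg = rep(0L, n))      # consecutive negative surveillance exams
}

#' Create the initial target population
#'
#' Builds `initial_size` persons with ages uniform over the configured range,
#' genders by the configured split, a sampled time to death, and alternating
#' assignment to the two biennial invitation waves (wave 0 is invited during
#' the first simulated year, wave 1 during the second), with invitation dates
#' staggered uniformly within the wave year.
#'
#' @param demography A [demography()] object.
#' @return A person-state list (fields `age0`, `gender`, `death`, `next_time`,
#'   ... ) used by [run_simulation()]; `age0` is the age at simulation start,
#'   so age at time `t` is `age0 + t`. Times are simulation years from 0.
#' @export
init_population <- function(demography) {
  stopifnot(inherits(demography, "crc_demography"))
  n <- demography$initial_size
  if (n == 0L) return(.new_persons(numeric(0), integer(0), numeric(0),
                                   numeric(0)))
  age0 <- stats::runif(n, demography$age_range[1], demography$age_range[2])
  gender <- ifelse(stats::runif(n) < demography$male_share, 1L, 2L)
  death <- draw_time_to_death(age0, gender, demography)
  wave <- rep_len(c(0L, 1L), n)
  inv_time <- wave + stats::runif(n)
  .new_persons(age0, gender, death, inv_time)
}

#' Create one year's 50-year-old entrants
#'
#' From the second simulated year on, new 50-year-olds join the target
#' population. Each entrant is aged exactly 50 at an entry time uniform
#' within the calendar year and receives their first invitation at entry.
#'
#' @param demography A [demography()] object.
#' @param year Calendar year; must lie within the entrant series (the second
#'   simulated year through the end of the horizon).
#' @return A person-state list (possibly empty).
#' @export
annual_entrants <- function(demography, year) {
  stopifnot(inherits(demography, "crc_demography"))
  yrs <- as.integer(names(demography$entrants))
  if (!length(yrs) || year < min(yrs) || year > max(yrs)) {
    stop(sprintf("annual_entrants: year %d outside the entrant series [%d, %d]",
                 year, min(yrs), max(yrs)))
  }
  n <- demography$entrants[[as.character(year)]]
  if (n == 0L) return(.new_persons(numeric(0), integer(0), numeric(0),
                                   numeric(0)))
  t_entry <- (year - demography$start_year) + stats::runif(n)
  age0 <- 50 - t_entry
  gender <- ifelse(stats::runif(n) < demography$male_share, 1L, 2L)
  # age at entry is exactly 50
  death <- t_entry + draw_time_to_death(rep(50, n), gender, demography)
  .new_persons(age0, gender, death, t_entry)
}

# Concatenate person-state lists.
.bind_persons <- function(a, b) {
  if (b$n == 0L) return(a)
  if (a$n == 0L) return(b)
  out <- mapply(function(x, y) c(x, y), a[-1L], b[-1L], SIMPLIFY = FALSE)
  c(list(n = a$n + b$n), out)
}
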