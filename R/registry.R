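## Synthetic screening registry and parameter estimation ------------------
##
## Emulates two rounds of person-level records from a stratified screening
## program (invitation -> exclusion -> opportunistic -> participation -> FIT
## result -> colonoscopy -> result category), so the stratified estimator can
## be validated against known parameters without any real registry.

#' Generate a synthetic two-round screening registry
#'
#' Draws person-level records through the screening Bernoulli chain with the
#' supplied true parameters: round 1 uses initial-screening parameters;
#' round 2 applies medical-only exclusion, conditions participation on
#' round-1 behaviour, and uses successive-screening positivity and result
#' distributions for persons who already screened in round 1. Round-1
#' opportunistic screeners with a recent (<= 3 years) colonoscopy are
#' deferred past round 2 and appear there as not invited.
#'
#' @param params A `crc_parameters` set (e.g. from [sample_parameters()] or
#'   [fix_parameters()]).
#' @param n_per_stratum Persons per gender/age stratum (>= 1).
#' @return Data frame of class `crc_registry`, one row per person-round:
#'   `person`, `round`, `gender`, `age_group`, `excluded`, `opportunistic`,
#'   `invited`, `participated`, `fit_positive`, `colonoscopy_done`,
#'   `outcome`. Flags are logically nested; stages never reached are `NA`.
#' @export
generate_registry <- function(params, n_per_stratum) {
  stopifnot(inherits(params, "crc_parameters"), n_per_stratum >= 1)
  strata <- strata_table()
  n <- 8L * n_per_stratum
  s <- rep(1:8, each = n_per_stratum)
  ru <- function() stats::runif(n)

  draw_round <- function(excluded_prev, opp_deferred, participated_prev,
                         screened_prev, first) {
    excluded <- if (first) ru() < params$exclusion_initial[s] else
      excluded_prev | ru() < params$exclusion_successive
    opportunistic <- ifelse(excluded, NA, if (first)
      ru() < params$opportunistic[s] else
      !opp_deferred & ru() < params$opportunistic[s])
    invited <- !excluded & !is.na(opportunistic) & !opportunistic &
      !(if (first) rep(FALSE, n) else opp_deferred)
    p_part <- if (first) params$participation_initial[s] else
      ifelse(participated_prev, params$participation_prev_participant,
             params$participation_prev_nonparticipant)
    participated <- ifelse(invited, ru() < p_part, NA)
    initial_screen <- if (first) rep(TRUE, n) else !screened_prev
    p_pos <- ifelse(initial_screen, params$positivity_initial[s],
                    params$positivity_successive)
    fit_positive <- ifelse(!is.na(participated) & participated,
                           ru() < p_pos, NA)
    pos <- !is.na(fit_positive) & fit_positive
    colonoscopy_done <- ifelse(pos, ru() >= params$refusal[s], NA)
    done <- !is.na(colonoscopy_done) & colonoscopy_done
    outcome <- rep(NA_character_, n)
    if (any(done)) {
      idx <- which(done)
      cum <- matrix(rep(cumsum(params$result_successive), each = length(idx)),
                    nrow = length(idx))
      ini <- initial_screen[idx]
      if (any(ini)) {
        cum[ini, ] <- matrix(rep(cumsum(params$result_initial),
                                 each = sum(ini)), nrow = sum(ini))
      }
      outcome[idx] <- .result_categories[
        .draw_category(stats::runif(length(idx)), cum)]
    }
    list(excluded = excluded, opportunistic = opportunistic,
         invited = invited, participated = participated,
         fit_positive = fit_positive, colonoscopy_done = colonoscopy_done,
         outcome = outcome, initial_screen = initial_screen)
  }

  r1 <- draw_round(first = TRUE)
  opp1 <- !is.na(r1$opportunistic) & r1$opportunistic
  # recent outside colonoscopy (<= 3 y) defers past the next round
  deferred <- opp1 & stats::runif(n) < params$opportunistic_recent_share
  part1 <- !is.na(r1$participated) & r1$participated
  r2 <- draw_round(excluded_prev = r1$excluded, opp_deferred = deferred,
                   participated_prev = part1, screened_prev = part1,
                   first = FALSE)

  mk <- function(r, round) {
    data.frame(person = seq_len(n), round = round,
               gender = strata$gender[s], age_group = strata$age_group[s],
               excluded = r$excluded, opportunistic = r$opportunistic,
               invited = r$invited, participated = r$participated,
               fit_positive = r$fit_positive,
               colonoscopy_done = r$colonoscopy_done,
               outcome = r$outcome, initial_screen = r$initial_screen,
               stringsAsFactors = FALSE)
  }
  out <- rbind(mk(r1, 1L), mk(r2, 2L))
  class(out) <- c("crc_registry", "data.frame")
  out
}

# Clopper-Pearson exact binomial interval.
.clopper_pearson <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lo <- ifelse(x == 0, 0, stats::qbeta(a, x, n - x + 1))
  hi <- ifelse(x == n, 1, stats::qbeta(1 - a, x + 1, n - x))
  cbind(lo = lo, hi = hi)
}

#' Estimate screening parameters from a registry
#'
#' Computes the stratified conditional proportions down the screening chain
#' (the natural estimator for a sequential Bernoulli process), with exact
#' Clopper-Pearson 95% intervals; colonoscopy result categories get
#' per-category exact intervals on their multinomial shares. Cells with no
#' denominator are reported as `NA`.
#'
#' @param records A `crc_registry` data frame.
#' @return Data frame of class `crc_estimates`: `field`, `stratum` (`"all"`
#'   for pooled fields), `estimate`, `lo`, `hi`, `successes`, `trials`.
#' @export
estimate_parameters <- function(records) {
  if (!nrow(records)) stop("estimate_parameters: empty registry")
  strata <- strata_table()
  s_of <- function(d) match(paste(d$gender, d$age_group),
                            paste(strata$gender, strata$age_group))
  r1 <- records[records$round == 1L, ]
  r2 <- records[records$round == 2L, ]

  rows <- list()
  add <- function(field, stratum, x, n) {
    ci <- .clopper_pearson(x, n)
    rows[[length(rows) + 1L]] <<- data.frame(
      field = field, stratum = stratum,
      estimate = ifelse(n > 0, x / n, NA_real_),
      lo = ifelse(n > 0, ci[, "lo"], NA_real_),
      hi = ifelse(n > 0, ci[, "hi"], NA_real_),
      successes = x, trials = n, stringsAsFactors = FALSE)
  }
  by_stratum <- function(d, num, den) {
    si <- s_of(d)
    n <- vapply(1:8, function(k) sum(den & si == k, na.rm = TRUE), 0)
    x <- vapply(1:8, function(k) sum(num & den & si == k, na.rm = TRUE), 0)
    list(x = x, n = n)
  }

  # round 1: initial screening, stratified
  b <- by_stratum(r1, r1$excluded, rep(TRUE, nrow(r1)))
  add("exclusion_initial", 1:8, b$x, b$n)
  b <- by_stratum(r1, r1$opportunistic, !r1$excluded)
  add("opportunistic", 1:8, b$x, b$n)
  b <- by_stratum(r1, r1$participated, r1$invited)
  add("participation_initial", 1:8, b$x, b$n)

  # initial-screen positivity: first-ever kits, both rounds
  ini <- records[!is.na(records$participated) & records$participated &
                   records$initial_screen, ]
  b <- by_stratum(ini, ini$fit_positive, rep(TRUE, nrow(ini)))
  add("positivity_initial", 1:8, b$x, b$n)

  # refusal: stratified, both rounds
  pos <- records[!is.na(records$fit_positive) & records$fit_positive, ]
  b <- by_stratum(pos, !pos$colonoscopy_done, rep(TRUE, nrow(pos)))
  add("refusal", 1:8, b$x, b$n)

  # pooled successive-screening parameters
  was_in_r1 <- !r1$excluded
  add("exclusion_successive", "all",
      sum(r2$excluded & was_in_r1 & !r1$excluded),
      sum(was_in_r1))
  prev_part <- !is.na(r1$participated) & r1$participated
  prev_non <- r1$invited & !prev_part
  add("participation_prev_participant", "all",
      sum(r2$participated & prev_part[r2$person], na.rm = TRUE),
      sum(r2$invited & prev_part[r2$person]))
  add("participation_prev_nonparticipant", "all",
      sum(r2$participated & prev_non[r2$person], na.rm = TRUE),
      sum(r2$invited & prev_non[r2$person]))
  succ <- records[!is.na(records$participated) & records$participated &
                    !records$initial_screen, ]
  add("positivity_successive", "all",
      sum(succ$fit_positive, na.rm = TRUE), nrow(succ))

  # colonoscopy result shares by screen type
  for (type in c("initial", "successive")) {
    done <- records[!is.na(records$colonoscopy_done) &
                      records$colonoscopy_done &
                      (records$initial_screen == (type == "initial")), ]
    for (k in .result_categories) {
      add(paste0("result_", type, ".", k), "all",
          sum(done$outcome == k), nrow(done))
    }
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("crc_estimates", "data.frame")
  out
}

#' @export
print.crc_estimates <- function(x, ...) {
  cat(sprintf("Estimated screening parameters (%d cells)\n", nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 12))
  if (nrow(x) > 12) cat("...\n")
  invisible(x)
}

#' Turn registry estimates into point-mass simulation parameters
#'
#' Collapses a `crc_estimates` table into the named-list shape used by
#' [fix_parameters()], so a simulation can be run at the estimated values.
#'
#' @param estimates A `crc_estimates` data frame.
#' @return Named list of point estimates (stratified fields as length-8
#'   vectors, result distributions renormalised to sum to 1).
#' @export
estimates_as_parameters <- function(estimates) {
  stopifnot(inherits(estimates, "crc_estimates"))
  get1 <- function(field) {
    e <- estimates[estimates$field == field, ]
    stats::setNames(e$estimate, e$stratum)
  }
  dist <- function(prefix) {
    v <- vapply(.result_categories, function(k)
      unname(get1(paste0(prefix, ".", k))), 0)
    v / sum(v)
  }
  list(exclusion_initial = unname(get1("exclusion_initial")),
       exclusion_successive = unname(get1("exclusion_successive")),
       opportunistic = unname(get1("opportunistic")),
       participation_initial = unname(get1("participation_initial")),
       participation_prev_participant =
         unname(get1("participation_prev_participant")),
       participation_prev_nonparticipant =
         unname(get1("participation_prev_nonparticipant")),
       positivity_initial = unname(get1("positivity_initial")),
       positivity_successive = unname(get1("positivity_successive")),
       refusal = unname(get1("refusal")),
       result_initial = dist("result_initial"),
       result_successive = dist("result_successive"))
}
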