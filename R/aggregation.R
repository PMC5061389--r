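## Ensemble, scenario filter and across-run aggregation -------------------

#' Run a replication ensemble
#'
#' Runs `n_runs` independent replications of the microsimulation, each with
#' its own L'Ecuyer-CMRG random stream spawned from `seed`. Results are keyed
#' by run index, so the ensemble content is independent of execution order
#' and fully reproducible from `(seed, n_runs)`.
#'
#' @param config A `crc_config`.
#' @param n_runs Number of replications (>= 1).
#' @param seed Integer base seed.
#' @param progress Print a line every `progress` runs (0 = silent).
#' @return An object of class `crc_ensemble`: list with `runs` (list of
#'   `crc_run`), `seed`, and `filtered` (logical flag used by
#'   [filter_scenario()]).
#' @export
run_ensemble <- function(config, n_runs, seed = 1L, progress = 0L) {
  stopifnot(inherits(config, "crc_config"), n_runs >= 1)
  old <- .set_rng_stream(seed)
  on.exit(.restore_rng(old), add = TRUE)
  runs <- vector("list", n_runs)
  s <- get(".Random.seed", globalenv())
  for (i in seq_len(n_runs)) {
    assign(".Random.seed", s, globalenv())
    runs[[i]] <- run_simulation(config)
    runs[[i]]$seed <- c(base = seed, stream = i)
    s <- parallel::nextRNGStream(s)
    if (progress > 0 && i %% progress == 0) {
      message(sprintf("run %d/%d", i, n_runs))
    }
  }
  structure(list(runs = runs, seed = seed, n_runs = n_runs, filtered = FALSE),
            class = "crc_ensemble")
}

#' @export
print.crc_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d microsimulation run%s%s\n", length(x$runs),
              if (length(x$runs) == 1L) "" else "s",
              if (x$filtered) " (scenario-filtered)" else ""))
  s <- runs_summary(x)
  cat(sprintf("  20-year mean participation %.1f%% | positivity %.2f%% | adherence %.1f%%\n",
              100 * mean(s$mean_participation), 100 * mean(s$mean_positivity),
              100 * mean(s$adherence)))
  invisible(x)
}

#' Per-run summary table
#'
#' @param ensemble A `crc_ensemble`.
#' @return Data frame with one row per run: stream index, 20-year mean
#'   participation and positivity (ratios of sums), run-constant adherence,
#'   and 20-year totals of the three colonoscopy counts.
#' @export
runs_summary <- function(ensemble) {
  stopifnot(inherits(ensemble, "crc_ensemble"))
  do.call(rbind, lapply(seq_along(ensemble$runs), function(i) {
    r <- ensemble$runs[[i]]
    data.frame(run = i,
               mean_participation = r$mean_participation,
               mean_positivity = r$mean_positivity,
               adherence = r$adherence,
               index_total_20y = sum(r$yearly$index_total),
               surveillance_20y = sum(r$yearly$surveillance),
               overall_20y = sum(r$yearly$index_total) +
                 sum(r$yearly$surveillance))
  }))
}

#' Construct a current-scenario run filter
#'
#' The current-scenario subgroup keeps runs whose 20-year mean participation,
#' 20-year mean positivity and surveillance adherence fall inside closed
#' bounds (defaults: participation 40-60%, positivity 4.7-6.8%, adherence
#' 35-70%).
#'
#' @param participation,positivity,adherence Length-2 numeric bounds
#'   (fractions).
#' @return An object of class `crc_filter`.
#' @export
scenario_filter <- function(participation = c(0.40, 0.60),
                            positivity = c(0.047, 0.068),
                            adherence = c(0.35, 0.70)) {
  chk <- function(b, nm) {
    if (length(b) != 2L || b[1] >= b[2]) {
      stop("filter bounds for ", nm, " must be (lower, upper) with lower < upper")
    }
    b
  }
  structure(list(participation = chk(participation, "participation"),
                 positivity = chk(positivity, "positivity"),
                 adherence = chk(adherence, "adherence")),
            class = "crc_filter")
}

#' Filter an ensemble to the current scenario
#'
#' Keeps runs whose three run-level summaries fall inside the closed filter
#' bounds. Idempotent: filtering a filtered ensemble with the same bounds
#' changes nothing.
#'
#' @param ensemble A `crc_ensemble`.
#' @param filter A [scenario_filter()].
#' @return The filtered `crc_ensemble`.
#' @export
filter_scenario <- function(ensemble, filter = scenario_filter()) {
  stopifnot(inherits(ensemble, "crc_ensemble"), inherits(filter, "crc_filter"))
  s <- runs_summary(ensemble)
  keep <- s$mean_participation >= filter$participation[1] &
    s$mean_participation <= filter$participation[2] &
    s$mean_positivity >= filter$positivity[1] &
    s$mean_positivity <= filter$positivity[2] &
    s$adherence >= filter$adherence[1] &
    s$adherence <= filter$adherence[2]
  ensemble$runs <- ensemble$runs[keep]
  ensemble$filtered <- TRUE
  ensemble
}

# Fields whose Table-style percentage has a defined denominator, expressed as
# (numerator field -> denominator field); index outcome percentages attach to
# first colonoscopies, surveillance outcomes to attended surveillance exams.
.pct_denominator <- c(
  participants = "invited", successive_participants = "participants",
  fit_positives = "participants", index_first = "fit_positives",
  index_negative = "index_first", index_low_risk = "index_first",
  index_intermediate_risk = "index_first", index_high_risk = "index_first",
  index_cancer = "index_first",
  surv_negative = "surveillance", surv_low_risk = "surveillance",
  surv_intermediate_high = "surveillance", surv_cancer = "surveillance")

#' Aggregate yearly tallies across runs
#'
#' For every tally field and calendar year, computes the across-run mean and
#' an empirical 95% interval (2.5th to 97.5th percentile, linear
#' interpolation), plus the derived percentage where one is defined (e.g.
#' participants as a share of invited, result categories as a share of first
#' colonoscopies). Percentages are ratios of across-run mean numerators and
#' denominators. The derived field `overall` is the sum of colonoscopies
#' after a positive FIT and surveillance colonoscopies.
#'
#' @param ensemble A `crc_ensemble` with at least 2 runs.
#' @return Data frame with columns `year`, `field`, `mean`, `lo95`, `hi95`,
#'   `pct` (NA where no percentage is defined).
#' @export
aggregate_runs <- function(ensemble) {
  stopifnot(inherits(ensemble, "crc_ensemble"))
  if (length(ensemble$runs) < 2L) {
    stop("aggregate_runs: at least 2 runs are required for intervals")
  }
  years <- ensemble$runs[[1]]$yearly$year
  fields <- c(.tally_fields, "overall")
  arr <- vapply(ensemble$runs, function(r) {
    m <- as.matrix(r$yearly[, .tally_fields])
    cbind(m, overall = m[, "index_total"] + m[, "surveillance"])
  }, matrix(0, length(years), length(fields)))
  mean_mat <- apply(arr, c(1, 2), mean)
  lo <- apply(arr, c(1, 2), stats::quantile, probs = 0.025, names = FALSE)
  hi <- apply(arr, c(1, 2), stats::quantile, probs = 0.975, names = FALSE)
  out <- do.call(rbind, lapply(seq_along(fields), function(j) {
    f <- fields[j]
    den <- .pct_denominator[f]
    pct <- if (!is.na(den)) {
      100 * mean_mat[, j] / mean_mat[, den]
    } else if (f == "index_total") {
      # share of FIT-positives receiving a colonoscopy: first exams only
      100 * mean_mat[, "index_first"] / mean_mat[, "fit_positives"]
    } else NA_real_
    data.frame(year = years, field = f, mean = mean_mat[, j],
               lo95 = lo[, j], hi95 = hi[, j], pct = pct)
  }))
  rownames(out) <- NULL
  out
}
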