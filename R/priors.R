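#' @keywords internal
"_PACKAGE"

## Stratum bookkeeping -------------------------------------------------------

#' Gender by age-group strata
#'
#' Screening parameters are stratified by gender crossed with the age groups
#' 50-54, 55-59, 60-64 and 65-69 years: eight strata in all. Strata are indexed
#' 1..8 in the order male 50-54, ..., male 65-69, female 50-54, ..., female
#' 65-69.
#'
#' @return A data frame with columns `stratum`, `gender` and `age_group`.
#' @export
#' @examples
#' strata_table()
strata_table <- function() {
  data.frame(
    stratum   = 1:8,
    gender    = rep(c("male", "female"), each = 4L),
    age_group = rep(c("50-54", "55-59", "60-64", "65-69"), 2L),
    stringsAsFactors = FALSE
  )
}

#' Map gender and age to a stratum index
#'
#' @param gender Integer vector, 1 = male, 2 = female.
#' @param age Numeric vector of ages in years; must lie in [50, 70).
#' @return Integer stratum indices in 1..8 (see [strata_table()]).
#' @export
stratum_index <- function(gender, age) {
  if (any(age < 50 | age >= 70)) {
    stop("stratum_index: ages must lie in [50, 70)")
  }
  (as.integer(gender) - 1L) * 4L + pmin(as.integer((age - 50) %/% 5), 3L) + 1L
}

## Probability priors --------------------------------------------------------

#' Construct a probability prior
#'
#' Priors describe the run-level uncertainty of each model probability for the
#' probabilistic sensitivity analysis. Three families are supported, all with
#' support inside [0, 1]:
#'
#' * `"beta"`: Beta distribution parameterised by `mean` and an effective
#'   sample size `ess` (`shape1 = mean * ess`, `shape2 = (1 - mean) * ess`).
#'   `mean` may be a vector (one entry per stratum), in which case one
#'   independent draw is taken per stratum.
#' * `"uniform"`: Uniform on `[min, max]` (used for surveillance adherence).
#' * `"fixed"`: a point mass at `value` (scalar or vector); used for
#'   quantities the analysis treats as known, e.g. the second-look rate and
#'   the colonoscopy result distributions.
#'
#' @param dist One of `"beta"`, `"uniform"`, `"fixed"`.
#' @param mean,ess Beta mean(s) and effective sample size.
#' @param min,max Uniform bounds.
#' @param value Point mass value(s).
#' @return An object of class `crc_prior`.
#' @export
probability_prior <- function(dist = c("beta", "uniform", "fixed"),
                              mean = NULL, ess = NULL,
                              min = NULL, max = NULL, value = NULL) {
  dist <- match.arg(dist)
  p <- switch(dist,
    beta = {
      stopifnot(is.numeric(mean), length(mean) >= 1L, is.numeric(ess), ess > 0)
      if (any(mean < 0 | mean > 1)) stop("beta prior mean outside [0, 1]")
      list(dist = "beta", mean = mean, ess = ess)
    },
    uniform = {
      stopifnot(is.numeric(min), is.numeric(max), min <= max)
      if (min < 0 || max > 1) stop("uniform prior support outside [0, 1]")
      list(dist = "uniform", min = min, max = max)
    },
    fixed = {
      stopifnot(is.numeric(value))
      if (any(value < 0 | value > 1)) stop("fixed prior value outside [0, 1]")
      list(dist = "fixed", value = value)
    }
  )
  structure(p, class = "crc_prior")
}

#' Draw from a probability prior
#'
#' Draws use the current R random stream. Beta priors with vector means return
#' one independent draw per element; degenerate (fixed) priors return their
#' constant.
#'
#' @param prior A [probability_prior()].
#' @return Numeric vector of draws in the prior's support.
#' @export
sample_prior <- function(prior) {
  stopifnot(inherits(prior, "crc_prior"))
  switch(prior$dist,
    beta = {
      m <- prior$mean
      x <- stats::rbeta(length(m), m * prior$ess, (1 - m) * prior$ess)
      # rbeta returns NaN for degenerate shapes (mean 0 or 1)
      x[m == 0] <- 0
      x[m == 1] <- 1
      x
    },
    uniform = stats::runif(1L, prior$min, prior$max),
    fixed = prior$value
  )
}

#' @export
print.crc_prior <- function(x, ...) {
  cat(switch(x$dist,
    beta = sprintf("Beta prior: mean %s, ess %g",
                   paste(signif(x$mean, 4), collapse = "/"), x$ess),
    uniform = sprintf("Uniform prior on [%g, %g]", x$min, x$max),
    fixed = sprintf("Point mass at %s", paste(signif(x$value, 4), collapse = "/"))
  ), "\n")
  invisible(x)
}

## Configuration -------------------------------------------------------------

# Fields of the screening section, with their stratification and whether they
# are probabilistic (Beta) or fixed. Result distributions are always fixed:
# test results come from empirical distributions, not from run-level priors.
.screening_fields <- function() {
  list(
    exclusion_initial             = list(strat = TRUE,  psa = TRUE),
    exclusion_successive          = list(strat = FALSE, psa = TRUE),
    opportunistic                 = list(strat = TRUE,  psa = TRUE),
    opportunistic_recent_share    = list(strat = FALSE, psa = FALSE),
    participation_initial         = list(strat = TRUE,  psa = TRUE),
    participation_prev_participant    = list(strat = FALSE, psa = TRUE),
    participation_prev_nonparticipant = list(strat = FALSE, psa = TRUE),
    positivity_initial            = list(strat = TRUE,  psa = TRUE),
    positivity_successive         = list(strat = FALSE, psa = TRUE),
    refusal                       = list(strat = TRUE,  psa = TRUE),
    second_look                   = list(strat = FALSE, psa = FALSE)
  )
}

.result_categories <- c("negative", "low_risk", "intermediate_risk",
                        "high_risk", "cancer")
.surv_categories <- c("negative", "low_risk", "intermediate_high", "cancer")

.default_config_path <- function() {
  system.file("extdata", "default_config.yaml", package = "crcdemand",
              mustWork = TRUE)
}

.check_prob <- function(x, field) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0 | x > 1)) {
    stop(sprintf("config field '%s' must be a probability in [0, 1]", field),
         call. = FALSE)
  }
  x
}

.check_dist <- function(x, field, categories) {
  x <- unlist(x)[categories]
  if (any(is.na(x))) {
    stop(sprintf("config field '%s' must name categories %s", field,
                 paste(categories, collapse = ", ")), call. = FALSE)
  }
  .check_prob(x, field)
  if (abs(sum(x) - 1) > 1e-9) {
    stop(sprintf("config field '%s' must sum to 1 (got %.10f)", field, sum(x)),
         call. = FALSE)
  }
  x
}

# recursive right-biased merge of two config lists, recording fallbacks
.merge_config <- function(default, user, path = character()) {
  fallbacks <- character()
  out <- default
  for (nm in names(default)) {
    here <- c(path, nm)
    if (is.null(user[[nm]])) {
      fallbacks <- c(fallbacks, paste(here, collapse = "."))
    } else if (is.list(default[[nm]]) && is.list(user[[nm]])) {
      sub <- .merge_config(default[[nm]], user[[nm]], here)
      out[[nm]] <- sub$config
      fallbacks <- c(fallbacks, sub$fallbacks)
    } else {
      out[[nm]] <- user[[nm]]
    }
  }
  list(config = out, fallbacks = fallbacks)
}

#' Load a model configuration and build its prior library
#'
#' Reads a hierarchical key-value (YAML) configuration with sections
#' `demography`, `screening`, `surveillance`, `psa` and `run`, validates it,
#' and assembles the complete prior library used to sample per-run parameter
#' sets. Any field omitted from a user configuration falls back to the
#' packaged calibrated default, and the fallback is reported via `message()`.
#'
#' All probabilities are decimals in [0, 1]; intervals are in years. Screening
#' probabilities listed in the `psa` section are given Beta priors with the
#' configured effective sample size; the rest are point masses. Stratified
#' fields (exclusion at initial screening, opportunistic screening, initial
#' participation, initial positivity, colonoscopy refusal) accept either a
#' single value shared by all eight gender/age strata or a vector of eight.
#'
#' @param path Path to a YAML configuration file, or `NULL` for the packaged
#'   calibrated defaults.
#' @param quiet Suppress fallback messages.
#' @return An object of class `crc_config`: a list with elements `priors`
#'   (class `crc_prior_library`), `demography`, `surveillance`, `run` and
#'   `raw` (the merged configuration).
#' @export
#' @examples
#' cfg <- load_config()
#' cfg$priors$positivity_initial
load_config <- function(path = NULL, quiet = is.null(path)) {
  default <- yaml::read_yaml(.default_config_path())
  if (is.null(path)) {
    merged <- default
  } else {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    m <- .merge_config(default, user)
    merged <- m$config
    if (!quiet && length(m$fallbacks)) {
      message("config fields falling back to packaged defaults: ",
              paste(m$fallbacks, collapse = ", "))
    }
  }
  .build_config(merged)
}

.expand_stratified <- function(x, field) {
  x <- .check_prob(unlist(x), field)
  if (length(x) == 1L) x <- rep(x, 8L)
  if (length(x) != 8L) {
    stop(sprintf("config field '%s' must have length 1 or 8", field),
         call. = FALSE)
  }
  x
}

.build_config <- function(cf) {
  sc <- cf$screening
  ess <- sc$ess
  stopifnot(is.numeric(ess), ess > 0)
  psa_fields <- unlist(cf$psa$probabilistic)
  fields <- .screening_fields()
  unknown <- setdiff(psa_fields, names(fields))
  if (length(unknown)) {
    stop("psa section names unknown fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  priors <- list()
  for (nm in names(fields)) {
    info <- fields[[nm]]
    val <- sc[[nm]]
    if (is.null(val)) stop("config is missing screening field '", nm, "'",
                           call. = FALSE)
    val <- if (info$strat) .expand_stratified(val, nm) else
      .check_prob(unlist(val), nm)
    priors[[nm]] <- if (nm %in% psa_fields && info$psa) {
      probability_prior("beta", mean = val, ess = ess)
    } else {
      probability_prior("fixed", value = val)
    }
  }
  priors$result_initial <- probability_prior(
    "fixed", value = .check_dist(sc$result_initial, "result_initial",
                                 .result_categories))
  priors$result_successive <- probability_prior(
    "fixed", value = .check_dist(sc$result_successive, "result_successive",
                                 .result_categories))
  priors$surveillance_result <- probability_prior(
    "fixed", value = .check_dist(cf$surveillance$result, "surveillance_result",
                                 .surv_categories))
  adh <- cf$surveillance$adherence
  priors$adherence <- probability_prior("uniform", min = .check_prob(adh$min,
    "adherence.min"), max = .check_prob(adh$max, "adherence.max"))
  class(priors) <- "crc_prior_library"

  reinvite <- unlist(sc$reinvite)
  needed <- c("non_participation", "negative_fit", "refusal", "low_risk",
              "opportunistic_recent", "opportunistic_old",
              "negative_colonoscopy")
  if (any(is.na(reinvite[needed]))) {
    stop("screening.reinvite must define: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  trans <- cf$surveillance$transitions
  surv_table <- data.frame(
    outcome = .surv_categories,
    action = vapply(.surv_categories, function(k) trans[[k]]$action, ""),
    interval = vapply(.surv_categories, function(k)
      as.numeric(trans[[k]]$interval), 0),
    stringsAsFactors = FALSE
  )
  if (!all(surv_table$action %in% c("reschedule", "exit"))) {
    stop("surveillance transition actions must be 'reschedule' or 'exit'",
         call. = FALSE)
  }

  structure(list(
    priors = priors,
    demography = .build_demography(cf$demography),
    surveillance = list(
      table = surv_table,
      entry_interval = c(
        intermediate_risk = as.numeric(cf$surveillance$entry_interval$intermediate_risk),
        high_risk = as.numeric(cf$surveillance$entry_interval$high_risk)),
      age_cap = as.numeric(cf$surveillance$age_cap),
      on_miss = match.arg(cf$surveillance$on_miss, c("exit", "reschedule")),
      discharge_negatives = as.integer(cf$surveillance$discharge_negatives),
      discharge_interval = as.numeric(cf$surveillance$discharge_interval)
    ),
    reinvite = reinvite[needed],
    run = list(filter = scenario_filter(
      participation = as.numeric(unlist(cf$run$filter$participation)),
      positivity = as.numeric(unlist(cf$run$filter$positivity)),
      adherence = as.numeric(unlist(cf$run$filter$adherence)))),
    raw = cf
  ), class = "crc_config")
}

#' @export
print.crc_config <- function(x, ...) {
  cat("CRC screening microsimulation configuration\n")
  cat(sprintf("  population: %d persons aged [%g, %g), start year %d, %d-year horizon\n",
              x$demography$initial_size, x$demography$age_range[1],
              x$demography$age_range[2], x$demography$start_year,
              x$demography$horizon))
  cat(sprintf("  probabilistic fields: %s\n",
              paste(names(Filter(function(p) p$dist != "fixed", x$priors)),
                    collapse = ", ")))
  invisible(x)
}

#' Sample one run's parameter set from a prior library
#'
#' Takes one draw per field from the prior library using the current random
#' stream: stratified fields are drawn independently per stratum, successive
#' surveillance adherence is drawn once and held constant for the run, and
#' point-mass priors return their constants. Identical random streams yield
#' identical parameter sets.
#'
#' @param config A `crc_config` (or its `$priors` prior library together with
#'   `surveillance`/`reinvite` structure taken from the default config).
#' @return An object of class `crc_parameters`: a named list of realised
#'   probabilities, result distributions, re-invitation intervals and the
#'   surveillance transition table.
#' @export
#' @examples
#' cfg <- load_config()
#' set.seed(1)
#' p <- sample_parameters(cfg)
#' p$adherence
sample_parameters <- function(config) {
  stopifnot(inherits(config, "crc_config"))
  pr <- config$priors
  draws <- lapply(pr, sample_prior)
  names(draws$result_initial) <- .result_categories
  names(draws$result_successive) <- .result_categories
  names(draws$surveillance_result) <- .surv_categories
  ps <- c(draws, list(
    reinvite = config$reinvite,
    surv_table = config$surveillance$table,
    surv_entry = config$surveillance$entry_interval,
    surv_age_cap = config$surveillance$age_cap,
    surv_on_miss = config$surveillance$on_miss,
    surv_discharge_negatives = config$surveillance$discharge_negatives,
    surv_discharge_interval = config$surveillance$discharge_interval
  ))
  structure(ps, class = "crc_parameters")
}

#' @export
print.crc_parameters <- function(x, ...) {
  cat("Realised parameter set (one PSA draw)\n")
  cat(sprintf("  participation (initial, mean over strata): %.3f\n",
              mean(x$participation_initial)))
  cat(sprintf("  positivity (initial mean / successive): %.3f / %.3f\n",
              mean(x$positivity_initial), x$positivity_successive))
  cat(sprintf("  colonoscopy refusal (mean): %.3f; second look: %.3f\n",
              mean(x$refusal), x$second_look))
  cat(sprintf("  surveillance adherence (run-constant): %.3f\n", x$adherence))
  invisible(x)
}

#' Build a degenerate (point-mass) configuration from realised parameters
#'
#' Replaces every probabilistic prior by a point mass at the supplied values.
#' Used to re-run the simulator at known or estimated parameter values, e.g.
#' when feeding registry estimates back into the model.
#'
#' @param config A `crc_config` to use as the template.
#' @param params A named list of values to pin; fields not named keep their
#'   prior means (Beta) or constants.
#' @return A `crc_config` whose priors are all point masses.
#' @export
fix_parameters <- function(config, params = list()) {
  stopifnot(inherits(config, "crc_config"))
  pr <- config$priors
  for (nm in setdiff(names(pr), "adherence")) {
    width <- length(switch(pr[[nm]]$dist, beta = pr[[nm]]$mean,
                           fixed = pr[[nm]]$value, uniform = 1))
    val <- if (!is.null(params[[nm]])) params[[nm]] else
      switch(pr[[nm]]$dist, beta = pr[[nm]]$mean, fixed = pr[[nm]]$value,
             uniform = (pr[[nm]]$min + pr[[nm]]$max) / 2)
    if (length(val) == 1L && width > 1L) val <- rep(val, width)
    if (length(val) != width) {
      stop("fix_parameters: field '", nm, "' expects length 1 or ", width)
    }
    pr[[nm]] <- probability_prior("fixed", value = val)
  }
  adh <- if (!is.null(params$adherence)) params$adherence else
    (pr$adherence$min + pr$adherence$max) / 2
  pr$adherence <- probability_prior("fixed", value = adh)
  config$priors <- pr
  config
}
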