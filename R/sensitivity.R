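## Regression meta-model of demand drivers --------------------------------

#' Build the meta-regression design
#'
#' One row per run and simulated year: the year's realised participation
#' (participants / invited) and FIT positivity (positives / participants) in
#' percentage points, the run's surveillance adherence in percentage points,
#' the year index `t` (0 for the first simulated year), and the outcome
#' colonoscopy count. Years with an undefined predictor (zero invited or
#' zero participants) are dropped with a warning.
#'
#' @param ensemble A `crc_ensemble`.
#' @param outcome Which demand count to model: colonoscopies after a positive
#'   FIT (`"index"`), surveillance colonoscopies (`"surveillance"`), or their
#'   sum (`"overall"`).
#' @return Data frame with columns `run`, `t`, `participation`, `positivity`,
#'   `adherence`, `outcome`.
#' @export
build_design <- function(ensemble,
                         outcome = c("index", "surveillance", "overall")) {
  stopifnot(inherits(ensemble, "crc_ensemble"))
  outcome <- match.arg(outcome)
  rows <- do.call(rbind, lapply(seq_along(ensemble$runs), function(i) {
    y <- ensemble$runs[[i]]$yearly
    out <- switch(outcome, index = y$index_total,
                  surveillance = y$surveillance,
                  overall = y$index_total + y$surveillance)
    data.frame(run = i, t = seq_len(nrow(y)) - 1L,
               participation = 100 * y$participants / y$invited,
               positivity = 100 * y$fit_positives / y$participants,
               adherence = 100 * ensemble$runs[[i]]$adherence,
               outcome = out)
  }))
  bad <- !is.finite(rows$participation) | !is.finite(rows$positivity)
  if (any(bad)) {
    warning(sprintf("dropping %d run-year row(s) with undefined participation or positivity",
                    sum(bad)))
    rows <- rows[!bad, ]
  }
  rows
}

#' Fit the demand meta-model
#'
#' Ordinary least squares of the yearly colonoscopy count on participation,
#' positivity and adherence (all in percentage points), the year index, the
#' interaction of each parameter with the year index, and the
#' positivity-by-participation interaction. Coefficients therefore read as
#' the change in yearly colonoscopies per +1 percentage point of a driver.
#'
#' @param design A design data frame from [build_design()].
#' @return An object of class `demand_metamodel` wrapping the `lm` fit, with
#'   `coef()` and `vcov()` methods.
#' @export
fit_sensitivity_model <- function(design) {
  stopifnot(is.data.frame(design),
            all(c("t", "participation", "positivity", "adherence",
                  "outcome") %in% names(design)))
  fit <- stats::lm(outcome ~ participation + positivity + adherence + t +
                     participation:t + positivity:t + adherence:t +
                     participation:positivity, data = design)
  if (anyNA(stats::coef(fit))) {
    stop("rank-deficient meta-model design; collinear columns: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  }
  # cache the covariance (summary.lm warns on interpolating fits)
  V <- suppressWarnings(stats::vcov(fit))
  structure(list(fit = fit, vcov = V, n = nrow(design)),
            class = "demand_metamodel")
}

#' @export
coef.demand_metamodel <- function(object, ...) stats::coef(object$fit)

#' @export
vcov.demand_metamodel <- function(object, ...) object$vcov

#' @export
print.demand_metamodel <- function(x, ...) {
  cat(sprintf("Demand meta-model (OLS on %d run-years)\n", x$n))
  print(signif(stats::coef(x$fit), 4))
  invisible(x)
}

#' @export
summary.demand_metamodel <- function(object, ...) summary(object$fit)

#' Marginal effect of a +1 percentage-point change in a demand driver
#'
#' Evaluates the fitted model's marginal effect of participation, positivity
#' or adherence on the yearly colonoscopy count:
#' `beta_param + beta_param:t * t`, plus
#' `beta_positivity:participation * conditioning value` for the positivity
#' (conditioning on participation) and participation (conditioning on
#' positivity) effects. A delta-method standard error is attached.
#'
#' @param model A `demand_metamodel`.
#' @param parameter One of `"participation"`, `"positivity"`, `"adherence"`.
#' @param t Year index (0 = first simulated year; 19 = last of a 20-year
#'   horizon).
#' @param at Conditioning value in percentage points: participation when
#'   `parameter = "positivity"`, positivity when
#'   `parameter = "participation"`; ignored for adherence.
#' @return List with `effect` (extra colonoscopies per year per +1
#'   percentage point) and `se`.
#' @export
#' @examples
#' d <- data.frame(t = rep(0:4, 20),
#'                 participation = runif(100, 40, 60),
#'                 positivity = runif(100, 4, 7),
#'                 adherence = runif(100, 30, 70))
#' d$outcome <- 10 * d$positivity + 2 * d$t + rnorm(100)
#' m <- fit_sensitivity_model(d)
#' marginal_effect(m, "positivity", t = 4, at = 50)
marginal_effect <- function(model,
                            parameter = c("participation", "positivity",
                                          "adherence"),
                            t, at = NULL) {
  stopifnot(inherits(model, "demand_metamodel"))
  parameter <- match.arg(parameter)
  cf <- stats::coef(model$fit)
  V <- model$vcov
  g <- stats::setNames(numeric(length(cf)), names(cf))
  g[parameter] <- 1
  g[paste0(parameter, ":t")] <- t
  if (parameter %in% c("participation", "positivity")) {
    if (is.null(at)) {
      stop("'at' (the conditioning value, in percentage points) is required ",
           "for the participation and positivity effects")
    }
    g["participation:positivity"] <- at
  }
  list(effect = unname(sum(g * cf)),
       se = unname(sqrt(drop(t(g) %*% V %*% g))))
}

#' Marginal-effect surfaces over years and conditioning values
#'
#' @param model A `demand_metamodel`.
#' @param parameter Driver name.
#' @param t Vector of year indices.
#' @param at Vector of conditioning values (percentage points); may be `NA`
#'   for adherence.
#' @return Data frame (parameter, t, at, effect, se), one row per
#'   combination.
#' @export
effects_grid <- function(model, parameter, t, at = NA_real_) {
  grid <- expand.grid(t = t, at = at)
  eff <- lapply(seq_len(nrow(grid)), function(i) {
    marginal_effect(model, parameter, t = grid$t[i],
                    at = if (is.na(grid$at[i])) NULL else grid$at[i])
  })
  data.frame(parameter = parameter, t = grid$t, at = grid$at,
             effect = vapply(eff, `[[`, 0, "effect"),
             se = vapply(eff, `[[`, 0, "se"))
}
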