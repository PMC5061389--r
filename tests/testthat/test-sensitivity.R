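random_design <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(run = seq_len(n), t = sample(0:19, n, TRUE),
             participation = runif(n, 40, 60),
             positivity = runif(n, 4, 7),
             adherence = runif(n, 30, 70))
}

linear_outcome <- function(d, beta) {
  beta["(Intercept)"] + beta["participation"] * d$participation +
    beta["positivity"] * d$positivity + beta["adherence"] * d$adherence +
    beta["t"] * d$t + beta["participation:t"] * d$participation * d$t +
    beta["positivity:t"] * d$positivity * d$t +
    beta["adherence:t"] * d$adherence * d$t +
    beta["participation:positivity"] * d$participation * d$positivity
}

all_terms <- c("(Intercept)", "participation", "positivity", "adherence",
               "t", "participation:t", "positivity:t", "adherence:t",
               "participation:positivity")

test_that("noise-free linear data is recovered to machine precision", {
  beta <- setNames(c(100, 2, 50, 0.5, 3, 0.1, 4, 0.02, 0.8), all_terms)
  d <- random_design(200, seed = 91)
  d$outcome <- linear_outcome(d, beta)
  m <- fit_sensitivity_model(d)
  expect_equal(coef(m)[all_terms], beta, tolerance = 1e-9)
  # residuals orthogonal to every design column
  X <- stats::model.matrix(m$fit)
  expect_lt(max(abs(crossprod(X, stats::residuals(m$fit)))), 1e-6)
})

test_that("the fit equals an independent normal-equations solve", {
  d <- random_design(12, seed = 92)
  set.seed(93)
  d$outcome <- rnorm(12, 500, 50)
  m <- fit_sensitivity_model(d)
  X <- cbind(1, d$participation, d$positivity, d$adherence, d$t,
             d$participation * d$t, d$positivity * d$t, d$adherence * d$t,
             d$participation * d$positivity)
  oracle <- drop(solve(crossprod(X), crossprod(X, d$outcome)))
  expect_equal(unname(coef(m)[all_terms]), oracle, tolerance = 1e-8)
})

test_that("coefficients are recovered within sampling error under noise", {
  beta <- setNames(c(-50, 1.5, 60, 0.4, 2, 0.08, 5, 0.03, 0.6), all_terms)
  d <- random_design(4000, seed = 94)
  set.seed(95)
  d$outcome <- linear_outcome(d, beta) + rnorm(4000, sd = 20)
  m <- fit_sensitivity_model(d)
  se <- sqrt(diag(vcov(m)))
  expect_true(all(abs(coef(m)[all_terms] - beta) < 3.5 * se[all_terms]))
})

test_that("rank-deficient designs are rejected with the collinear column", {
  d <- random_design(100, seed = 96)
  d$positivity <- d$participation      # collinear with the interaction set
  d$outcome <- rnorm(100)
  expect_error(fit_sensitivity_model(d), "collinear")
})

test_that("marginal effects follow the interaction arithmetic", {
  # hand-set model: beta_pos = 10, beta_pos:t = 1, beta_pos:part = 2
  beta <- setNames(c(0, 0, 10, 0, 0, 0, 1, 0, 2), all_terms)
  d <- random_design(200, seed = 97)
  d$outcome <- linear_outcome(d, beta)
  m <- fit_sensitivity_model(d)
  e <- marginal_effect(m, "positivity", t = 4, at = 50)
  expect_equal(e$effect, 10 + 4 * 1 + 50 * 2, tolerance = 1e-6)  # 114
  expect_gte(e$se, 0)
  # effect is affine in t and in the conditioning value by construction
  e2 <- marginal_effect(m, "positivity", t = 8, at = 50)
  e3 <- marginal_effect(m, "positivity", t = 4, at = 60)
  expect_equal(e2$effect - e$effect, 4 * 1, tolerance = 1e-6)
  expect_equal(e3$effect - e$effect, 10 * 2, tolerance = 1e-6)
  expect_error(marginal_effect(m, "positivity", t = 4), "'at'")
  expect_error(marginal_effect(m, "detection", t = 4), "arg")
})

test_that("zero interactions make the effect constant", {
  beta <- setNames(c(5, 3, 10, 1, 2, 0, 0, 0, 0), all_terms)
  d <- random_design(200, seed = 98)
  d$outcome <- linear_outcome(d, beta)
  m <- fit_sensitivity_model(d)
  eff <- sapply(c(0, 7, 19), function(t)
    marginal_effect(m, "positivity", t = t, at = 55)$effect)
  expect_equal(max(eff) - min(eff), 0, tolerance = 1e-6)
  adh <- marginal_effect(m, "adherence", t = 12)   # no conditioning needed
  expect_equal(adh$effect, 1, tolerance = 1e-6)
})

test_that("the design builder emits one row per run-year", {
  ens <- run_ensemble(small_config(0.02), n_runs = 2, seed = 99)
  d <- build_design(ens, "index")
  expect_equal(nrow(d), 2L * 20L)
  y <- ens$runs[[1]]$yearly
  expect_equal(d$participation[d$run == 1],
               100 * y$participants / y$invited)
  expect_equal(d$outcome[d$run == 1], y$index_total)
  ov <- build_design(ens, "overall")
  expect_equal(ov$outcome, d$outcome +
                 build_design(ens, "surveillance")$outcome)
  # a year with no participants loses its row, with a warning
  ens$runs[[1]]$yearly$participants[3] <- 0L
  ens$runs[[1]]$yearly$fit_positives[3] <- 0L
  expect_warning(d2 <- build_design(ens, "index"), "dropping 1")
  expect_equal(nrow(d2), 39L)
})
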