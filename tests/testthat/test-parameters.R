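test_that("packaged defaults carry the program's screening probabilities", {
  cfg <- load_config()
  expect_s3_class(cfg, "crc_config")
  expect_equal(unname(cfg$priors$result_initial$value),
               c(0.320, 0.175, 0.275, 0.167, 0.063))
  expect_equal(sum(cfg$priors$result_initial$value), 1, tolerance = 1e-12)
  expect_equal(sum(cfg$priors$result_successive$value), 1, tolerance = 1e-9)
  expect_equal(sum(cfg$priors$surveillance_result$value), 1, tolerance = 1e-9)
  expect_equal(cfg$priors$second_look$value, 0.123)
  # stratified fields expand to the eight gender/age strata
  expect_length(cfg$priors$participation_initial$mean, 8L)
  expect_length(cfg$priors$positivity_initial$mean, 8L)
  expect_equal(mean(cfg$priors$participation_initial$mean), 0.438)
  expect_equal(mean(cfg$priors$positivity_initial$mean), 0.067)
  # adherence prior spans the stated range
  expect_equal(c(cfg$priors$adherence$min, cfg$priors$adherence$max),
               c(0.20, 0.90))
  # fixed re-invitation intervals
  expect_equal(unname(cfg$reinvite[c("non_participation", "negative_fit",
                                     "refusal", "low_risk",
                                     "opportunistic_recent",
                                     "opportunistic_old",
                                     "negative_colonoscopy")]),
               c(2, 2, 2, 2, 4, 2, 10))
})

test_that("strata cover gender by age group exactly once", {
  st <- strata_table()
  expect_equal(nrow(st), 8L)
  expect_equal(stratum_index(1, 50), 1L)
  expect_equal(stratum_index(1, 69.99), 4L)
  expect_equal(stratum_index(2, 55), 6L)
  # every person aged 50-69 maps to exactly one stratum
  ages <- runif(500, 50, 70 - 1e-9)
  genders <- sample(1:2, 500, replace = TRUE)
  idx <- stratum_index(genders, ages)
  expect_true(all(idx %in% 1:8))
  expect_error(stratum_index(1, 49.5), "50")
})

test_that("user configs override fields, fall back elsewhere, and validate", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("screening:", "  second_look: 0.0"), f)
  expect_message(cfg <- load_config(f, quiet = FALSE), "fall")
  expect_equal(cfg$priors$second_look$value, 0)
  expect_equal(sample_prior(cfg$priors$second_look), 0)  # degenerate override
  # other fields fell back to the packaged defaults
  expect_equal(mean(cfg$priors$participation_initial$mean), 0.438)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("screening:", "  result_initial:", "    negative: 0.5",
               "    low_risk: 0.5", "    intermediate_risk: 0.5",
               "    high_risk: 0.0", "    cancer: 0.0"), bad)
  expect_error(load_config(bad), "result_initial.*sum to 1")

  bad2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("screening:", "  refusal: 1.3"), bad2)
  expect_error(load_config(bad2), "refusal")

  expect_error(load_config("/nonexistent/config.yaml"), "not found")
})

test_that("probability priors stay inside their support", {
  expect_error(probability_prior("beta", mean = 1.2, ess = 10), "\\[0, 1\\]")
  expect_error(probability_prior("uniform", min = -0.1, max = 0.5),
               "\\[0, 1\\]")
  p <- probability_prior("beta", mean = c(0, 0.5, 1), ess = 20)
  set.seed(1)
  draws <- replicate(200, sample_prior(p))
  expect_true(all(draws >= 0 & draws <= 1))
  expect_true(all(draws[1, ] == 0) && all(draws[3, ] == 1))
})

test_that("parameter sampling is a pure function of the random stream", {
  cfg <- load_config()
  set.seed(99); p1 <- sample_parameters(cfg)
  set.seed(99); p2 <- sample_parameters(cfg)
  expect_identical(p1, p2)
  set.seed(100)
  expect_false(identical(sample_parameters(cfg)$adherence, p1$adherence))
  # stratified fields are drawn per stratum (eight distinct draws)
  expect_length(p1$participation_initial, 8L)
  expect_gt(stats::sd(p1$participation_initial), 0)
})

test_that("sampled parameter sets always satisfy the type invariants", {
  cfg <- load_config()
  set.seed(7)
  prob_fields <- c("exclusion_initial", "exclusion_successive",
                   "opportunistic", "participation_initial",
                   "participation_prev_participant",
                   "participation_prev_nonparticipant", "positivity_initial",
                   "positivity_successive", "refusal", "second_look",
                   "adherence")
  for (i in 1:400) {
    ps <- sample_parameters(cfg)
    vals <- unlist(ps[prob_fields])
    expect_true(all(vals >= 0 & vals <= 1))
    expect_equal(sum(ps$result_initial), 1, tolerance = 1e-9)
    expect_equal(sum(ps$result_successive), 1, tolerance = 1e-9)
    expect_equal(sum(ps$surveillance_result), 1, tolerance = 1e-9)
    expect_true(ps$adherence >= 0.20 && ps$adherence <= 0.90)
  }
})

test_that("uniform adherence prior has the stated mean and truncated support", {
  cfg <- load_config()
  set.seed(5)
  draws <- replicate(10000, sample_prior(cfg$priors$adherence))
  expect_true(all(draws >= 0.20 & draws <= 0.90))
  expect_equal(mean(draws), 0.55, tolerance = 0.01)  # closed-form mean
})

test_that("fix_parameters collapses every prior to a point mass", {
  cfg <- fix_parameters(load_config(), list(adherence = 0.4))
  set.seed(1); a <- sample_parameters(cfg)
  set.seed(2); b <- sample_parameters(cfg)
  expect_identical(a, b)
  expect_equal(a$adherence, 0.4)
  expect_equal(mean(a$participation_initial), 0.438)
})
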