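params_with <- function(...) {
  crcdemand::sample_parameters(point_config(list(...)))
}

test_that("invitation routing matches exact multinomial expectations", {
  p <- params_with(exclusion_initial = 0.1, opportunistic = 0.05,
                   opportunistic_recent_share = 0.5)
  n <- 10000
  set.seed(21)
  out <- process_invitation(runif(n, 50, 70), sample(1:2, n, TRUE),
                            initial = rep(TRUE, n), params = p)
  tab <- table(out)
  # oracle: exact multinomial means 1000 / 450 (split 225+225) / 8550
  expect_equal(unname(tab[["excluded"]]), 1000, tolerance = 0.12)
  expect_equal(unname(tab[["deferred_4y"]] + tab[["deferred_2y"]]), 450,
               tolerance = 0.2)
  expect_equal(unname(tab[["invited"]]), 8550, tolerance = 0.02)
})

test_that("certain exclusion removes everyone before invitation", {
  p <- params_with(exclusion_initial = 1)
  out <- process_invitation(c(52, 61), c(1, 2), c(TRUE, TRUE), p)
  expect_true(all(out == "excluded"))
  expect_error(process_invitation(49, 1, TRUE, p), "50")
  expect_error(process_invitation(70, 1, TRUE, p), "70")
})

test_that("participation follows the previous-round Markov chain", {
  p <- params_with(participation_prev_participant = 0.85,
                   participation_prev_nonparticipant = 0.30)
  expect_false(any(draw_participation(rep(60, 50), rep(1, 50), FALSE,
                                      rep(TRUE, 50),
                                      params_with(participation_prev_participant = 0))))
  # long-run participation of the 2-state chain: b / (1 - a + b) = 2/3
  set.seed(22)
  n <- 4000
  state <- rep(FALSE, n)
  for (round in 1:120) {
    state <- draw_participation(rep(60, n), rep(1, n),
                                initial = rep(FALSE, n),
                                prev_participant = state, params = p)
  }
  expect_equal(mean(state), 2 / 3, tolerance = 0.035)
})

test_that("FIT positivity obeys its degenerate limits", {
  n <- 200
  age <- runif(n, 50, 70); g <- sample(1:2, n, TRUE)
  expect_false(any(draw_fit_result(age, g, rep(TRUE, n),
                                   params_with(positivity_initial = 0))))
  expect_true(all(draw_fit_result(age, g, rep(TRUE, n),
                                  params_with(positivity_initial = 1))))
})

test_that("index colonoscopy counts match expectation arithmetic", {
  # 1,000 positives, refusal 0.178, second-look 0.123:
  # expected colonoscopies = 1,000 x 0.822 x 1.123 = 923.1
  p <- params_with(refusal = 0.178, second_look = 0.123)
  n <- 100000
  set.seed(23)
  res <- perform_index_colonoscopy(runif(n, 50, 70), sample(1:2, n, TRUE),
                                   rep(TRUE, n), p)
  total_per_1000 <- 1000 * (sum(!res$refused) + sum(res$second_look)) / n
  expect_equal(total_per_1000, 923.1, tolerance = 6 / 923.1)
  expect_true(all(is.na(res$category[res$refused])))
  expect_true(all(res$second_look_delay[res$second_look] > 0 &
                    res$second_look_delay[res$second_look] <= 1))

  res0 <- perform_index_colonoscopy(runif(500, 50, 70), rep(1, 500),
                                    rep(TRUE, 500),
                                    params_with(second_look = 0))
  expect_equal(sum(res0$second_look), 0L)
})

test_that("index findings follow the configured result distribution", {
  p <- params_with(refusal = 0)
  n <- 50000
  set.seed(24)
  res <- perform_index_colonoscopy(runif(n, 50, 70), sample(1:2, n, TRUE),
                                   rep(TRUE, n), p)
  shares <- tabulate(res$category, 5) / n
  expect_equal(shares, c(0.320, 0.175, 0.275, 0.167, 0.063),
               tolerance = 0.03)
})

test_that("degenerate priors produce the expected run-level limits", {
  # no participation: nobody screens, no colonoscopies of any kind
  r <- run_simulation(point_config(list(participation_initial = 0,
                                        participation_prev_participant = 0,
                                        participation_prev_nonparticipant = 0)),
                      seed = 31)
  expect_true(all(r$yearly$participants == 0))
  expect_true(all(r$yearly$index_total == 0))
  expect_true(all(r$yearly$surveillance == 0))
  expect_gt(sum(r$yearly$invited), 0)

  # no positives: no colonoscopies after FIT and hence no surveillance
  r2 <- run_simulation(point_config(list(positivity_initial = 0,
                                         positivity_successive = 0)),
                       seed = 32)
  expect_gt(sum(r2$yearly$participants), 0)
  expect_true(all(r2$yearly$fit_positives == 0))
  expect_true(all(r2$yearly$index_total == 0))
  expect_true(all(r2$yearly$surveillance == 0))
})

test_that("runs are reproducible from their seed", {
  cfg <- small_config(0.02)
  r1 <- run_simulation(cfg, seed = 5)
  r2 <- run_simulation(cfg, seed = 5)
  expect_identical(r1$yearly, r2$yearly)
  expect_identical(r1$params, r2$params)
  r3 <- run_simulation(cfg, seed = 6)
  expect_false(identical(r1$yearly, r3$yearly))
})

test_that("yearly tallies nest and surveillance starts after the first year", {
  for (seed in 41:43) {
    y <- run_simulation(small_config(0.05), seed = seed)$yearly
    expect_true(all(y$participants <= y$invited))
    expect_true(all(y$successive_participants <= y$participants))
    expect_true(all(y$fit_positives <= y$participants))
    expect_true(all(y$index_first <= y$fit_positives))
    expect_true(all(y$index_total >= y$index_first))
    idx_sum <- y$index_negative + y$index_low_risk +
      y$index_intermediate_risk + y$index_high_risk + y$index_cancer
    expect_equal(idx_sum, y$index_first)
    srv_sum <- y$surv_negative + y$surv_low_risk +
      y$surv_intermediate_high + y$surv_cancer
    expect_equal(srv_sum, y$surveillance)
    # earliest surveillance exam is one year after an index finding
    expect_equal(y$surveillance[1], 0L)
    expect_gt(y$surveillance[3], 0L)
  }
})

test_that("raising positivity does not decrease colonoscopy demand", {
  lo <- point_config(list(positivity_initial = 0.05,
                          positivity_successive = 0.035), scale = 0.1)
  hi <- point_config(list(positivity_initial = 0.08,
                          positivity_successive = 0.056), scale = 0.1)
  y_lo <- run_simulation(lo, seed = 51)$yearly
  y_hi <- run_simulation(hi, seed = 51)$yearly
  expect_gt(sum(y_hi$index_total), sum(y_lo$index_total))
  expect_gt(sum(y_hi$surveillance), sum(y_lo$surveillance))
})

test_that("the event log honours mortality, ages and the age cap", {
  cfg <- small_config(0.03)
  r <- run_simulation(cfg, seed = 61, trace = TRUE)
  tr <- r$trace
  expect_true(all(tr$time < tr$death))      # no event at or after death
  inv <- tr[tr$event == "invitation", ]
  expect_true(all(inv$age >= 50 & inv$age < 70))
  srv <- tr[tr$event == "surveillance_colonoscopy", ]
  expect_gt(nrow(srv), 0)
  expect_true(all(srv$age < 80))            # age cap, every exam, every run
  # surveillance tally equals attended exams by calendar year of the event
  tab <- tabulate(floor(srv$time) + 1L, nbins = 20L)
  expect_equal(tab, r$yearly$surveillance)
  # conservation: every simulated person is accounted for
  expect_equal(r$n_persons,
               cfg$demography$initial_size + sum(cfg$demography$entrants))
  expect_true(all(tr$person >= 1 & tr$person <= r$n_persons))
})
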