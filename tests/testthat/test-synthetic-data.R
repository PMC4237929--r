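test_that("largest-remainder quotas allocate the deck exactly", {
  mix <- planning_mix(0.4, 0.3, 0.25, 0.05)
  cards <- generate_cards(20, mix, include_ambiguous = FALSE, seed = 1)
  counts <- table(cards$gold_accept)
  expect_equal(counts[["red"]], 8)
  expect_equal(counts[["yellow"]], 6)
  expect_equal(counts[["green"]], 5)
  expect_equal(counts[["black"]], 1)
})

test_that("one and only one ambiguous red-or-black card is generated", {
  cards <- generate_cards(40, seed = 2)
  expect_equal(sum(cards$gold_accept == "red|black"), 1)
  amb <- cards[cards$gold_accept == "red|black", ]
  expect_equal(amb$breathing, "apnoea")
  expect_equal(amb$death_signs, "none")
  expect_equal(sum(generate_cards(40, seed = 2,
                                  include_ambiguous = FALSE)$gold_accept ==
                     "red|black"), 0)
})

test_that("card generation is deterministic under a seed and validates", {
  a <- generate_cards(25, seed = 9)
  b <- generate_cards(25, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, generate_cards(25, seed = 10)))
  expect_identical(nrow(validate_cards(a)), 0L)
})

test_that("generated vitals reproduce their gold category under the engine", {
  for (seed in c(1, 42, 99)) {
    cards <- generate_cards(30, seed = seed)
    decisions <- classify_cards(cards)
    accept <- strsplit(cards$gold_accept, "|", fixed = TRUE)
    expect_true(all(purrr::map2_lgl(decisions$assigned, accept, `%in%`)))
    # gold LSI flags are the tree's indications on the card
    expect_equal(decisions$airway_lsi, cards$gold_airway_lsi)
    expect_equal(decisions$bleeding_lsi, cards$gold_bleeding_lsi)
  }
})

test_that("degenerate deck requests are rejected", {
  expect_error(generate_cards(3, seed = 1), "at least the number")
  expect_error(generate_cards(10, mix = c(red = 0.5, yellow = 0.2,
                                          green = 0.2, black = 0.2),
                              seed = 1), "sum to 1")
  expect_error(generate_cards(10, mix = planning_mix(0, 0.5, 0.5, 0),
                              seed = 1), "red-quota")
})

test_that("error-model rows must be stochastic", {
  k <- diag(4)
  k[1, 1] <- 0.9
  expect_error(error_model(k), "sum to 1")
  k2 <- diag(4); k2[1, 1] <- 1.2; k2[1, 2] <- -0.2
  expect_error(error_model(k2), "\\[0, 1\\]")
  expect_error(error_model(diag(4), lsi_miss_prob = 1.5), "lsi_miss_prob")
})

test_that("the mis-triage kernel builder implies its targets exactly", {
  mix <- planning_mix(0.4, 0.3, 0.25, 0.05)
  em <- mistriage_error_model(0.10, 0.06, mix)
  implied <- implied_mistriage_rates(em, mix)
  expect_equal(implied$under_triage, 0.10)
  expect_equal(implied$over_triage, 0.06)
  expect_equal(implied$correct, 1 - 0.16)
  expect_error(mistriage_error_model(0.6, 0.06, mix), "infeasible")
})

test_that("critical-rate targets are honoured exactly by the kernel builder", {
  mix <- planning_mix(0.4, 0.3, 0.25, 0.05)
  em <- mistriage_error_model(0.097, 0.064, mix,
                              critical_under_triage = 0.048,
                              critical_over_triage = 0.044)
  implied <- implied_mistriage_rates(em, mix)
  expect_equal(implied$under_triage, 0.097)
  expect_equal(implied$over_triage, 0.064)
  expect_equal(implied$critical_under_triage, 0.048)
  expect_equal(implied$critical_over_triage, 0.044)
  # criticals pin down the red-vs-rest operating point
  expect_equal(1 - 0.048 / mix[["red"]], 0.88, tolerance = 1e-12)
  expect_error(mistriage_error_model(0.05, 0.06, mix,
                                     critical_under_triage = 0.06),
               "cannot exceed")
})

test_that("lognormal time model reproduces target means and medians", {
  tm <- asav_time_model()
  target <- c(red = 41.8, yellow = 38.9, green = 14.5, black = 28.8)
  fitted <- time_model_means(tm)
  expect_true(all(abs(fitted - target) / target < 0.01))
  medians <- purrr::map_dbl(tm$params, ~ exp(.x$meanlog))
  expect_equal(unname(medians), unname(target * 35.0 / 35.4))
  expect_error(time_model(means = c(red = 10, yellow = 10, green = 10,
                                    black = 10),
                          medians = c(red = 12, yellow = 10, green = 10,
                                      black = 10)),
               "median <= mean")
})

test_that("empirical time model resamples the supplied observations", {
  tm <- time_model(family = "empirical",
                   samples = list(red = c(40, 44), yellow = 38, green = 15,
                                  black = 30))
  cards <- generate_cards(8, seed = 4)
  teams <- make_teams(2, seed = 5)
  runs <- simulate_runs(cards, teams, identity_error_model(), tm, seed = 6)
  expect_true(all(runs$elapsed_seconds %in% c(40, 44, 38, 15, 30)))
})

test_that("team rosters follow the composition weights", {
  degenerate <- list(
    employment = c(career = 1),
    qualification = list(career = c(paramedic = 1)),
    training = list(career = c(yes = 1))
  )
  teams <- make_teams(12, degenerate, seed = 8)
  expect_true(all(teams$staffing_class == "micu"))
  expect_true(all(teams$employment == "career"))
  expect_true(all(teams$prior_mstart_training == "yes"))

  roster <- make_teams(38, seed = 8)
  expect_identical(roster, make_teams(38, seed = 8))
  expect_true(all(roster$staffing_class %in%
                    c("micu", "patient_transport_ambulance",
                      "disaster_response", "excluded")))
  expect_error(make_teams(5, list(employment = c(career = 0),
                                  qualification = list(),
                                  training = list()), seed = 1),
               "nonnegative and not all zero")
})

test_that("zero-error simulation scores perfectly downstream", {
  cards <- generate_cards(20, seed = 21)
  teams <- make_teams(6, seed = 22)
  runs <- simulate_runs(cards, teams, identity_error_model(),
                        asav_time_model(), seed = 23)
  expect_equal(nrow(runs), 20 * 6)
  report <- metrics_report(runs, cards)
  est <- setNames(report$estimate, report$metric)
  expect_equal(est[["correct_rate"]], 1)
  expect_equal(est[["sensitivity"]], 1)
  expect_equal(est[["specificity"]], 1)
  expect_equal(est[["under_triage"]], 0)
  expect_equal(est[["over_triage"]], 0)
  expect_equal(est[["bleeding_lsi_rate"]], 1)
  expect_equal(est[["airway_lsi_rate"]], 1)
})

test_that("run simulation is deterministic under a seed", {
  cards <- generate_cards(10, seed = 31)
  teams <- make_teams(4, seed = 32)
  em <- mistriage_error_model(0.1, 0.06, lsi_miss_prob = 0.1)
  a <- simulate_runs(cards, teams, em, asav_time_model(), seed = 33)
  b <- simulate_runs(cards, teams, em, asav_time_model(), seed = 33)
  expect_identical(a, b)
  expect_false(identical(a, simulate_runs(cards, teams, em,
                                          asav_time_model(), seed = 34)))
})

test_that("red-to-yellow kernel leakage surfaces as under-triage", {
  mix <- planning_mix(0.4, 0.3, 0.25, 0.05)
  cards <- generate_cards(40, mix, include_ambiguous = FALSE, seed = 41)
  teams <- make_teams(25, seed = 42)
  k <- diag(4)
  dimnames(k) <- list(c("red", "yellow", "green", "black"),
                      c("red", "yellow", "green", "black"))
  k["red", "red"] <- 0.9
  k["red", "yellow"] <- 0.1
  em <- error_model(k)
  runs <- simulate_runs(cards, teams, em, asav_time_model(), seed = 43)
  got <- mistriage_rates(runs, cards)
  # expected rate: 10% leakage times the realised red share (16/40)
  expected <- 0.1 * 16 / 40
  se <- sqrt(expected * (1 - expected) / nrow(runs))
  expect_lt(abs(got$under_triage - expected), 3 * se)
  expect_equal(got$over_triage, 0)
})
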