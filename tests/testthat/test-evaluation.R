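two_card_deck <- function() {
  tibble::tibble(
    card_id = c("r1", "y1", "g1", "b1", "amb"),
    demographics = "", posture = "", injuries = "",
    can_walk = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    consciousness = c("unconscious", "alert", "alert", "unconscious",
                      "unconscious"),
    breathing = c("normal", "normal", "normal", "apnoea", "apnoea"),
    breathing_disorder_tags = "",
    spurting_haemorrhage = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    radial_pulse_present = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    skin_abnormal = FALSE,
    pain_level = 0L,
    death_signs = c("none", "none", "none", "decapitation", "none"),
    gold_accept = c("red", "yellow", "green", "black", "red|black"),
    gold_airway_lsi = c(TRUE, FALSE, FALSE, FALSE, TRUE),
    gold_bleeding_lsi = c(TRUE, FALSE, FALSE, FALSE, FALSE)
  )
}

run_on <- function(card_id, assigned, airway = FALSE, bleeding = FALSE) {
  new_runs(card_id, "t1", assigned, airway, bleeding, 30)
}

test_that("confusion table separates unambiguous and multi-accept runs", {
  cards <- two_card_deck()
  runs <- dplyr::bind_rows(
    run_on("r1", "red"), run_on("y1", "yellow"), run_on("g1", "green"),
    run_on("amb", "black"), run_on("amb", "red"), run_on("amb", "green")
  )
  ct <- build_confusion(runs, cards)
  expect_equal(sum(diag(ct$counts)), 3)
  expect_equal(ct$ambiguous_concordant, 2L)  # black and red both accepted
  expect_equal(ct$ambiguous_discordant, 1L)
  expect_equal(ct$n_total, 6L)
  expect_equal(sum(ct$counts) + ct$ambiguous_concordant +
                 ct$ambiguous_discordant, ct$n_total)
  expect_error(build_confusion(run_on("ghost", "red"), cards), "ghost")
})

test_that("correct rate counts the diagonal plus concordant multi-accepts", {
  cards <- two_card_deck()
  all_right <- dplyr::bind_rows(purrr::map(
    c("r1", "y1", "g1", "b1"),
    ~ run_on(.x, cards$gold_accept[cards$card_id == .x])
  ))
  expect_equal(correct_rate(build_confusion(all_right, cards)), 1)

  mixed <- dplyr::bind_rows(
    purrr::map(rep(c("r1", "y1"), 4), ~ run_on(.x, "red")),
    run_on("amb", "black"), run_on("g1", "green")
  )
  # diagonal 4 reds + 1 green + wrong yellows 4->0 + concordant 1 over 10
  ct <- build_confusion(mixed, cards)
  expect_equal(correct_rate(ct), 0.6)

  empty <- build_confusion(run_on(character(), character()), cards)
  expect_error(correct_rate(empty), "n_total")
})

test_that("red sensitivity and specificity come from the unambiguous 2x2", {
  cards <- two_card_deck()
  runs <- dplyr::bind_rows(
    purrr::map(1:8, ~ run_on("r1", "red")),
    purrr::map(1:2, ~ run_on("r1", "yellow")),
    purrr::map(1:9, ~ run_on("y1", "yellow")),
    run_on("g1", "red"),
    purrr::map(1:5, ~ run_on("amb", "red"))  # excluded from the 2x2
  )
  ss <- red_sens_spec(build_confusion(runs, cards))
  expect_equal(ss$sensitivity, 0.8)
  expect_equal(ss$specificity, 0.9)
  expect_equal(ss$n_positive, 10L)
  expect_equal(ss$n_negative, 10L)

  only_red <- build_confusion(run_on("r1", "red"), cards)
  expect_error(red_sens_spec(only_red), "specificity undefined")
  only_green <- build_confusion(run_on("g1", "green"), cards)
  expect_error(red_sens_spec(only_green), "sensitivity undefined")
})

test_that("likelihood ratios reproduce the published identities", {
  # whole collective: sens 87.4%, spec 91.0% -> LR+ 9.7
  expect_equal(likelihood_ratios(0.874, 0.910)$lr_pos, 9.71, tolerance = 1e-3)
  # previously-trained subgroup: 93.8% / 90.7% -> LR- 0.068
  expect_equal(likelihood_ratios(0.938, 0.907)$lr_neg, 0.0684,
               tolerance = 1e-3)
  # perfect sensitivity -> LR- exactly 0 (patient-transport-ambulance column)
  expect_equal(likelihood_ratios(1.0, 0.923)$lr_neg, 0)
  # uninformative test
  expect_equal(unlist(likelihood_ratios(0.5, 0.5)), c(lr_pos = 1, lr_neg = 1))
  # sentinels at the specificity boundaries
  expect_identical(likelihood_ratios(0.9, 1)$lr_pos, Inf)
  expect_true(is.nan(likelihood_ratios(0.9, 0)$lr_neg))
  expect_error(likelihood_ratios(1.2, 0.5), "\\[0, 1\\]")
})

test_that("likelihood-ratio identities hold wherever defined", {
  withr::with_seed(17, {
    sens <- runif(50)
    spec <- runif(50, 0.01, 0.99)
  })
  lr <- likelihood_ratios(sens, spec)
  expect_equal(lr$lr_pos * (1 - spec), sens, tolerance = 1e-12)
  expect_equal(lr$lr_neg * spec, 1 - sens, tolerance = 1e-12)
})

test_that("mis-triage pairs are scored literally", {
  cards <- two_card_deck()
  runs <- dplyr::bind_rows(
    run_on("r1", "yellow"),   # under + critical under
    run_on("y1", "red"),      # over + critical over
    run_on("g1", "green")     # correct
  )
  rates <- mistriage_rates(runs, cards)
  expect_equal(rates$over_triage, 1 / 3)
  expect_equal(rates$critical_over_triage, 1 / 3)
  expect_equal(rates$under_triage, 1 / 3)
  expect_equal(rates$critical_under_triage, 1 / 3)
  expect_equal(rates$other_mismatch, 0)

  # black instead of red is under-triage and critical under-triage
  black_on_red <- mistriage_rates(run_on("r1", "black"), cards)
  expect_equal(black_on_red$under_triage, 1)
  expect_equal(black_on_red$critical_under_triage, 1)

  # yellow on a gold black fits neither enumeration
  odd <- mistriage_rates(run_on("b1", "yellow"), cards)
  expect_equal(odd$other_mismatch, 1)
  expect_equal(odd$over_triage + odd$under_triage, 0)

  # concordant multi-accept runs enter no numerator
  amb <- mistriage_rates(run_on("amb", "black"), cards)
  expect_equal(amb$over_triage + amb$under_triage + amb$other_mismatch, 0)
})

test_that("rates match the brute-force per-run oracle on random tables", {
  for (seed in 1:8) {
    tbl <- random_run_table(n_runs = sample(10:50, 1), seed = seed)
    got <- mistriage_rates(tbl$runs, tbl$cards)
    ct <- build_confusion(tbl$runs, tbl$cards)
    want <- oracle_rates(tbl$runs, tbl$cards)
    expect_equal(got$over_triage, want$over)
    expect_equal(got$critical_over_triage, want$critical_over)
    expect_equal(got$under_triage, want$under)
    expect_equal(got$critical_under_triage, want$critical_under)
    expect_equal(got$other_mismatch, want$other)
    expect_equal(correct_rate(ct), want$correct)

    # exact partition of all runs; critical pairs nest inside their lists
    expect_equal(want$correct + got$over_triage + got$under_triage +
                   got$other_mismatch + want$amb_disc, 1)
    expect_lte(got$critical_over_triage, got$over_triage)
  }
})

test_that("LSI accuracy scores indicated-equals-gold per intervention", {
  cards <- two_card_deck()
  runs <- dplyr::bind_rows(
    run_on("r1", "red", airway = TRUE, bleeding = TRUE),    # both right
    run_on("r1", "red", airway = FALSE, bleeding = TRUE),   # airway missed
    run_on("g1", "green", airway = FALSE, bleeding = FALSE), # both right
    run_on("g1", "green", airway = TRUE, bleeding = FALSE)  # airway overcalled
  )
  acc <- lsi_accuracy(runs, cards)
  expect_equal(acc$airway_lsi_rate, 0.5)
  expect_equal(acc$bleeding_lsi_rate, 1)
})

test_that("Wald intervals match closed-form values and clip to [0, 1]", {
  # the published whole-collective interval: 83.9% of 780 -> (81.3, 86.5)
  ci <- wald_ci(0.839, 780, 0.95)
  expect_equal(round(100 * ci$lower, 1), 81.3)
  expect_equal(round(100 * ci$upper, 1), 86.5)

  expect_equal(unlist(wald_ci(0, 100)), c(lower = 0, upper = 0))
  ci5 <- wald_ci(0.5, 100, 0.95)
  expect_equal(ci5$lower, 0.402, tolerance = 1e-3)
  expect_equal(ci5$upper, 0.598, tolerance = 1e-3)
  expect_error(wald_ci(0.5, 100, level = 1.5), "level")
  expect_error(wald_ci(1.2, 100), "p_hat")
})

test_that("subgroup reports apply the homogeneity filters", {
  cards <- generate_cards(12, seed = 51)
  teams <- new_teams(
    team_id = c("t1", "t2", "t3", "t4"),
    leader_qualification = c("paramedic", "emt", "emt", "other"),
    assistant_qualification = c("emt", "emt", "paramedic", "other"),
    employment = c("career", "volunteer", "mixed", "career"),
    prior_mstart_training = c("yes", "no", "unknown", "mixed")
  )
  runs <- simulate_runs(cards, teams, identity_error_model(),
                        asav_time_model(), seed = 52)

  by_staff <- subgroup_report(runs, cards, teams, "staffing_class")
  expect_setequal(unique(by_staff$group),
                  c("micu", "patient_transport_ambulance",
                    "disaster_response"))  # t3 (emt+paramedic) excluded

  by_emp <- subgroup_report(runs, cards, teams, "employment")
  expect_setequal(unique(by_emp$group), c("career", "volunteer"))

  by_train <- subgroup_report(runs, cards, teams, "prior_training")
  expect_setequal(unique(by_train$group), c("yes", "no"))

  # zero-error simulation: every subgroup is perfect
  sens <- dplyr::filter(by_staff, metric == "sensitivity")
  expect_true(all(sens$estimate == 1))
})

test_that("confusion tables tidy and plot", {
  tbl <- random_run_table(30, seed = 61)
  ct <- build_confusion(tbl$runs, tbl$cards)
  tidied <- tidy(ct)
  expect_equal(sum(tidied$n), ct$n_total)
  p <- autoplot(ct)
  expect_s3_class(p, "ggplot")
})
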