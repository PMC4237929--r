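# Independent reference implementations used as oracles. These deliberately
# avoid the package's engine and rate machinery: the triage oracle is a
# hand-coded nested conditional, the rate oracle a literal per-run loop over
# the enumerated mis-triage pair lists.

oracle_asav_one <- function(can_walk, consciousness, breathing,
                            spurting, radial, skin, death_signs) {
  airway <- FALSE
  bleeding <- FALSE
  if (death_signs != "none") {
    return(list(assigned = "black", airway = FALSE, bleeding = FALSE))
  }
  if (spurting) bleeding <- TRUE
  if (can_walk) {
    return(list(assigned = "green", airway = airway, bleeding = bleeding))
  }
  if (consciousness == "unconscious") {
    return(list(assigned = "red", airway = TRUE, bleeding = bleeding))
  }
  if (breathing %in% c("disorder", "apnoea")) {
    return(list(assigned = "red", airway = airway, bleeding = bleeding))
  }
  if (!radial || skin) {
    return(list(assigned = "red", airway = airway, bleeding = bleeding))
  }
  list(assigned = "yellow", airway = airway, bleeding = bleeding)
}

# full discretised cross-product of the vital-sign fields the predicate
# vocabulary can read (576 combinations), as a cards tibble
vitals_grid_cards <- function() {
  grid <- expand.grid(
    can_walk = c(TRUE, FALSE),
    consciousness = c("alert", "responsive", "unconscious"),
    breathing = c("normal", "disorder", "apnoea"),
    spurting_haemorrhage = c(TRUE, FALSE),
    radial_pulse_present = c(TRUE, FALSE),
    skin_abnormal = c(TRUE, FALSE),
    death_signs = c("none", "decapitation", "torso_destruction",
                    "other_definite"),
    stringsAsFactors = FALSE
  )
  tibble::tibble(
    card_id = sprintf("grid_%03d", seq_len(nrow(grid))),
    demographics = "", posture = "", injuries = "",
    can_walk = grid$can_walk,
    consciousness = grid$consciousness,
    breathing = grid$breathing,
    breathing_disorder_tags = "",
    spurting_haemorrhage = grid$spurting_haemorrhage,
    radial_pulse_present = grid$radial_pulse_present,
    skin_abnormal = grid$skin_abnormal,
    pain_level = 0L,
    death_signs = grid$death_signs,
    gold_accept = "red",
    gold_airway_lsi = FALSE,
    gold_bleeding_lsi = FALSE
  )
}

# literal per-run scoring loop over the enumerated pair lists
oracle_rates <- function(runs, cards) {
  accept <- strsplit(cards$gold_accept, "|", fixed = TRUE)
  names(accept) <- cards$card_id
  over_pairs <- list(c("yellow", "red"), c("green", "red"),
                     c("black", "red"), c("green", "yellow"))
  under_pairs <- list(c("red", "yellow"), c("yellow", "green"),
                      c("red", "green"), c("red", "black"))
  in_pairs <- function(gold, assigned, pairs) {
    any(vapply(pairs, function(p) p[1] == gold && p[2] == assigned, logical(1)))
  }
  tallies <- c(correct = 0, over = 0, critical_over = 0, under = 0,
               critical_under = 0, other = 0, amb_disc = 0)
  for (i in seq_len(nrow(runs))) {
    acc <- accept[[runs$card_id[i]]]
    a <- runs$assigned[i]
    if (length(acc) > 1) {
      if (a %in% acc) tallies["correct"] <- tallies["correct"] + 1
      else tallies["amb_disc"] <- tallies["amb_disc"] + 1
      next
    }
    g <- acc
    if (a == g) {
      tallies["correct"] <- tallies["correct"] + 1
      next
    }
    hit <- FALSE
    if (in_pairs(g, a, over_pairs)) {
      tallies["over"] <- tallies["over"] + 1
      hit <- TRUE
    }
    if (in_pairs(g, a, under_pairs)) {
      tallies["under"] <- tallies["under"] + 1
      hit <- TRUE
    }
    if (a == "red" && g != "red") {
      tallies["critical_over"] <- tallies["critical_over"] + 1
    }
    if (g == "red" && a != "red") {
      tallies["critical_under"] <- tallies["critical_under"] + 1
    }
    if (!hit) tallies["other"] <- tallies["other"] + 1
  }
  as.list(tallies / nrow(runs))
}

# random run table over a small random deck, for property-style tests
random_run_table <- function(n_runs, seed) {
  withr::with_seed(seed, {
    cards <- generate_cards(
      n = sample(5:12, 1),
      include_ambiguous = sample(c(TRUE, FALSE), 1),
      seed = sample.int(10000, 1)
    )
    runs <- new_runs(
      card_id = sample(cards$card_id, n_runs, replace = TRUE),
      team_id = "team_001",
      assigned = sample(triage_categories(), n_runs, replace = TRUE),
      airway_lsi = sample(c(TRUE, FALSE), n_runs, replace = TRUE),
      bleeding_lsi = sample(c(TRUE, FALSE), n_runs, replace = TRUE),
      elapsed_seconds = stats::runif(n_runs, 5, 90)
    )
    list(cards = cards, runs = runs)
  })
}
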