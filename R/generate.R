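#' Largest-remainder allocation of casualties to categories
#'
#' @param n total count.
#' @param mix a [planning_mix()] (named proportions over the categories).
#' @return named integer vector of per-category quotas summing to `n`.
#' @keywords internal
largest_remainder <- function(n, mix) {
  exact <- n * mix
  quota <- floor(exact)
  left <- n - sum(quota)
  if (left > 0) {
    # ties broken by position in the mix (red, yellow, green, black)
    extra <- order(exact - quota, decreasing = TRUE)[seq_len(left)]
    quota[extra] <- quota[extra] + 1
  }
  stats::setNames(as.integer(quota), names(mix))
}

#' Misclassification model for simulated triage runs
#'
#' The error model drives the simulated providers: the `confusion_kernel` is
#' a row-stochastic matrix over the four categories — row = the category the
#' algorithm implies for the card, column = the probability the simulated
#' team assigns that category — and `lsi_miss_prob` is the probability of a
#' wrong lifesaving-intervention decision, applied independently per LSI and
#' per run.
#'
#' @param confusion_kernel 4x4 numeric matrix; rows and columns in the order
#'   red, yellow, green, black (dimnames are set accordingly). Each row must
#'   sum to 1 within 1e-9 with entries in \[0, 1\].
#' @param lsi_miss_prob probability in \[0, 1\].
#' @return an object of class `error_model`.
#' @seealso [identity_error_model()], [mistriage_error_model()],
#'   [implied_mistriage_rates()]
#' @export
error_model <- function(confusion_kernel, lsi_miss_prob = 0) {
  cats <- c("red", "yellow", "green", "black")
  k <- as.matrix(confusion_kernel)
  if (!all(dim(k) == c(4, 4))) {
    stop("confusion_kernel must be a 4x4 matrix", call. = FALSE)
  }
  if (!is.null(rownames(k))) k <- k[cats, cats] else dimnames(k) <- list(cats, cats)
  if (any(k < 0 | k > 1)) {
    stop("confusion_kernel entries must lie in [0, 1]", call. = FALSE)
  }
  if (any(abs(rowSums(k) - 1) > 1e-9)) {
    stop("every confusion_kernel row must sum to 1 (within 1e-9)",
         call. = FALSE)
  }
  if (lsi_miss_prob < 0 || lsi_miss_prob > 1) {
    stop("lsi_miss_prob must lie in [0, 1]", call. = FALSE)
  }
  structure(list(confusion_kernel = k, lsi_miss_prob = lsi_miss_prob),
            class = "error_model")
}

#' @rdname error_model
#' @export
identity_error_model <- function() {
  error_model(diag(4), lsi_miss_prob = 0)
}

#' Build an error model implying target over- and under-triage rates
#'
#' Constructs the simplest kernel whose population mis-triage rates, under a
#' given casualty mix, equal the requested targets. With only the two
#' aggregate targets, the whole under-triage mass is red-to-yellow leakage
#' and the whole over-triage mass green-to-yellow leakage. When the critical
#' rates are also given, the critical under-triage mass goes on
#' red-to-yellow with the remainder on yellow-to-green, and the critical
#' over-triage mass on yellow-to-red with the remainder on green-to-yellow —
#' which additionally pins down the red-vs-rest sensitivity
#' (`1 - critical_under / mix_red`) and specificity
#' (`1 - critical_over / (1 - mix_red)`). Everything else stays on the
#' diagonal; the implied rates are exact by construction (see
#' [implied_mistriage_rates()]).
#'
#' @param under_triage,over_triage target population rates in \[0, 1\].
#' @param mix the casualty mix the rates refer to ([planning_mix()]).
#' @param lsi_miss_prob per-LSI, per-run error probability.
#' @param critical_under_triage,critical_over_triage optional targets for
#'   the critical rates; each must not exceed its aggregate rate.
#' @return an `error_model`.
#' @examples
#' em <- mistriage_error_model(0.10, 0.06, planning_mix(0.4, 0.3, 0.25, 0.05))
#' implied_mistriage_rates(em, planning_mix(0.4, 0.3, 0.25, 0.05))
#' @export
mistriage_error_model <- function(under_triage, over_triage,
                                  mix = planning_mix(0.4, 0.3, 0.25, 0.05),
                                  lsi_miss_prob = 0,
                                  critical_under_triage = NULL,
                                  critical_over_triage = NULL) {
  mix <- validate_mix(mix)
  k <- diag(4)
  cats <- c("red", "yellow", "green", "black")
  dimnames(k) <- list(cats, cats)
  leak <- function(from, to, mass, what) {
    if (mass <= 0) return()
    if (mix[[from]] <= 0) {
      stop(sprintf("cannot place %s mass: mix has no %s casualties",
                   what, from), call. = FALSE)
    }
    p <- mass / mix[[from]]
    if (k[from, from] - p < -1e-12) {
      stop(what, " target infeasible for this mix", call. = FALSE)
    }
    k[from, to] <<- k[from, to] + p
    k[from, from] <<- k[from, from] - p
  }
  cu <- critical_under_triage %||% under_triage
  if (cu > under_triage) {
    stop("critical_under_triage cannot exceed under_triage", call. = FALSE)
  }
  leak("red", "yellow", cu, "under_triage")
  leak("yellow", "green", under_triage - cu, "under_triage")
  co <- critical_over_triage %||% 0
  if (co > over_triage) {
    stop("critical_over_triage cannot exceed over_triage", call. = FALSE)
  }
  leak("yellow", "red", co, "over_triage")
  leak("green", "yellow", over_triage - co, "over_triage")
  error_model(k, lsi_miss_prob)
}

#' Population mis-triage rates implied by an error model
#'
#' Closed-form expectation of the evaluation rates when cards follow `mix`
#' (with no ambiguous card) and assignments follow the model's confusion
#' kernel: each rate is the mix-weighted sum of the kernel mass falling on
#' the corresponding enumerated gold/assigned category pairs.
#'
#' @param model an [error_model()].
#' @param mix a [planning_mix()].
#' @return one-row tibble with `correct`, `over_triage`,
#'   `critical_over_triage`, `under_triage`, `critical_under_triage` and
#'   `other_mismatch`.
#' @export
implied_mistriage_rates <- function(model, mix) {
  mix <- validate_mix(mix)
  k <- model$confusion_kernel
  pair_mass <- function(pairs) {
    sum(purrr::map_dbl(pairs, ~ mix[[.x[1]]] * k[.x[1], .x[2]]))
  }
  tibble::tibble(
    correct = sum(purrr::map_dbl(c("red", "yellow", "green", "black"),
                                 ~ mix[[.x]] * k[.x, .x])),
    over_triage = pair_mass(over_triage_pairs()),
    critical_over_triage = pair_mass(critical_over_pairs()),
    under_triage = pair_mass(under_triage_pairs()),
    critical_under_triage = pair_mass(critical_under_pairs()),
    other_mismatch = pair_mass(other_mismatch_pairs())
  )
}

#' Per-category triage-time model
#'
#' Service-time distributions for the triage of one patient, by expected
#' triage category. The default family is lognormal — strictly positive and
#' right-skewed, matching service-time data whose mean exceeds the median —
#' parameterised so the distribution reproduces a target (mean, median)
#' pair exactly: `meanlog = log(median)` and
#' `sdlog = sqrt(2 log(mean / median))`, which requires `mean >= median`.
#' An empirical family resamples supplied observations instead, for use when
#' raw times are available.
#'
#' When `medians` is omitted they default to the means scaled by the
#' published whole-collective median/mean ratio 35.0 / 35.4, the only
#' skewness information the study summaries provide.
#'
#' @param means named numeric, mean seconds per category
#'   (`red`, `yellow`, `green`, `black`).
#' @param medians optional named numeric of per-category medians.
#' @param family `"lognormal"` or `"empirical"`.
#' @param samples for the empirical family, a named list of observed times
#'   per category.
#' @return an object of class `time_model`.
#' @seealso [asav_time_model()], [time_model_means()]
#' @export
time_model <- function(means = NULL, medians = NULL,
                       family = c("lognormal", "empirical"),
                       samples = NULL) {
  family <- match.arg(family)
  cats <- c("red", "yellow", "green", "black")
  if (family == "lognormal") {
    if (is.null(means)) stop("lognormal family requires `means`", call. = FALSE)
    means <- means[cats]
    if (anyNA(means) || any(means <= 0)) {
      stop("`means` must give a positive mean for each of red, yellow, ",
           "green, black", call. = FALSE)
    }
    if (is.null(medians)) medians <- means * 35.0 / 35.4
    medians <- medians[cats]
    if (any(medians > means)) {
      stop("lognormal family requires median <= mean in every category",
           call. = FALSE)
    }
    params <- purrr::map2(means, medians, function(m, md) {
      list(meanlog = log(md), sdlog = sqrt(2 * log(m / md)))
    })
    structure(list(family = family, params = params,
                   means = stats::setNames(as.numeric(means), cats)),
              class = "time_model")
  } else {
    if (is.null(samples)) stop("empirical family requires `samples`", call. = FALSE)
    missing_cats <- setdiff(cats, names(samples))
    if (length(missing_cats) > 0) {
      stop("empirical samples missing for: ",
           paste(missing_cats, collapse = ", "), call. = FALSE)
    }
    samples <- samples[cats]
    if (any(purrr::map_lgl(samples, ~ length(.x) == 0 || any(.x < 0)))) {
      stop("empirical samples must be non-empty and non-negative", call. = FALSE)
    }
    structure(list(family = family, samples = samples,
                   means = purrr::map_dbl(samples, mean)),
              class = "time_model")
  }
}

#' @rdname time_model
#' @param model a `time_model`.
#' @return `time_model_means()` returns the analytic (lognormal) or sample
#'   (empirical) mean seconds per category.
#' @export
time_model_means <- function(model) {
  if (model$family == "lognormal") {
    purrr::map_dbl(model$params, ~ exp(.x$meanlog + .x$sdlog^2 / 2))
  } else {
    model$means
  }
}

#' Time model calibrated to the published per-category means
#'
#' Lognormal [time_model()] with category means 41.8 (red), 38.9 (yellow),
#' 14.5 (green) and 28.8 (black) seconds, the study's reported mean primary
#' survey durations by expected triage category.
#'
#' @return a `time_model`.
#' @export
asav_time_model <- function() {
  time_model(means = c(red = 41.8, yellow = 38.9, green = 14.5, black = 28.8))
}

sample_times <- function(model, categories) {
  out <- numeric(length(categories))
  for (cat in unique(categories)) {
    idx <- which(categories == cat)
    out[idx] <- if (model$family == "lognormal") {
      p <- model$params[[cat]]
      stats::rlnorm(length(idx), meanlog = p$meanlog, sdlog = p$sdlog)
    } else {
      s <- model$samples[[cat]]
      s[sample.int(length(s), length(idx), replace = TRUE)]
    }
  }
  out
}

check_seed <- function(seed) {
  if (length(seed) != 1 || is.na(seed) || seed != as.integer(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  as.integer(seed)
}

injury_pools <- function() {
  list(
    green = c("superficial laceration (left forearm)",
              "abrasion (right knee)", "contusion (left shoulder)",
              "small cut (scalp)"),
    yellow = c("closed fracture (right lower leg)",
               "suspected fracture (left forearm)",
               "deep laceration (right thigh)",
               "dislocated shoulder (left)"),
    red = c("open fracture (left femur)", "blunt abdominal trauma (abdomen)",
            "penetrating chest wound (left thorax)",
            "severe head injury (skull)"),
    black = c("destruction of the torso (trunk)", "decapitation (neck)",
              "open skull with brain exposure (head)")
  )
}

#' Generate synthetic casualty description cards
#'
#' Emulates a deck of written dummy description cards: `n` casualties are
#' allocated to gold categories by exact largest-remainder quota on `mix`,
#' and each card's vital signs are sampled conditional on its category so
#' that the default ASAV tree reproduces it ([classify_cards()] always lands
#' in the card's accept-set). Gold lifesaving-intervention flags are the
#' indications the algorithm raises on the card (airway opening for the
#' unconscious, bleeding control for spurting haemorrhage).
#'
#' When `include_ambiguous` is `TRUE`, exactly one red-quota card is replaced
#' by the ambiguous consensus-failure case — apnoeic and pulseless with
#' massive torso trauma but no definite sign of death — whose accept-set is
#' `{red, black}`.
#'
#' @param n number of cards; must be at least the number of categories with
#'   positive mix proportion.
#' @param mix a [planning_mix()]; defaults to a 40/30/25/5 red/yellow/green/
#'   black exercise deck.
#' @param include_ambiguous include the one red-or-black card?
#' @param seed integer; all sampling is reproducible under it.
#' @param disorder_labels labels to draw breathing-disorder tags from.
#' @return a validated cards tibble ([new_cards()]) in randomised deck order.
#' @examples
#' cards <- generate_cards(20, seed = 7)
#' dplyr::count(cards, gold_accept)
#' @export
generate_cards <- function(n,
                           mix = planning_mix(0.4, 0.3, 0.25, 0.05),
                           include_ambiguous = TRUE,
                           seed,
                           disorder_labels = breathing_disorder_labels()) {
  mix <- validate_mix(mix)
  seed <- check_seed(seed)
  n_active <- sum(mix > 0)
  if (n < n_active) {
    stop("`n` must be at least the number of categories with positive mix (",
         n_active, ")", call. = FALSE)
  }
  quota <- largest_remainder(n, mix)
  if (include_ambiguous && quota[["red"]] < 1) {
    stop("include_ambiguous requires at least one red-quota card", call. = FALSE)
  }

  withr::with_seed(seed, {
    rows <- list()
    pools <- injury_pools()
    demo_pool <- c("male, ~25 y", "female, ~40 y", "male, ~60 y",
                   "female, ~17 y", "male, ~35 y", "female, ~70 y")
    for (cat in names(quota)) {
      for (i in seq_len(quota[[cat]])) {
        row <- switch(cat,
          green = list(
            can_walk = TRUE, consciousness = "alert", breathing = "normal",
            tags = "", spurting = stats::runif(1) < 0.15,
            radial = TRUE, skin = FALSE,
            pain = sample(0:6, 1), death = "none",
            posture = sample(c("walking around", "sitting upright"), 1),
            injuries = sample(pools$green, 1)
          ),
          yellow = list(
            can_walk = FALSE,
            consciousness = sample(c("alert", "responsive"), 1),
            breathing = "normal", tags = "",
            spurting = stats::runif(1) < 0.20,
            radial = TRUE, skin = FALSE,
            pain = sample(3:9, 1), death = "none",
            posture = sample(c("lying supine", "sitting, leaning back"), 1),
            injuries = paste(sample(pools$yellow, 2), collapse = "; ")
          ),
          red = {
            mechanism <- sample(c("unconscious", "disorder", "apnoea",
                                  "circulation"), 1,
                                prob = c(0.40, 0.30, 0.10, 0.20))
            consciousness <- if (mechanism == "unconscious") "unconscious"
              else sample(c("alert", "responsive"), 1)
            breathing <- switch(mechanism, disorder = "disorder",
                                apnoea = "apnoea", "normal")
            circulation_bad <- mechanism == "circulation" ||
              stats::runif(1) < 0.25
            list(
              can_walk = FALSE, consciousness = consciousness,
              breathing = breathing,
              tags = if (breathing == "disorder") {
                paste(sample(disorder_labels,
                             sample(1:2, 1)), collapse = "|")
              } else "",
              spurting = stats::runif(1) < 0.30,
              radial = !circulation_bad,
              skin = circulation_bad && stats::runif(1) < 0.5,
              pain = sample(0:10, 1), death = "none",
              posture = "lying supine, motionless",
              injuries = paste(sample(pools$red, 2), collapse = "; ")
            )
          },
          black = list(
            can_walk = FALSE, consciousness = "unconscious",
            breathing = "apnoea", tags = "", spurting = FALSE,
            radial = FALSE, skin = TRUE, pain = 0L,
            death = sample(c("decapitation", "torso_destruction",
                             "other_definite"), 1),
            posture = "lying prone, motionless",
            injuries = sample(pools$black, 1)
          )
        )
        row$gold <- cat
        rows <- c(rows, list(row))
      }
    }

    if (include_ambiguous) {
      amb_idx <- which(purrr::map_chr(rows, "gold") == "red")[1]
      rows[[amb_idx]] <- list(
        can_walk = FALSE, consciousness = "unconscious",
        breathing = "apnoea", tags = "", spurting = FALSE,
        radial = FALSE, skin = TRUE, pain = 0L, death = "none",
        posture = "lying supine, motionless",
        injuries = "massive crush trauma (trunk); open skull fracture (head)",
        gold = "red|black"
      )
    }

    rows <- rows[sample.int(length(rows))]
    cards <- new_cards(
      card_id = sprintf("card_%03d", seq_along(rows)),
      demographics = sample(demo_pool, length(rows), replace = TRUE),
      posture = purrr::map_chr(rows, "posture"),
      injuries = purrr::map_chr(rows, "injuries"),
      can_walk = purrr::map_lgl(rows, "can_walk"),
      consciousness = purrr::map_chr(rows, "consciousness"),
      breathing = purrr::map_chr(rows, "breathing"),
      breathing_disorder_tags = purrr::map_chr(rows, "tags"),
      spurting_haemorrhage = purrr::map_lgl(rows, "spurting"),
      radial_pulse_present = purrr::map_lgl(rows, "radial"),
      skin_abnormal = purrr::map_lgl(rows, "skin"),
      pain_level = purrr::map_int(rows, ~ as.integer(.x$pain)),
      death_signs = purrr::map_chr(rows, "death"),
      gold_accept = purrr::map_chr(rows, "gold"),
      gold_airway_lsi = FALSE,
      gold_bleeding_lsi = FALSE
    )
    # gold LSI flags are the indications the default tree raises on the card
    decisions <- classify_cards(cards, asav_algorithm())
    cards$gold_airway_lsi <- decisions$airway_lsi
    cards$gold_bleeding_lsi <- decisions$bleeding_lsi
    ok <- purrr::map2_lgl(split_accept(cards$gold_accept), decisions$assigned,
                          ~ .y %in% .x)
    stopifnot(all(ok))
    cards
  })
}

#' Default team-composition weights
#'
#' Sampling weights for [make_teams()], shaped like the study roster: 55 of
#' 76 providers were career staff; career qualifications split 41 paramedic /
#' 9 EMT / 5 other with mSTaRT pre-training 37 yes / 16 no / 2 unknown, and
#' volunteer qualifications 2 / 3 / 16 with pre-training 3 / 15 / 3.
#'
#' @return a nested list with components `employment`, `qualification`
#'   (per-employment) and `training` (per-employment).
#' @export
default_team_weights <- function() {
  list(
    employment = c(career = 55, volunteer = 21),
    qualification = list(
      career = c(paramedic = 41, emt = 9, other = 5),
      volunteer = c(paramedic = 2, emt = 3, other = 16)
    ),
    training = list(
      career = c(yes = 37, no = 16, unknown = 2),
      volunteer = c(yes = 3, no = 15, unknown = 3)
    )
  )
}

sample_weighted <- function(n, weights) {
  if (length(weights) == 0 || any(weights < 0) || sum(weights) <= 0) {
    stop("composition weights must be nonnegative and not all zero",
         call. = FALSE)
  }
  sample(names(weights), n, replace = TRUE, prob = weights / sum(weights))
}

#' Generate a synthetic roster of two-person triage teams
#'
#' Each team member's employment status, professional qualification and
#' prior mSTaRT-training status are sampled from `composition_weights`
#' (qualification and training conditional on employment). Team-level
#' employment is `"mixed"` when the members differ, and team-level training
#' is `"unknown"` if either member's is, `"mixed"` if they differ, else the
#' shared value — mirroring the homogeneous-team filters of the subgroup
#' analyses. The staffing class is derived from the two qualifications and
#' never stored independently.
#'
#' @param n number of teams.
#' @param composition_weights see [default_team_weights()].
#' @param seed integer seed.
#' @return a teams tibble ([new_teams()]).
#' @examples
#' teams <- make_teams(10, seed = 3)
#' dplyr::count(teams, staffing_class)
#' @export
make_teams <- function(n, composition_weights = default_team_weights(), seed) {
  seed <- check_seed(seed)
  w <- composition_weights
  if (is.null(w$employment) || is.null(w$qualification) || is.null(w$training)) {
    stop("composition_weights needs components employment, qualification, ",
         "training", call. = FALSE)
  }
  withr::with_seed(seed, {
    member <- function() {
      emp <- sample_weighted(n, w$employment)
      qual <- purrr::map_chr(emp, ~ sample_weighted(1, w$qualification[[.x]]))
      train <- purrr::map_chr(emp, ~ sample_weighted(1, w$training[[.x]]))
      tibble::tibble(emp = emp, qual = qual, train = train)
    }
    leader <- member()
    assistant <- member()
    employment <- dplyr::if_else(leader$emp == assistant$emp, leader$emp,
                                 "mixed")
    training <- dplyr::case_when(
      leader$train == "unknown" | assistant$train == "unknown" ~ "unknown",
      leader$train == assistant$train ~ leader$train,
      .default = "mixed"
    )
    new_teams(
      team_id = sprintf("team_%03d", seq_len(n)),
      leader_qualification = leader$qual,
      assistant_qualification = assistant$qual,
      employment = employment,
      prior_mstart_training = training
    )
  })
}

#' Simulate triage runs over a card deck and a team roster
#'
#' Every (team, card) pair yields one run. The assigned category is drawn
#' from the error model's confusion-kernel row of the card's algorithm-implied
#' category; each lifesaving-intervention decision starts from the card's
#' gold flag and is flipped independently with probability `lsi_miss_prob`;
#' the elapsed time is drawn from the time model of the card's expected
#' (algorithm-implied) category.
#'
#' @param cards,teams tibbles from [generate_cards()] / [make_teams()] (or
#'   read from CSV).
#' @param error_model an [error_model()].
#' @param time_model a [time_model()].
#' @param seed integer seed.
#' @param algorithm the triage algorithm implying each card's expected
#'   category; defaults to the packaged ASAV reconstruction.
#' @return a runs tibble ([new_runs()]), one row per (team, card) pair.
#' @examples
#' cards <- generate_cards(10, seed = 1)
#' teams <- make_teams(3, seed = 2)
#' runs <- simulate_runs(cards, teams, identity_error_model(),
#'                       asav_time_model(), seed = 3)
#' nrow(runs)
#' @export
simulate_runs <- function(cards, teams, error_model, time_model, seed,
                          algorithm = asav_algorithm()) {
  if (!inherits(error_model, "error_model")) {
    stop("`error_model` must be built with error_model()", call. = FALSE)
  }
  if (!inherits(time_model, "time_model")) {
    stop("`time_model` must be built with time_model()", call. = FALSE)
  }
  seed <- check_seed(seed)
  implied <- classify_cards(cards, algorithm)
  card_info <- tibble::tibble(
    card_id = cards$card_id,
    implied = implied$assigned,
    gold_airway = cards$gold_airway_lsi,
    gold_bleeding = cards$gold_bleeding_lsi
  )
  grid <- tidyr::crossing(team_id = teams$team_id, card_id = cards$card_id) |>
    dplyr::left_join(card_info, by = "card_id")
  k <- error_model$confusion_kernel
  withr::with_seed(seed, {
    assigned <- purrr::map_chr(grid$implied, function(g) {
      sample(colnames(k), 1, prob = k[g, ])
    })
    n <- nrow(grid)
    flip_airway <- stats::runif(n) < error_model$lsi_miss_prob
    flip_bleeding <- stats::runif(n) < error_model$lsi_miss_prob
    elapsed <- sample_times(time_model, grid$implied)
    new_runs(
      card_id = grid$card_id,
      team_id = grid$team_id,
      assigned = assigned,
      airway_lsi = xor(grid$gold_airway, flip_airway),
      bleeding_lsi = xor(grid$gold_bleeding, flip_bleeding),
      elapsed_seconds = elapsed
    )
  })
}
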