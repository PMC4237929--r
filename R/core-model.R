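#' Triage categories
#'
#' The four primary-triage categories used throughout the package, always
#' serialised lowercase: `"red"` (immediate treatment and/or transport),
#' `"yellow"` (delayed treatment and transport), `"green"` (minor injuries)
#' and `"black"` (dead).
#'
#' An ordinal severity rank is defined only among green (1), yellow (2) and
#' red (3); black sits outside the ordinal scale and enters mis-triage scoring
#' only through the explicitly enumerated category pairs (see
#' [mistriage_rates()]).
#'
#' @return `triage_categories()` returns the four category names.
#'   `category_rank()` returns the ordinal rank of each category (`NA` for
#'   black).
#' @examples
#' triage_categories()
#' category_rank(c("green", "red", "black"))
#' @export
triage_categories <- function() {
  c("green", "yellow", "red", "black")
}

#' @param category character vector of category names.
#' @rdname triage_categories
#' @export
category_rank <- function(category) {
  assert_categories(category)
  unname(c(green = 1, yellow = 2, red = 3, black = NA_real_)[category])
}

assert_categories <- function(category, arg = "category") {
  bad <- setdiff(unique(category[!is.na(category)]), triage_categories())
  if (length(bad) > 0) {
    stop(sprintf(
      "`%s` contains unknown triage categories: %s",
      arg, paste(sQuote(bad), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(category)
}

qualification_levels <- function() c("paramedic", "emt", "other")

consciousness_levels <- function() c("alert", "responsive", "unconscious")

breathing_levels <- function() c("normal", "disorder", "apnoea")

death_sign_levels <- function() {
  c("none", "decapitation", "torso_destruction", "other_definite")
}

#' Default list of distinct breathing disorders
#'
#' The engine's single respiration step asks only whether any breathing
#' disorder (or apnoea) is present; the disorder labels themselves are
#' free-form descriptors attached to casualty cards. This default list is
#' configurable wherever cards are generated.
#'
#' @return character vector of disorder labels.
#' @export
breathing_disorder_labels <- function() {
  c("stridor", "gasping", "paradoxical_breathing", "severe_dyspnoea",
    "cyanotic_laboured_breathing")
}

#' Derive the vehicle-staffing class of a triage team
#'
#' Teams of two are classed by the minimal vehicle-staffing requirement their
#' qualifications satisfy: a paramedic team leader (any assistant) staffs a
#' mobile intensive care unit (`"micu"`); an EMT leader with an assistant of
#' the same or lower qualification staffs a patient transport ambulance
#' (`"patient_transport_ambulance"`); two members below EMT form a disaster
#' response team (`"disaster_response"`). Any other combination (an assistant
#' more qualified than the leader, e.g. EMT leader with paramedic assistant)
#' is `"excluded"` from staffing-class subgroup analyses.
#'
#' @param leader_qual,assistant_qual character vectors over
#'   `"paramedic"`, `"emt"`, `"other"`; recycled to a common length.
#' @return character vector of staffing classes.
#' @examples
#' derive_staffing_class("paramedic", "other")
#' derive_staffing_class("emt", "paramedic")
#' @export
derive_staffing_class <- function(leader_qual, assistant_qual) {
  for (q in list(leader_qual, assistant_qual)) {
    bad <- setdiff(unique(q), qualification_levels())
    if (length(bad) > 0) {
      stop(sprintf(
        "unknown qualification label(s): %s (expected one of %s)",
        paste(sQuote(bad), collapse = ", "),
        paste(sQuote(qualification_levels()), collapse = ", ")
      ), call. = FALSE)
    }
  }
  n <- max(length(leader_qual), length(assistant_qual))
  leader <- rep_len(leader_qual, n)
  assistant <- rep_len(assistant_qual, n)
  dplyr::case_when(
    leader == "paramedic" ~ "micu",
    leader == "emt" & assistant %in% c("emt", "other") ~
      "patient_transport_ambulance",
    leader == "other" & assistant == "other" ~ "disaster_response",
    .default = "excluded"
  )
}

#' Construct a casualty-card table
#'
#' A casualty card is the written stand-in for one mass-casualty-incident
#' victim: narrative fields (demographics, posture, injuries with body
#' locations), structured vital signs, a gold-standard accept-set of triage
#' categories fixed by consensus, and the two gold lifesaving-intervention
#' (LSI) flags — airway opening for unconscious patients and bleeding control
#' for spurting haemorrhage.
#'
#' `new_cards()` assembles a cards tibble from vectors and validates it;
#' [validate_cards()] reports invariant violations without raising.
#'
#' Multi-valued fields are serialised as `"|"`-joined strings: `gold_accept`
#' holds one or two lowercase category names (two only for the ambiguous
#' red-or-black card) and `breathing_disorder_tags` holds zero or more labels
#' (empty string when none; necessarily empty under apnoea).
#'
#' @param card_id unique card identifiers.
#' @param demographics,posture free-text card fields.
#' @param injuries free text, `"description (body location)"` entries joined
#'   by `"; "`.
#' @param can_walk,spurting_haemorrhage,radial_pulse_present,skin_abnormal
#'   logical vital signs.
#' @param consciousness one of `"alert"`, `"responsive"`, `"unconscious"`.
#' @param breathing one of `"normal"`, `"disorder"`, `"apnoea"`.
#' @param breathing_disorder_tags `"|"`-joined disorder labels (`""` if none).
#' @param pain_level integer 0-10.
#' @param death_signs one of `"none"`, `"decapitation"`,
#'   `"torso_destruction"`, `"other_definite"`.
#' @param gold_accept `"|"`-joined accept-set of categories.
#' @param gold_airway_lsi,gold_bleeding_lsi logical gold LSI indications.
#' @return a tibble with one row per card.
#' @seealso [validate_cards()], [generate_cards()], [read_cards()]
#' @export
new_cards <- function(card_id,
                      demographics = "",
                      posture = "",
                      injuries = "",
                      can_walk,
                      consciousness,
                      breathing,
                      breathing_disorder_tags = "",
                      spurting_haemorrhage,
                      radial_pulse_present,
                      skin_abnormal,
                      pain_level = 0L,
                      death_signs = "none",
                      gold_accept,
                      gold_airway_lsi = FALSE,
                      gold_bleeding_lsi = FALSE) {
  cards <- tibble::tibble(
    card_id = as.character(card_id),
    demographics = as.character(demographics),
    posture = as.character(posture),
    injuries = as.character(injuries),
    can_walk = as.logical(can_walk),
    consciousness = as.character(consciousness),
    breathing = as.character(breathing),
    breathing_disorder_tags = as.character(breathing_disorder_tags),
    spurting_haemorrhage = as.logical(spurting_haemorrhage),
    radial_pulse_present = as.logical(radial_pulse_present),
    skin_abnormal = as.logical(skin_abnormal),
    pain_level = as.integer(pain_level),
    death_signs = as.character(death_signs),
    gold_accept = as.character(gold_accept),
    gold_airway_lsi = as.logical(gold_airway_lsi),
    gold_bleeding_lsi = as.logical(gold_bleeding_lsi)
  )
  problems <- validate_cards(cards)
  if (nrow(problems) > 0) {
    stop(
      "invalid casualty cards:\n",
      paste(sprintf("  [%s] %s: %s", problems$card_id, problems$code,
                    problems$message), collapse = "\n"),
      call. = FALSE
    )
  }
  cards
}

card_columns <- function() {
  c("card_id", "demographics", "posture", "injuries", "can_walk",
    "consciousness", "breathing", "breathing_disorder_tags",
    "spurting_haemorrhage", "radial_pulse_present", "skin_abnormal",
    "pain_level", "death_signs", "gold_accept", "gold_airway_lsi",
    "gold_bleeding_lsi")
}

split_accept <- function(gold_accept) {
  strsplit(ifelse(is.na(gold_accept), "", gold_accept), "|", fixed = TRUE)
}

#' Validate casualty cards
#'
#' Checks every card invariant and returns the violations as a tibble rather
#' than raising: unique ids, closed enum fields, pain level in 0-10, a
#' non-empty accept-set of at most two categories where any two-category set
#' must be exactly red-or-black, no breathing-disorder tags under apnoea, and
#' a gold bleeding-control indication only in the presence of spurting
#' haemorrhage.
#'
#' @param cards a cards tibble (see [new_cards()]).
#' @return tibble with columns `card_id`, `code` (machine-readable violation
#'   code) and `message`; zero rows when all invariants hold.
#' @examples
#' cards <- generate_cards(8, seed = 1)
#' validate_cards(cards)
#' @export
validate_cards <- function(cards) {
  missing_cols <- setdiff(card_columns(), names(cards))
  if (length(missing_cols) > 0) {
    stop("cards table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  v <- list()
  add <- function(id, code, message) {
    tibble::tibble(card_id = id, code = code, message = message)
  }

  dup <- unique(cards$card_id[duplicated(cards$card_id)])
  if (length(dup) > 0) {
    v <- c(v, list(add(dup, "duplicate_id", "card_id is not unique")))
  }

  enum_checks <- list(
    consciousness = consciousness_levels(),
    breathing = breathing_levels(),
    death_signs = death_sign_levels()
  )
  for (col in names(enum_checks)) {
    bad <- !(cards[[col]] %in% enum_checks[[col]])
    if (any(bad)) {
      v <- c(v, list(add(
        cards$card_id[bad], paste0("bad_", col),
        sprintf("%s %s is not one of {%s}", col,
                sQuote(cards[[col]][bad]),
                paste(enum_checks[[col]], collapse = ", "))
      )))
    }
  }

  bad_pain <- is.na(cards$pain_level) | cards$pain_level < 0L |
    cards$pain_level > 10L
  if (any(bad_pain)) {
    v <- c(v, list(add(cards$card_id[bad_pain], "bad_pain_level",
                       "pain_level must be an integer in 0-10")))
  }

  accept <- split_accept(cards$gold_accept)
  n_accept <- lengths(accept)
  empty <- n_accept == 0
  if (any(empty)) {
    v <- c(v, list(add(cards$card_id[empty], "empty_accept_set",
                       "gold_accept must contain at least one category")))
  }
  unknown <- purrr::map_lgl(accept, ~ length(setdiff(.x, triage_categories())) > 0)
  if (any(unknown)) {
    v <- c(v, list(add(cards$card_id[unknown], "unknown_accept_category",
                       "gold_accept contains an unknown category name")))
  }
  bad_pair <- purrr::map_lgl(accept, function(a) {
    length(a) > 2 || (length(a) == 2 && !setequal(a, c("red", "black")))
  })
  if (any(bad_pair)) {
    v <- c(v, list(add(
      cards$card_id[bad_pair], "bad_accept_pair",
      "a multi-category accept-set must be exactly {red, black}"
    )))
  }

  apnoea_tags <- cards$breathing == "apnoea" &
    !is.na(cards$breathing_disorder_tags) & cards$breathing_disorder_tags != ""
  if (any(apnoea_tags)) {
    v <- c(v, list(add(cards$card_id[apnoea_tags], "tags_under_apnoea",
                       "breathing_disorder_tags must be empty under apnoea")))
  }

  bleed_no_haem <- cards$gold_bleeding_lsi & !cards$spurting_haemorrhage
  if (any(bleed_no_haem)) {
    v <- c(v, list(add(
      cards$card_id[bleed_no_haem], "bleeding_lsi_without_haemorrhage",
      "gold_bleeding_lsi requires spurting_haemorrhage"
    )))
  }

  if (length(v) == 0) {
    tibble::tibble(card_id = character(), code = character(),
                   message = character())
  } else {
    dplyr::bind_rows(v)
  }
}

#' Construct a triage-team table
#'
#' @param team_id unique team identifiers.
#' @param leader_qualification,assistant_qualification one of `"paramedic"`,
#'   `"emt"`, `"other"` per team member.
#' @param employment `"career"`, `"volunteer"` or `"mixed"` (heterogeneous
#'   teams, excluded from employment subgroup analyses).
#' @param prior_mstart_training `"yes"`, `"no"`, `"unknown"` or `"mixed"`.
#' @return tibble with one row per team; `staffing_class` is derived with
#'   [derive_staffing_class()] and never stored independently.
#' @seealso [make_teams()]
#' @export
new_teams <- function(team_id, leader_qualification, assistant_qualification,
                      employment = "career", prior_mstart_training = "unknown") {
  bad_emp <- setdiff(unique(employment), c("career", "volunteer", "mixed"))
  if (length(bad_emp) > 0) {
    stop("unknown employment value(s): ", paste(sQuote(bad_emp), collapse = ", "),
         call. = FALSE)
  }
  bad_tr <- setdiff(unique(prior_mstart_training),
                    c("yes", "no", "unknown", "mixed"))
  if (length(bad_tr) > 0) {
    stop("unknown prior_mstart_training value(s): ",
         paste(sQuote(bad_tr), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    team_id = as.character(team_id),
    leader_qualification = as.character(leader_qualification),
    assistant_qualification = as.character(assistant_qualification),
    employment = as.character(employment),
    prior_mstart_training = as.character(prior_mstart_training),
    staffing_class = derive_staffing_class(leader_qualification,
                                           assistant_qualification)
  )
}

#' Construct a triage-run table
#'
#' One row per triage event: the card triaged, the team, the assigned
#' category, the two lifesaving-intervention decisions, and the elapsed time
#' in seconds measured from arrival at the patient until reaching the next
#' patient (triage, tagging and walking included).
#'
#' @param card_id,team_id references into the cards and teams tables.
#' @param assigned assigned triage category (lowercase).
#' @param airway_lsi,bleeding_lsi logical LSI decisions made by the team.
#' @param elapsed_seconds non-negative elapsed time.
#' @return tibble with one row per run.
#' @export
new_runs <- function(card_id, team_id, assigned, airway_lsi, bleeding_lsi,
                     elapsed_seconds) {
  assert_categories(assigned, "assigned")
  if (any(elapsed_seconds < 0, na.rm = TRUE)) {
    stop("elapsed_seconds must be non-negative", call. = FALSE)
  }
  tibble::tibble(
    card_id = as.character(card_id),
    team_id = as.character(team_id),
    assigned = as.character(assigned),
    airway_lsi = as.logical(airway_lsi),
    bleeding_lsi = as.logical(bleeding_lsi),
    elapsed_seconds = as.numeric(elapsed_seconds)
  )
}
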