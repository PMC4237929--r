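#' Read and write the toolkit's CSV tables
#'
#' Cards, teams and runs are exchanged as plain CSV with one row per record.
#' Category names are serialised lowercase and accept-sets / breathing
#' disorder tags as `"|"`-joined strings, so a round trip through disk is an
#' identity on every field. `read_teams()` re-derives `staffing_class` from
#' the stored qualifications; the derived column is never persisted.
#'
#' @param path file path.
#' @param cards,teams,runs tibbles as produced by [new_cards()],
#'   [new_teams()] / [make_teams()] and [new_runs()] / [simulate_runs()].
#' @return the read functions return validated tibbles; the write functions
#'   return their input invisibly.
#' @name triage_io
NULL

#' @rdname triage_io
#' @export
read_cards <- function(path) {
  cards <- readr::read_csv(
    path,
    col_types = readr::cols(
      card_id = readr::col_character(),
      demographics = readr::col_character(),
      posture = readr::col_character(),
      injuries = readr::col_character(),
      can_walk = readr::col_logical(),
      consciousness = readr::col_character(),
      breathing = readr::col_character(),
      breathing_disorder_tags = readr::col_character(),
      spurting_haemorrhage = readr::col_logical(),
      radial_pulse_present = readr::col_logical(),
      skin_abnormal = readr::col_logical(),
      pain_level = readr::col_integer(),
      death_signs = readr::col_character(),
      gold_accept = readr::col_character(),
      gold_airway_lsi = readr::col_logical(),
      gold_bleeding_lsi = readr::col_logical()
    ),
    progress = FALSE
  )
  # empty strings survive as NA in readr; text fields are "" semantically
  text_cols <- c("demographics", "posture", "injuries",
                 "breathing_disorder_tags")
  cards <- dplyr::mutate(cards, dplyr::across(
    dplyr::all_of(text_cols), ~ dplyr::coalesce(.x, "")
  ))
  problems <- validate_cards(cards)
  if (nrow(problems) > 0) {
    stop("cards file ", path, " contains invalid cards (",
         nrow(problems), " violation(s)); run validate_cards() for details",
         call. = FALSE)
  }
  cards
}

#' @rdname triage_io
#' @export
write_cards <- function(cards, path) {
  readr::write_csv(cards[, card_columns()], path)
  invisible(cards)
}

#' @rdname triage_io
#' @export
read_teams <- function(path) {
  teams <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  new_teams(
    team_id = teams$team_id,
    leader_qualification = teams$leader_qualification,
    assistant_qualification = teams$assistant_qualification,
    employment = teams$employment,
    prior_mstart_training = teams$prior_mstart_training
  )
}

#' @rdname triage_io
#' @export
write_teams <- function(teams, path) {
  persisted <- c("team_id", "leader_qualification", "assistant_qualification",
                 "employment", "prior_mstart_training")
  readr::write_csv(teams[, persisted], path)
  invisible(teams)
}

#' @rdname triage_io
#' @export
read_runs <- function(path) {
  runs <- readr::read_csv(
    path,
    col_types = readr::cols(
      card_id = readr::col_character(),
      team_id = readr::col_character(),
      assigned = readr::col_character(),
      airway_lsi = readr::col_logical(),
      bleeding_lsi = readr::col_logical(),
      elapsed_seconds = readr::col_double()
    ),
    progress = FALSE
  )
  new_runs(runs$card_id, runs$team_id, runs$assigned, runs$airway_lsi,
           runs$bleeding_lsi, runs$elapsed_seconds)
}

#' @rdname triage_io
#' @export
write_runs <- function(runs, path) {
  cols <- c("card_id", "team_id", "assigned", "airway_lsi", "bleeding_lsi",
            "elapsed_seconds")
  readr::write_csv(runs[, cols], path)
  invisible(runs)
}
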