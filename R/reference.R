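#' Published test-performance summaries used for calibration
#'
#' The dummy-based ASAV evaluation study (780 triage runs by 76 providers)
#' published its test-performance criteria only as summary tables; the raw
#' run data were never deposited. These printed values are shipped as a
#' reference table because they are the natural calibration inputs for the
#' simulator and the inputs to the closed-form likelihood-ratio and
#' confidence-interval computations. They are observed human-rater outcomes:
#' the package can reproduce their internal identities, not re-derive them
#' from scratch.
#'
#' Rates are proportions in \[0, 1\]; likelihood ratios are ratios.
#'
#' @return long tibble with columns `subgroup`, `n`, `metric`, `value`.
#' @seealso [reference_times()]
#' @export
reference_performance <- function() {
  metrics <- c("correct_rate", "sensitivity", "specificity", "lr_pos",
               "lr_neg", "over_triage", "critical_over_triage",
               "under_triage", "critical_under_triage", "bleeding_lsi_rate",
               "airway_lsi_rate")
  cols <- list(
    whole_collective = list(780, c(.839, .874, .910, 9.7, 0.139,
                                   .064, .044, .097, .048, .931, .900)),
    micu = list(420, c(.852, .892, .896, 8.6, 0.121,
                       .069, .044, .097, .048, .924, .829)),
    patient_transport_ambulance = list(40, c(.900, 1.000, .923, 13.0, 0.000,
                                             .075, .050, .025, .000, .825, .850)),
    disaster_response = list(100, c(.880, .900, .956, 19.1, 0.105,
                                    .060, .020, .060, .050, .930, .840)),
    career = list(480, c(.843, .883, .902, 9.01, 0.130,
                         .063, .048, .094, .042, .908, .824)),
    volunteer = list(140, c(.879, .913, .954, 19.8, 0.091,
                            .064, .021, .057, .021, .921, .836)),
    training_yes = list(220, c(.886, .938, .907, 10.1, 0.068,
                               .068, .045, .045, .027, .895, .800)),
    training_no = list(160, c(.838, .868, .936, 13.6, 0.141,
                              .063, .031, .100, .063, .938, .831))
  )
  purrr::imap(cols, function(x, name) {
    tibble::tibble(subgroup = name, n = as.integer(x[[1]]), metric = metrics,
                   value = x[[2]])
  }) |>
    dplyr::bind_rows()
}

#' Published mean triage times by expected category
#'
#' Mean seconds of primary survey per patient (with 95% confidence
#' intervals) by the expected triage category of the casualty, as published
#' by the dummy-based evaluation: red and yellow patients take the longest,
#' green by far the least. These means calibrate [asav_time_model()] and
#' feed the incident-planning calculation.
#'
#' The whole-collective time distribution had mean 35.4 s (95% CI
#' 34.2-36.4) and median 35.0 s over 780 runs.
#'
#' @return tibble with columns `category`, `mean_seconds`, `conf.low`,
#'   `conf.high`.
#' @export
reference_times <- function() {
  tibble::tibble(
    category = c("red", "yellow", "green", "black"),
    mean_seconds = c(41.8, 38.9, 14.5, 28.8),
    conf.low = c(40.4, 37.1, 12.7, 24.4),
    conf.high = c(43.3, 40.7, 16.6, 34.0)
  )
}
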