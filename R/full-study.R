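#' Default configuration for an end-to-end simulated triage study
#'
#' The defaults emulate the published study conditions: a 40-card deck with
#' one ambiguous red-or-black card, a 38-team roster drawn from the study's
#' composition weights (two providers per team, 76 providers), an error
#' model calibrated to the published whole-collective mis-triage rates
#' (9.7% under-triage of which 4.8% critical; 6.4% over-triage of which
#' 4.4% critical) with a lifesaving-intervention error probability of 0.085
#' (between the published airway and bleeding error rates of 10.0% and
#' 6.9%), the published per-category time means, and the 20/20/60 planning
#' distribution.
#'
#' All stage seeds are derived from the single `seed` argument.
#'
#' @param seed master integer seed.
#' @return a named list understood by [run_full_study()].
#' @export
default_study_config <- function(seed = 1) {
  seed <- check_seed(seed)
  list(
    n_cards = 40,
    card_mix = c(red = 0.4, yellow = 0.3, green = 0.25, black = 0.05),
    include_ambiguous = TRUE,
    n_teams = 38,
    under_triage = 0.097,
    over_triage = 0.064,
    critical_under_triage = 0.048,
    critical_over_triage = 0.044,
    lsi_miss_prob = 0.085,
    time_means = c(red = 41.8, yellow = 38.9, green = 14.5, black = 28.8),
    planning_mix = c(red = 0.2, yellow = 0.2, green = 0.6, black = 0),
    seeds = list(cards = seed, teams = seed + 1L, runs = seed + 2L)
  )
}

#' Read a study configuration from YAML
#'
#' Values present in the file override the [default_study_config()]
#' defaults; `card_mix`, `time_means` and `planning_mix` may be given as
#' named mappings over red/yellow/green/black.
#'
#' @param path YAML file path.
#' @param seed master seed used for any stage seed the file does not set.
#' @return a configuration list.
#' @export
read_study_config <- function(path, seed = 1) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  config <- default_study_config(seed)
  for (key in names(user)) {
    value <- user[[key]]
    if (key %in% c("card_mix", "time_means", "planning_mix")) {
      value <- unlist(value)
    }
    if (key == "seeds") {
      config$seeds[names(value)] <- lapply(value, as.integer)
      next
    }
    config[[key]] <- value
  }
  config
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("study stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run a complete simulated triage study
#'
#' Chains every stage of the toolkit: generate a card deck and a team
#' roster, simulate the triage runs under the configured error and time
#' models, evaluate all test-performance criteria (overall and per
#' subgroup), summarise triage times (overall and by expected category,
#' with a one-way ANOVA across categories), and compute the planning mean.
#' The result is fully reproducible from the configuration and its seeds.
#'
#' @param config a configuration list ([default_study_config()],
#'   [read_study_config()]).
#' @param out_dir optional directory; when given, every table is written as
#'   CSV (`cards.csv`, `teams.csv`, `runs.csv`, `metrics.csv`,
#'   `subgroups.csv`, `time_summary.csv`, `time_by_category.csv`,
#'   `planning.csv`) plus a human-readable `summary.txt`.
#' @return (invisibly when writing, visibly otherwise) a list of class
#'   `triage_study` with elements `config`, `cards`, `teams`, `runs`,
#'   `metrics`, `subgroups`, `time_summary`, `time_by_category`,
#'   `time_anova`, `planning_mean_seconds`.
#' @examples
#' study <- run_full_study(default_study_config(seed = 7))
#' study$metrics
#' @export
run_full_study <- function(config = default_study_config(), out_dir = NULL) {
  mix <- validate_mix(config$card_mix)

  cards <- run_stage("generate_cards", generate_cards(
    n = config$n_cards, mix = mix,
    include_ambiguous = isTRUE(config$include_ambiguous),
    seed = config$seeds$cards
  ))
  teams <- run_stage("make_teams",
                     make_teams(config$n_teams, seed = config$seeds$teams))
  em <- run_stage("error_model", mistriage_error_model(
    under_triage = config$under_triage, over_triage = config$over_triage,
    mix = mix, lsi_miss_prob = config$lsi_miss_prob,
    critical_under_triage = config$critical_under_triage,
    critical_over_triage = config$critical_over_triage
  ))
  tm <- run_stage("time_model", time_model(means = config$time_means))
  runs <- run_stage("simulate_runs",
                    simulate_runs(cards, teams, em, tm,
                                  seed = config$seeds$runs))

  metrics <- run_stage("evaluate", metrics_report(runs, cards))
  subgroups <- run_stage("subgroup_report", dplyr::bind_rows(
    dplyr::mutate(subgroup_report(runs, cards, teams, "staffing_class"),
                  grouping = "staffing_class", .before = 1),
    dplyr::mutate(subgroup_report(runs, cards, teams, "employment"),
                  grouping = "employment", .before = 1),
    dplyr::mutate(subgroup_report(runs, cards, teams, "prior_training"),
                  grouping = "prior_training", .before = 1)
  ))

  implied <- classify_cards(cards)
  runs_cat <- dplyr::left_join(
    runs, tibble::tibble(card_id = implied$card_id, category = implied$assigned),
    by = "card_id"
  )
  time_summary <- run_stage("time_summary", summarize_times(runs$elapsed_seconds))
  time_by_category <- run_stage("time_by_category",
    runs_cat |>
      dplyr::group_by(.data$category) |>
      dplyr::group_modify(~ summarize_times(.x$elapsed_seconds)) |>
      dplyr::ungroup()
  )
  time_anova <- run_stage("time_anova",
                          anova_bonferroni(runs_cat, elapsed_seconds, category))
  pm <- run_stage("planning_mean",
                  planning_mean(config$planning_mix, time_model_means(tm)))

  study <- structure(
    list(config = config, cards = cards, teams = teams, runs = runs,
         metrics = metrics, subgroups = subgroups,
         time_summary = time_summary, time_by_category = time_by_category,
         time_anova = time_anova, planning_mean_seconds = pm),
    class = "triage_study"
  )

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_cards(cards, file.path(out_dir, "cards.csv"))
    write_teams(teams, file.path(out_dir, "teams.csv"))
    write_runs(runs, file.path(out_dir, "runs.csv"))
    readr::write_csv(metrics, file.path(out_dir, "metrics.csv"))
    readr::write_csv(subgroups, file.path(out_dir, "subgroups.csv"))
    readr::write_csv(time_summary, file.path(out_dir, "time_summary.csv"))
    readr::write_csv(time_by_category,
                     file.path(out_dir, "time_by_category.csv"))
    readr::write_csv(
      tibble::tibble(planning_mean_seconds = pm),
      file.path(out_dir, "planning.csv")
    )
    writeLines(utils::capture.output(print(study)),
               file.path(out_dir, "summary.txt"))
    return(invisible(study))
  }
  study
}

#' @export
print.triage_study <- function(x, ...) {
  cat("<triage_study>\n")
  cat(sprintf("  %d cards, %d teams, %d simulated runs\n",
              nrow(x$cards), nrow(x$teams), nrow(x$runs)))
  key <- dplyr::filter(x$metrics, .data$metric %in%
                         c("correct_rate", "sensitivity", "specificity",
                           "under_triage", "over_triage"))
  for (i in seq_len(nrow(key))) {
    cat(sprintf("  %-22s %6.3f (%.3f - %.3f)\n", key$metric[i],
                key$estimate[i], key$conf.low[i], key$conf.high[i]))
  }
  mean_row <- dplyr::filter(x$time_summary, .data$statistic == "mean")
  cat(sprintf("  mean triage time       %5.1f s (%.1f - %.1f)\n",
              mean_row$estimate, mean_row$conf.low, mean_row$conf.high))
  cat(sprintf("  planning mean          %5.2f s/patient\n",
              x$planning_mean_seconds))
  invisible(x)
}

#' Point-range plot of a test-performance report
#'
#' @param report a [metrics_report()] or [subgroup_report()] tibble.
#' @return a ggplot object; proportions only (likelihood ratios have no
#'   interval and their own scale).
#' @export
plot_metrics <- function(report) {
  props <- dplyr::filter(report, !.data$metric %in% c("lr_pos", "lr_neg"))
  p <- ggplot2::ggplot(props, ggplot2::aes(x = .data$estimate,
                                           y = .data$metric)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::scale_x_continuous(limits = c(0, 1),
                                labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = "rate (95% CI)", y = NULL,
                  title = "Triage test-performance criteria") +
    ggplot2::theme_minimal()
  if ("group" %in% names(props)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$group))
  }
  p
}
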