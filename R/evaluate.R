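#' Enumerated mis-triage category pairs
#'
#' Over- and under-triage are scored by explicit (gold, assigned) category
#' pairs rather than by an ordinal distance, because the black category has
#' no rank: over-triage is red instead of yellow, green or black, or yellow
#' instead of green; under-triage is yellow instead of red, green instead of
#' yellow or red, or black instead of red. Critical over-triage is any
#' non-critical patient declared red; critical under-triage is any red
#' patient not declared red. Mismatches in neither list (e.g. yellow on a
#' gold black) are tallied separately as "other".
#'
#' @return list of `c(gold, assigned)` pairs.
#' @keywords internal
#' @name mistriage_pairs
NULL

#' @rdname mistriage_pairs
over_triage_pairs <- function() {
  list(c("yellow", "red"), c("green", "red"), c("black", "red"),
       c("green", "yellow"))
}

#' @rdname mistriage_pairs
critical_over_pairs <- function() {
  list(c("yellow", "red"), c("green", "red"), c("black", "red"))
}

#' @rdname mistriage_pairs
under_triage_pairs <- function() {
  list(c("red", "yellow"), c("yellow", "green"), c("red", "green"),
       c("red", "black"))
}

#' @rdname mistriage_pairs
critical_under_pairs <- function() {
  list(c("red", "yellow"), c("red", "green"), c("red", "black"))
}

#' @rdname mistriage_pairs
other_mismatch_pairs <- function() {
  list(c("black", "yellow"), c("black", "green"), c("green", "black"),
       c("yellow", "black"))
}

resolve_gold <- function(runs, cards) {
  dangling <- setdiff(runs$card_id, cards$card_id)
  if (length(dangling) > 0) {
    stop("run(s) reference unknown card_id(s): ",
         paste(unique(dangling), collapse = ", "), call. = FALSE)
  }
  accept <- split_accept(cards$gold_accept)
  lookup <- tibble::tibble(
    card_id = cards$card_id,
    ambiguous = lengths(accept) > 1,
    gold = purrr::map_chr(accept, ~ .x[1]),
    accept = accept
  )
  dplyr::left_join(runs, lookup, by = "card_id")
}

#' Cross-tabulate triage runs against the standard solution
#'
#' Runs on unambiguous cards are tallied into a 4x4 gold-by-assigned count
#' matrix. Runs on multi-accept (red-or-black) cards are kept out of the
#' matrix and counted as `ambiguous_concordant` when the assigned category
#' lies in the accept-set, `ambiguous_discordant` otherwise.
#'
#' @param runs a runs tibble.
#' @param cards the card deck the runs refer to.
#' @return an object of class `triage_confusion` with fields `counts`
#'   (matrix, rows = gold, columns = assigned, order red/yellow/green/black),
#'   `ambiguous_concordant`, `ambiguous_discordant` and `n_total`.
#' @examples
#' cards <- generate_cards(10, seed = 1)
#' teams <- make_teams(4, seed = 2)
#' runs <- simulate_runs(cards, teams, identity_error_model(),
#'                       asav_time_model(), seed = 3)
#' build_confusion(runs, cards)
#' @export
build_confusion <- function(runs, cards) {
  scored <- resolve_gold(runs, cards)
  cats <- c("red", "yellow", "green", "black")
  unamb <- dplyr::filter(scored, !.data$ambiguous)
  counts <- table(factor(unamb$gold, levels = cats),
                  factor(unamb$assigned, levels = cats))
  counts <- matrix(as.integer(counts), 4, 4, dimnames = list(cats, cats))
  amb <- dplyr::filter(scored, .data$ambiguous)
  concordant <- sum(purrr::map2_lgl(amb$assigned, amb$accept, `%in%`))
  structure(
    list(
      counts = counts,
      ambiguous_concordant = as.integer(concordant),
      ambiguous_discordant = as.integer(nrow(amb) - concordant),
      n_total = nrow(scored)
    ),
    class = "triage_confusion"
  )
}

#' @export
print.triage_confusion <- function(x, ...) {
  cat("<triage_confusion> ", x$n_total, " runs\n", sep = "")
  print(x$counts)
  if (x$ambiguous_concordant + x$ambiguous_discordant > 0) {
    cat("multi-accept runs: ", x$ambiguous_concordant, " concordant, ",
        x$ambiguous_discordant, " discordant\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.triage_confusion <- function(x, ...) {
  long <- tibble::as_tibble(as.table(x$counts), .name_repair = "minimal")
  names(long) <- c("gold", "assigned", "n")
  long <- dplyr::mutate(long, gold = as.character(.data$gold),
                        assigned = as.character(.data$assigned),
                        n = as.integer(.data$n))
  dplyr::bind_rows(
    long,
    tibble::tibble(gold = "red|black",
                   assigned = c("concordant", "discordant"),
                   n = c(x$ambiguous_concordant, x$ambiguous_discordant))
  )
}

#' @export
autoplot.triage_confusion <- function(object, ...) {
  cats <- c("red", "yellow", "green", "black")
  long <- tibble::as_tibble(as.table(object$counts), .name_repair = "minimal")
  names(long) <- c("gold", "assigned", "n")
  long$gold <- factor(long$gold, levels = rev(cats))
  long$assigned <- factor(long$assigned, levels = cats)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$assigned, y = .data$gold,
                                     fill = .data$n)) +
    ggplot2::geom_tile(colour = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "#b2182b") +
    ggplot2::labs(x = "assigned category", y = "standard solution",
                  fill = "runs",
                  title = "Triage assignments vs standard solution") +
    ggplot2::theme_minimal()
}

#' Overall rate of correct triage
#'
#' Diagonal of the confusion matrix plus multi-accept concordant runs, over
#' all runs in scope.
#'
#' @param ct a [build_confusion()] result.
#' @return proportion in \[0, 1\].
#' @export
correct_rate <- function(ct) {
  if (ct$n_total == 0) stop("no runs: n_total is 0", call. = FALSE)
  (sum(diag(ct$counts)) + ct$ambiguous_concordant) / ct$n_total
}

#' Sensitivity and specificity for the red category
#'
#' Collapses the unambiguous part of the confusion table into a red-vs-rest
#' 2x2 table. Runs on multi-accept (red-or-black) cards carry no single gold
#' polarity and are excluded entirely.
#'
#' @param ct a [build_confusion()] result.
#' @return one-row tibble with `sensitivity`, `specificity`, and the class
#'   sizes `n_positive`, `n_negative`.
#' @export
red_sens_spec <- function(ct) {
  counts <- ct$counts
  tp <- counts["red", "red"]
  fn <- sum(counts["red", ]) - tp
  fp <- sum(counts[, "red"]) - tp
  tn <- sum(counts) - tp - fn - fp
  if (tp + fn == 0) stop("no gold-red runs: sensitivity undefined", call. = FALSE)
  if (tn + fp == 0) stop("no gold-non-red runs: specificity undefined",
                         call. = FALSE)
  tibble::tibble(
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    n_positive = as.integer(tp + fn),
    n_negative = as.integer(tn + fp)
  )
}

#' Positive and negative likelihood ratios
#'
#' `lr_pos = sensitivity / (1 - specificity)` and
#' `lr_neg = (1 - sensitivity) / specificity`. A perfect specificity yields
#' `lr_pos = Inf`; a zero specificity leaves `lr_neg` undefined (`NaN`).
#'
#' @param sensitivity,specificity proportions in \[0, 1\]; recycled to a
#'   common length.
#' @return tibble with columns `lr_pos` and `lr_neg`.
#' @examples
#' likelihood_ratios(0.874, 0.910)
#' @export
likelihood_ratios <- function(sensitivity, specificity) {
  if (any(sensitivity < 0 | sensitivity > 1, na.rm = TRUE) ||
      any(specificity < 0 | specificity > 1, na.rm = TRUE)) {
    stop("sensitivity and specificity must lie in [0, 1]", call. = FALSE)
  }
  n <- max(length(sensitivity), length(specificity))
  sens <- rep_len(sensitivity, n)
  spec <- rep_len(specificity, n)
  tibble::tibble(
    lr_pos = dplyr::if_else(spec == 1, Inf, sens / (1 - spec)),
    lr_neg = dplyr::if_else(spec == 0, NaN, (1 - sens) / spec)
  )
}

count_pairs <- function(scored, pairs) {
  unamb <- scored[!scored$ambiguous, ]
  sum(purrr::map_int(pairs, function(p) {
    sum(unamb$gold == p[1] & unamb$assigned == p[2])
  }))
}

#' Over- and under-triage rates
#'
#' Applies the enumerated category-pair definitions (see
#' [over_triage_pairs()]) to every run. Multi-accept concordant runs enter
#' no numerator; every rate's denominator is the total number of runs in
#' scope.
#'
#' @param runs,cards as for [build_confusion()].
#' @return one-row tibble with `over_triage`, `critical_over_triage`,
#'   `under_triage`, `critical_under_triage`, `other_mismatch` and `n`.
#' @export
mistriage_rates <- function(runs, cards) {
  scored <- resolve_gold(runs, cards)
  n <- nrow(scored)
  if (n == 0) stop("no runs: n_total is 0", call. = FALSE)
  tibble::tibble(
    over_triage = count_pairs(scored, over_triage_pairs()) / n,
    critical_over_triage = count_pairs(scored, critical_over_pairs()) / n,
    under_triage = count_pairs(scored, under_triage_pairs()) / n,
    critical_under_triage = count_pairs(scored, critical_under_pairs()) / n,
    other_mismatch = count_pairs(scored, other_mismatch_pairs()) / n,
    n = n
  )
}

#' Accuracy of lifesaving-intervention decisions
#'
#' Per intervention, the proportion of runs whose indicated flag equals the
#' card's gold flag; correctly withholding an intervention counts as
#' correct.
#'
#' @param runs,cards as for [build_confusion()].
#' @return one-row tibble with `bleeding_lsi_rate`, `airway_lsi_rate`, `n`.
#' @export
lsi_accuracy <- function(runs, cards) {
  dangling <- setdiff(runs$card_id, cards$card_id)
  if (length(dangling) > 0) {
    stop("run(s) reference unknown card_id(s): ",
         paste(unique(dangling), collapse = ", "), call. = FALSE)
  }
  gold <- cards[, c("card_id", "gold_airway_lsi", "gold_bleeding_lsi")]
  scored <- dplyr::left_join(runs, gold, by = "card_id")
  n <- nrow(scored)
  if (n == 0) stop("no runs: n_total is 0", call. = FALSE)
  tibble::tibble(
    bleeding_lsi_rate = mean(scored$bleeding_lsi == scored$gold_bleeding_lsi),
    airway_lsi_rate = mean(scored$airway_lsi == scored$gold_airway_lsi),
    n = n
  )
}

#' Wald confidence interval for a proportion
#'
#' `p_hat +/- z * sqrt(p_hat (1 - p_hat) / n)`, clipped to \[0, 1\], with
#' `z` the standard-normal quantile at the requested level. No continuity
#' correction is applied.
#'
#' @param p_hat observed proportion(s) in \[0, 1\].
#' @param n sample size(s), at least 1.
#' @param level confidence level in (0, 1).
#' @return tibble with columns `lower` and `upper`.
#' @examples
#' wald_ci(0.839, 780)
#' @export
wald_ci <- function(p_hat, n, level = 0.95) {
  if (length(level) != 1 || is.na(level) || level <= 0 || level >= 1) {
    stop("`level` must be a single value in (0, 1)", call. = FALSE)
  }
  if (any(p_hat < 0 | p_hat > 1, na.rm = TRUE)) {
    stop("`p_hat` must lie in [0, 1]", call. = FALSE)
  }
  if (any(n < 1, na.rm = TRUE)) stop("`n` must be at least 1", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(p_hat * (1 - p_hat) / n)
  tibble::tibble(
    lower = pmax(0, p_hat - half),
    upper = pmin(1, p_hat + half)
  )
}

#' Full test-performance report for a set of triage runs
#'
#' Computes every test-performance criterion from a run table: correct
#' triage rate, red-category sensitivity and specificity, likelihood ratios,
#' the four mis-triage rates, and the two lifesaving-intervention accuracy
#' rates. Proportions carry Wald confidence intervals (sensitivity and
#' specificity over their own class sizes, all whole-collective rates over
#' the total run count); likelihood ratios are reported without intervals.
#'
#' @param runs,cards as for [build_confusion()].
#' @param level confidence level for the intervals.
#' @return tibble with columns `metric`, `estimate`, `conf.low`,
#'   `conf.high`, `n`.
#' @examples
#' cards <- generate_cards(20, seed = 1)
#' teams <- make_teams(5, seed = 2)
#' runs <- simulate_runs(cards, teams, mistriage_error_model(0.10, 0.06),
#'                       asav_time_model(), seed = 3)
#' metrics_report(runs, cards)
#' @export
metrics_report <- function(runs, cards, level = 0.95) {
  ct <- build_confusion(runs, cards)
  ss <- red_sens_spec(ct)
  lr <- likelihood_ratios(ss$sensitivity, ss$specificity)
  mt <- mistriage_rates(runs, cards)
  lsi <- lsi_accuracy(runs, cards)

  est <- tibble::tibble(
    metric = c("correct_rate", "sensitivity", "specificity", "lr_pos",
               "lr_neg", "over_triage", "critical_over_triage",
               "under_triage", "critical_under_triage", "bleeding_lsi_rate",
               "airway_lsi_rate"),
    estimate = c(correct_rate(ct), ss$sensitivity, ss$specificity, lr$lr_pos,
                 lr$lr_neg, mt$over_triage, mt$critical_over_triage,
                 mt$under_triage, mt$critical_under_triage,
                 lsi$bleeding_lsi_rate, lsi$airway_lsi_rate),
    n = c(ct$n_total, ss$n_positive, ss$n_negative, NA_integer_, NA_integer_,
          rep(ct$n_total, 6))
  )
  ci <- wald_ci(
    p_hat = dplyr::if_else(is.na(est$n), NA_real_, est$estimate),
    n = dplyr::coalesce(est$n, 1L),
    level = level
  )
  dplyr::mutate(est, conf.low = ci$lower, conf.high = ci$upper,
                .after = "estimate")
}

#' Test-performance report by provider subgroup
#'
#' Joins runs to their teams and produces one [metrics_report()] per
#' subgroup. Grouping follows the study's homogeneity rules: for
#' `employment` and `prior_training`, runs from heterogeneous teams
#' (`"mixed"`, and `"unknown"` training) are excluded; for `staffing_class`,
#' runs from teams whose qualification combination fits no vehicle staffing
#' class (`"excluded"`) are dropped. A subgroup left empty after filtering
#' is omitted with a message, not an error.
#'
#' @param runs,cards as for [build_confusion()].
#' @param teams the team roster the runs refer to.
#' @param grouping one of `"staffing_class"`, `"employment"`,
#'   `"prior_training"`.
#' @param level confidence level.
#' @return tibble: the [metrics_report()] columns preceded by a `group`
#'   column.
#' @export
subgroup_report <- function(runs, cards, teams,
                            grouping = c("staffing_class", "employment",
                                         "prior_training"),
                            level = 0.95) {
  grouping <- match.arg(grouping)
  dangling <- setdiff(runs$team_id, teams$team_id)
  if (length(dangling) > 0) {
    stop("run(s) reference unknown team_id(s): ",
         paste(unique(dangling), collapse = ", "), call. = FALSE)
  }
  col <- switch(grouping,
    staffing_class = "staffing_class",
    employment = "employment",
    prior_training = "prior_mstart_training"
  )
  drop_values <- switch(grouping,
    staffing_class = "excluded",
    employment = "mixed",
    prior_training = c("mixed", "unknown")
  )
  scoped <- runs |>
    dplyr::left_join(teams[, c("team_id", col)], by = "team_id") |>
    dplyr::rename(group = dplyr::all_of(col)) |>
    dplyr::filter(!.data$group %in% drop_values)
  groups <- split(scoped, scoped$group)
  reports <- purrr::imap(groups, function(g, name) {
    if (nrow(g) == 0) {
      message("subgroup ", sQuote(name), " is empty after filtering; omitted")
      return(NULL)
    }
    dplyr::mutate(metrics_report(g, cards, level = level), group = name,
                  .before = 1)
  })
  dplyr::bind_rows(reports)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
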