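#' Casualty-mix proportions for incident planning
#'
#' A planning mix gives the expected share of each triage category in a
#' casualty load, e.g. the 20% red / 20% yellow / 60% green distribution
#' commonly assumed for incident planning.
#'
#' @param red,yellow,green,black proportions in \[0, 1\], summing to 1
#'   within 1e-9.
#' @return named numeric vector over red, yellow, green, black.
#' @examples
#' planning_mix(0.2, 0.2, 0.6, 0)
#' @export
planning_mix <- function(red, yellow, green, black = 0) {
  validate_mix(c(red = red, yellow = yellow, green = green, black = black))
}

validate_mix <- function(mix) {
  cats <- c("red", "yellow", "green", "black")
  if (is.null(names(mix))) {
    if (length(mix) != 4) {
      stop("an unnamed mix must have 4 entries (red, yellow, green, black)",
           call. = FALSE)
    }
    names(mix) <- cats
  }
  missing_cats <- setdiff(cats, names(mix))
  mix <- c(mix, stats::setNames(rep(0, length(missing_cats)), missing_cats))
  mix <- mix[cats]
  if (any(mix < 0 | mix > 1)) {
    stop("mix proportions must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(mix) - 1) > 1e-9) {
    stop("mix proportions must sum to 1 (within 1e-9), got ", sum(mix),
         call. = FALSE)
  }
  mix
}

#' Summary statistics for triage times
#'
#' Mean (with t-distribution confidence interval), minimum, maximum, and the
#' 25th/50th/75th/90th/95th percentiles with distribution-free
#' order-statistic confidence intervals. Percentile point estimates use
#' linear interpolation between order statistics (type-7 quantiles); the
#' interval for the p-th percentile is \[x(l), x(u)\] with ranks
#' `l = qbinom(alpha/2, n, p)` (at least 1) and
#' `u = qbinom(1 - alpha/2, n, p) + 1` (at most n).
#'
#' @param times numeric vector of non-negative seconds, length >= 2.
#' @param level confidence level.
#' @return tibble with columns `statistic`, `estimate`, `conf.low`,
#'   `conf.high` and `n` (min and max carry no interval).
#' @examples
#' summarize_times(c(10, 20, 30, 40))
#' @export
summarize_times <- function(times, level = 0.95) {
  times <- as.numeric(times)
  if (length(times) < 2) {
    stop("at least 2 observations are required", call. = FALSE)
  }
  if (anyNA(times) || any(times < 0)) {
    stop("`times` must be non-negative and free of missing values",
         call. = FALSE)
  }
  n <- length(times)
  alpha <- 1 - level
  m <- mean(times)
  half <- stats::qt(1 - alpha / 2, df = n - 1) * stats::sd(times) / sqrt(n)

  sorted <- sort(times)
  probs <- c(0.25, 0.50, 0.75, 0.90, 0.95)
  qs <- stats::quantile(times, probs, type = 7, names = FALSE)
  lo_rank <- pmax(1L, stats::qbinom(alpha / 2, n, probs))
  hi_rank <- pmin(n, stats::qbinom(1 - alpha / 2, n, probs) + 1L)

  tibble::tibble(
    statistic = c("mean", "min", "p25", "median", "p75", "p90", "p95", "max"),
    estimate = c(m, min(times), qs, max(times)),
    conf.low = c(m - half, NA, sorted[lo_rank], NA),
    conf.high = c(m + half, NA, sorted[hi_rank], NA),
    n = n
  )
}

#' One-way ANOVA with Bonferroni post-hoc comparisons
#'
#' Classical one-way analysis of variance on (possibly unbalanced) groups,
#' followed by all pairwise comparisons using pooled-variance t tests with
#' Bonferroni-adjusted p values — the conventional post-hoc procedure of
#' desktop statistics packages. The 0.05 significance threshold is a
#' reporting convention, not baked into the returned values.
#'
#' @param data a data frame.
#' @param value column of measurements (tidy-eval).
#' @param group column naming the groups (tidy-eval).
#' @return an object of class `triage_anova`; see [tidy.triage_anova()] for
#'   the pairwise table and [glance.triage_anova()] for the omnibus test.
#' @examples
#' df <- data.frame(t = c(5, 6, 7, 9, 10, 11), g = rep(c("a", "b"), each = 3))
#' fit <- anova_bonferroni(df, t, g)
#' glance(fit)
#' tidy(fit)
#' @export
anova_bonferroni <- function(data, value, group) {
  values <- dplyr::pull(data, {{ value }})
  groups <- as.character(dplyr::pull(data, {{ group }}))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- groups[keep]
  sizes <- table(groups)
  if (length(sizes) < 2) stop("at least 2 groups are required", call. = FALSE)
  if (any(sizes < 2)) {
    stop("every group needs at least 2 observations; too small: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }

  fit <- stats::aov(values ~ factor(groups))
  tab <- summary(fit)[[1]]
  pw <- stats::pairwise.t.test(values, groups, p.adjust.method = "bonferroni",
                               pool.sd = TRUE)
  pw_long <- tibble::as_tibble(as.table(pw$p.value), .name_repair = "minimal")
  names(pw_long) <- c("group1", "group2", "p.adj")
  pw_long <- dplyr::filter(pw_long, !is.na(.data$p.adj))

  structure(
    list(
      f_statistic = tab[["F value"]][1],
      df_between = tab[["Df"]][1],
      df_within = tab[["Df"]][2],
      p_value = tab[["Pr(>F)"]][1],
      pairwise = pw_long,
      group_summary = tibble::tibble(
        group = names(sizes),
        n = as.integer(sizes),
        mean = purrr::map_dbl(names(sizes), ~ mean(values[groups == .x]))
      )
    ),
    class = "triage_anova"
  )
}

#' @export
print.triage_anova <- function(x, ...) {
  cat(sprintf("<triage_anova> F(%d, %d) = %.3f, p = %.4g\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value))
  cat("Bonferroni-adjusted pairwise comparisons:\n")
  print(x$pairwise)
  invisible(x)
}

#' @rdname anova_bonferroni
#' @param x,.x a `triage_anova` object.
#' @param ... unused.
#' @export
tidy.triage_anova <- function(x, ...) {
  x$pairwise
}

#' @rdname anova_bonferroni
#' @export
glance.triage_anova <- function(x, ...) {
  tibble::tibble(
    statistic = x$f_statistic,
    df = x$df_between,
    df.residual = x$df_within,
    p.value = x$p_value,
    n.groups = nrow(x$group_summary)
  )
}

#' Casualty-mix-weighted mean triage time
#'
#' Expected seconds of primary triage per patient under a planning mix:
#' the mix-weighted average of the per-category mean times,
#' `sum_c p_c * mean_c`. With the published category means and the
#' conventional 20/20/60 red/yellow/green planning distribution this is the
#' "about 25 seconds per patient" figure used for incident planning.
#'
#' @param mix a [planning_mix()].
#' @param category_means named seconds per category; categories with zero
#'   mix proportion may be missing or `NA`.
#' @return expected seconds per patient (scalar).
#' @examples
#' planning_mean(planning_mix(0.2, 0.2, 0.6, 0),
#'               c(red = 41.8, yellow = 38.9, green = 14.5, black = 28.8))
#' @export
planning_mean <- function(mix, category_means) {
  mix <- validate_mix(mix)
  cats <- names(mix)
  means <- category_means[cats]
  names(means) <- cats
  active <- cats[mix > 0]
  if (anyNA(means[active])) {
    stop("missing mean time for weighted categor(ies): ",
         paste(active[is.na(means[active])], collapse = ", "), call. = FALSE)
  }
  sum(mix[active] * means[active])
}

#' Monte Carlo scene-completion time for a planned incident
#'
#' Simulates the primary triage of `n_patients` casualties by `n_teams`
#' teams working in parallel: casualties are allocated to categories by
#' largest-remainder quota on `mix`, shuffled, dealt round-robin to the
#' teams, and each patient's triage time is drawn from the time model of
#' their category. A replicate's completion time is the slowest team's total.
#'
#' @param n_patients,n_teams positive integers.
#' @param mix a [planning_mix()].
#' @param time_model a [time_model()].
#' @param replicates number of Monte Carlo replicates.
#' @param seed integer seed.
#' @return tibble of class `incident_sim` with one row per replicate:
#'   `replicate`, `completion_seconds`, `total_seconds` (summed over teams)
#'   and `mean_seconds_per_patient`.
#' @examples
#' sim <- simulate_incident(50, 5, planning_mix(0.2, 0.2, 0.6, 0),
#'                          asav_time_model(), replicates = 100, seed = 7)
#' summary(sim$completion_seconds)
#' @export
simulate_incident <- function(n_patients, n_teams, mix, time_model,
                              replicates = 1000, seed) {
  if (n_patients < 1 || n_teams < 1 || replicates < 1) {
    stop("n_patients, n_teams and replicates must be positive", call. = FALSE)
  }
  mix <- validate_mix(mix)
  seed <- check_seed(seed)
  if (!inherits(time_model, "time_model")) {
    stop("`time_model` must be built with time_model()", call. = FALSE)
  }
  quota <- largest_remainder(n_patients, mix)
  categories <- rep(names(quota), quota)
  team_of <- rep_len(seq_len(n_teams), n_patients)
  withr::with_seed(seed, {
    res <- purrr::map(seq_len(replicates), function(r) {
      cats <- sample(categories)
      t_i <- sample_times(time_model, cats)
      sums <- tapply(t_i, team_of, sum)
      c(completion = max(sums), total = sum(t_i))
    })
    completion <- purrr::map_dbl(res, "completion")
    total <- purrr::map_dbl(res, "total")
  })
  out <- tibble::tibble(
    replicate = seq_len(replicates),
    completion_seconds = completion,
    total_seconds = total,
    mean_seconds_per_patient = total / n_patients
  )
  class(out) <- c("incident_sim", class(out))
  attr(out, "n_patients") <- n_patients
  attr(out, "n_teams") <- n_teams
  out
}

#' @export
autoplot.incident_sim <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$completion_seconds)) +
    ggplot2::geom_histogram(bins = 30, fill = "#2166ac", colour = "white") +
    ggplot2::labs(
      x = "scene-completion time (s)", y = "replicates",
      title = sprintf("Completion of primary triage: %d patients, %d teams",
                      attr(object, "n_patients"), attr(object, "n_teams"))
    ) +
    ggplot2::theme_minimal()
}

#' Histogram of a simulated incident's completion times
#'
#' Convenience wrapper around [autoplot()] for [simulate_incident()] output.
#'
#' @param sim an `incident_sim` tibble.
#' @return a ggplot object.
#' @export
plot_incident_times <- function(sim) {
  autoplot(sim)
}
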