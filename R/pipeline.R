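#' Run the full overuse-and-review analysis pipeline
#'
#' Orchestrates load -> day aggregation -> overuse classification -> review
#' linkage -> exacerbation episodes -> peri-exacerbation windows ->
#' between-arm statistics, and (optionally) writes the report tables:
#' `table2_high.csv`, `table2_marked.csv`, `table2_extreme.csv` (one row
#' per reported outcome, both arms side by side), `comparisons.csv`,
#' `episodes.csv`, `window_profiles.csv`, `overuse_review.csv`,
#' `dose_dump_flags.csv` and `run_log.txt` with a config echo and row-count
#' provenance for every stage.
#'
#' Table cells are rendered at report precision (ratios to 2 decimals,
#' half-up; integer percentages); `comparisons.csv` retains full machine
#' precision.
#'
#' @param actuations,reviews,ocs,participants Paths or data frames, passed
#'   to [load_events()]; alternatively pass an `overuse_cohort` as
#'   `actuations`.
#' @param out_dir Output directory; `NULL` computes everything but writes
#'   nothing.
#' @param thresholds A [threshold_config()].
#' @param review_window_days,standdown_days Review-linkage parameters
#'   (defaults 1 and 7).
#' @param min_course_days,course_separation_days Episode construction
#'   parameters (defaults 3 and 7).
#' @param overlap_interval_days Minimum Day 0 spacing for window inclusion
#'   (default 28).
#' @param window_days Peri-exacerbation half-window (default 14).
#' @param dose_dump_threshold,dose_dump_window_hours Dose-dumping rule
#'   (defaults 100 actuations, 3 hours).
#' @param no_data_episodes Episode ids without monitor data, excluded from
#'   the window analysis.
#' @param tz Time zone for day boundaries.
#' @return Invisibly, a list with every intermediate and final product:
#'   `cohort`, `days`, `outcomes`, `summaries` (per level), `episodes`,
#'   `windows`, `profiles`, `dose_dumps`, `table2` (per level),
#'   `comparisons`, `log`.
#' @export
run_pipeline <- function(actuations, reviews = NULL, ocs = NULL,
                         participants = NULL, out_dir = NULL,
                         thresholds = threshold_config(),
                         review_window_days = 1L, standdown_days = 7L,
                         min_course_days = 3L, course_separation_days = 7L,
                         overlap_interval_days = 28L, window_days = 14L,
                         dose_dump_threshold = 100L, dose_dump_window_hours = 3,
                         no_data_episodes = NULL, tz = "UTC") {
  stopifnot(review_window_days >= 1L, standdown_days >= 1L,
            min_course_days >= 1L, course_separation_days >= 1L,
            overlap_interval_days >= 1L, window_days >= 1L,
            dose_dump_threshold >= 1L, dose_dump_window_hours > 0)
  log <- character()
  say <- function(...) {
    log <<- c(log, sprintf(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  say("reliefwatch pipeline")
  say("config: review window %d d after index; stand-down %d d; course >= %d d; course separation %d d; Day0 interval %d d; dose dump >= %d actuations / %s h; tz %s",
      review_window_days, standdown_days, min_course_days,
      course_separation_days, overlap_interval_days, dose_dump_threshold,
      format(dose_dump_window_hours), tz)
  say("thresholds: SMART total >%s, Standard salbutamol >%s (mode %s)",
      paste(thresholds$smart_total_thresholds, collapse = "/>"),
      paste(thresholds$standard_salbutamol_thresholds, collapse = "/>"),
      thresholds$smart_mode)

  cohort <- if (inherits(actuations, "overuse_cohort")) {
    actuations
  } else {
    stage("load", load_events(actuations, reviews, ocs, participants, tz = tz))
  }
  say("load: %d participants, %d actuations, %d reviews, %d ocs courses, %d rejected rows",
      nrow(cohort$participants), nrow(cohort$actuations),
      nrow(cohort$reviews), nrow(cohort$ocs), nrow(cohort$rejected))

  days <- stage("aggregate_days", aggregate_days(cohort))
  stopifnot(sum(days$bud_form_actuations) + sum(days$salbutamol_actuations) ==
              nrow(cohort$actuations))
  say("aggregate_days: %d day records (event total conserved)", nrow(days))

  days <- stage("classify_days", classify_days(days, thresholds))
  say("classify_days: %d high / %d marked / %d extreme use days",
      sum(days$high), sum(days$marked), sum(days$extreme))

  outcomes <- stage("review_linkage",
                    link_overuse_reviews(days, cohort,
                                         window_days = review_window_days,
                                         standdown_days = standdown_days))
  say("review_linkage: %d overuse days, %d counted as unreviewed",
      nrow(outcomes), sum(outcomes$counted_as_unreviewed))

  summaries <- lapply(stats::setNames(nm = c("HIGH", "MARKED", "EXTREME")),
                      function(lv) {
                        count_unreviewed_days(outcomes, lv,
                                              participants = cohort$participants)
                      })

  episodes <- stage("episodes", {
    ep <- build_episodes(cohort, min_course_days = min_course_days,
                         separation_days = course_separation_days)
    select_window_episodes(ep, min_interval_days = overlap_interval_days,
                           no_data_episodes = no_data_episodes)
  })
  say("episodes: %d severe exacerbations, %d included in window analysis",
      nrow(episodes), sum(episodes$included_in_window_analysis))

  windows <- stage("windows", extract_window(episodes, days,
                                             window_days = window_days))
  profiles <- stage("profiles", profile_medians(windows))
  dumps <- stage("dose_dumping",
                 detect_dose_dumping(cohort, threshold = dose_dump_threshold,
                                     window_hours = dose_dump_window_hours))
  say("windows: %d window rows; profiles: %d offsets; dose-dump flags: %d",
      nrow(windows), nrow(profiles), nrow(dumps))

  exposure <- stats::setNames(
    as.integer(cohort$participants$monitor_end -
                 cohort$participants$monitor_start) + 1L,
    cohort$participants$participant_id
  )
  table2 <- list()
  comparisons <- list()
  for (lv in c("HIGH", "MARKED", "EXTREME")) {
    t2 <- stage(paste0("table2_", tolower(lv)),
                build_table2(summaries[[lv]], exposure, lv))
    table2[[lv]] <- t2$table
    comparisons[[lv]] <- t2$comparisons
  }
  counts <- exacerbation_counts(episodes, cohort$participants)
  exa <- rate_ratio(counts$n[counts$arm == "SMART"],
                    exposure[counts$participant_id[counts$arm == "SMART"]],
                    counts$n[counts$arm == "STANDARD"],
                    exposure[counts$participant_id[counts$arm == "STANDARD"]])
  comparisons <- dplyr::bind_rows(
    dplyr::bind_rows(comparisons),
    as_comparison_row(exa, "severe_exacerbations")
  )
  say("stats: %d between-arm comparisons (exacerbation rate ratio %.3f)",
      nrow(comparisons), exa$estimate)

  result <- list(cohort = cohort, days = days, outcomes = outcomes,
                 summaries = summaries, episodes = episodes,
                 windows = windows, profiles = profiles, dose_dumps = dumps,
                 table2 = table2, comparisons = comparisons, log = log)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_csv(outcomes, file.path(out_dir, "overuse_review.csv"),
                     progress = FALSE)
    readr::write_csv(episodes, file.path(out_dir, "episodes.csv"),
                     progress = FALSE)
    readr::write_csv(profiles, file.path(out_dir, "window_profiles.csv"),
                     progress = FALSE)
    dumps_out <- dumps
    dumps_out$window_start <- format(dumps_out$window_start,
                                     "%Y-%m-%dT%H:%M:%S", tz = tz)
    dumps_out$window_end <- format(dumps_out$window_end,
                                   "%Y-%m-%dT%H:%M:%S", tz = tz)
    readr::write_csv(dumps_out, file.path(out_dir, "dose_dump_flags.csv"),
                     progress = FALSE)
    readr::write_csv(comparisons, file.path(out_dir, "comparisons.csv"),
                     progress = FALSE)
    for (lv in names(table2)) {
      readr::write_csv(table2[[lv]],
                       file.path(out_dir, paste0("table2_", tolower(lv), ".csv")),
                       progress = FALSE)
    }
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  invisible(result)
}

#' One overuse level's report table plus its between-arm comparisons
#' @noRd
build_table2 <- function(summary_tbl, exposure, level) {
  a <- summary_tbl[summary_tbl$arm == "SMART", , drop = FALSE]
  b <- summary_tbl[summary_tbl$arm == "STANDARD", , drop = FALSE]
  n_a <- nrow(a)
  n_b <- nrow(b)
  ge1_a <- sum(a$overuse_days > 0)
  ge1_b <- sum(b$overuse_days > 0)

  fmt2 <- function(x) sprintf("%.2f", round_half_up(x, 2))
  fmt1 <- function(x) sprintf("%.1f", round_half_up(x, 1))
  cell_mean_sd <- function(x) {
    if (!length(x)) return("-")
    sprintf("%s (%s)", fmt1(mean(x)), fmt1(sd0(x)))
  }
  cell_med_iqr <- function(x) {
    if (!length(x)) return("-")
    sprintf("%s (%s-%s)", format(quantile2(x, 0.5)),
            format(quantile2(x, 0.25)), format(quantile2(x, 0.75)))
  }
  cell_range <- function(x) {
    if (!length(x)) return("-")
    sprintf("%s-%s", format(min(x)), format(max(x)))
  }
  cell_prop2 <- function(x) {
    if (!length(x)) return("-")
    sprintf("%s (%s)", fmt2(mean(x)), fmt2(sd0(x)))
  }
  ci_cell <- function(cmp) {
    sprintf("%s (%s-%s)", fmt2(cmp$estimate), fmt2(cmp$ci_low),
            fmt2(cmp$ci_high))
  }

  risk <- relative_risk(ge1_a, n_a, ge1_b, n_b)
  rate_days <- rate_ratio(a$overuse_days, exposure[a$participant_id],
                          b$overuse_days, exposure[b$participant_id])
  rate_unrev <- rate_ratio(a$unreviewed_days, exposure[a$participant_id],
                           b$unreviewed_days, exposure[b$participant_id])

  a1 <- a[a$overuse_days > 0, , drop = FALSE]
  b1 <- b[b$overuse_days > 0, , drop = FALSE]
  lvl_label <- c(HIGH = "high use", MARKED = "marked overuse",
                 EXTREME = "extreme overuse")[[level]]

  tbl <- tibble::tibble(
    outcome = c(
      sprintf("At least one episode of %s", lvl_label),
      sprintf("Number of days of %s", lvl_label),
      sprintf("Number of days of %s in participants with at least one episode", lvl_label),
      sprintf("Number of days of %s without medical review within 48 h in participants with at least one episode", lvl_label),
      sprintf("Proportion of %s days without medical review within 48 h compared to total %s days", lvl_label, lvl_label)
    ),
    smart = c(
      sprintf("%d (%d%%)", ge1_a, round_half_up(100 * ge1_a / max(n_a, 1L))),
      paste(cell_mean_sd(a$overuse_days), cell_med_iqr(a$overuse_days),
            cell_range(a$overuse_days), sep = "; "),
      paste(cell_mean_sd(a1$overuse_days), cell_med_iqr(a1$overuse_days),
            cell_range(a1$overuse_days), sep = "; "),
      paste(cell_mean_sd(a1$unreviewed_days), cell_med_iqr(a1$unreviewed_days),
            cell_range(a1$unreviewed_days), sep = "; "),
      paste(cell_prop2(a1$proportion), cell_med_iqr(a1$proportion),
            cell_range(a1$proportion), sep = "; ")
    ),
    standard = c(
      sprintf("%d (%d%%)", ge1_b, round_half_up(100 * ge1_b / max(n_b, 1L))),
      paste(cell_mean_sd(b$overuse_days), cell_med_iqr(b$overuse_days),
            cell_range(b$overuse_days), sep = "; "),
      paste(cell_mean_sd(b1$overuse_days), cell_med_iqr(b1$overuse_days),
            cell_range(b1$overuse_days), sep = "; "),
      paste(cell_mean_sd(b1$unreviewed_days), cell_med_iqr(b1$unreviewed_days),
            cell_range(b1$unreviewed_days), sep = "; "),
      paste(cell_prop2(b1$proportion), cell_med_iqr(b1$proportion),
            cell_range(b1$proportion), sep = "; ")
    ),
    estimate = c(ci_cell(risk), ci_cell(rate_days), "-", ci_cell(rate_unrev), "-"),
    p_value = c(sprintf("%.3f", risk$p_value), sprintf("%.3f", rate_days$p_value),
                "-", sprintf("%.3f", rate_unrev$p_value), "-")
  )

  comparisons <- dplyr::bind_rows(
    as_comparison_row(risk, "at_least_one_episode", level),
    as_comparison_row(rate_days, "days_of_overuse", level),
    as_comparison_row(rate_unrev, "unreviewed_days", level)
  )
  list(table = tbl, comparisons = comparisons)
}
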