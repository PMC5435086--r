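#' Regimen-specific overuse thresholds
#'
#' Builds the per-day actuation thresholds that define high, marked and
#' extreme beta-agonist use. The action plans set the review-triggering
#' limit at >8 as-needed actuations beyond the four scheduled maintenance
#' doses for the single-inhaler (SMART) regimen and >16 salbutamol
#' actuations for the Standard regimen; marked and extreme use are 1.5x and
#' 2x those limits. All comparisons are strict (`>`), so a SMART day with
#' exactly 12 total budesonide/formoterol actuations is not a high-use day.
#'
#' For the SMART arm the default `smart_mode = "total"` applies the
#' thresholds to the day's *total* budesonide/formoterol actuations
#' (12/16/20, i.e. the excess thresholds plus the four scheduled doses),
#' which is well defined even when maintenance adherence is imperfect.
#' `smart_mode = "excess"` instead thresholds the total minus
#' `maintenance_actuations_per_day` against `smart_excess_thresholds`; with
#' the defaults the two modes coincide for day-level counts, but the excess
#' form is kept as an escape hatch for configurations with a different
#' scheduled maintenance load.
#'
#' Standard-arm classification deliberately uses salbutamol only: reliever
#' use of the maintenance budesonide/formoterol inhaler in that arm is not
#' counted towards overuse, which will undercount overuse for patients who
#' treat their maintenance inhaler as a reliever.
#'
#' @param smart_excess_thresholds Three strictly increasing integer cut-offs
#'   on SMART budesonide/formoterol actuations in excess of maintenance
#'   (default 8, 12, 16).
#' @param standard_salbutamol_thresholds Three strictly increasing integer
#'   cut-offs on Standard-arm salbutamol actuations (default 16, 24, 32).
#' @param maintenance_actuations_per_day Scheduled maintenance actuations
#'   per day (default 4: two actuations twice daily).
#' @param smart_mode `"total"` or `"excess"`; see Details.
#' @return A `threshold_config` object.
#' @examples
#' threshold_config()
#' @export
threshold_config <- function(smart_excess_thresholds = c(8L, 12L, 16L),
                             standard_salbutamol_thresholds = c(16L, 24L, 32L),
                             maintenance_actuations_per_day = 4L,
                             smart_mode = c("total", "excess")) {
  smart_mode <- match.arg(smart_mode)
  smart_excess_thresholds <- as.integer(smart_excess_thresholds)
  standard_salbutamol_thresholds <- as.integer(standard_salbutamol_thresholds)
  maintenance_actuations_per_day <- as.integer(maintenance_actuations_per_day)
  check_thresholds <- function(x, name) {
    if (length(x) != 3L || anyNA(x) || any(diff(x) <= 0L) || any(x < 0L)) {
      stop("`", name, "` must be three strictly increasing non-negative integers",
           call. = FALSE)
    }
  }
  check_thresholds(smart_excess_thresholds, "smart_excess_thresholds")
  check_thresholds(standard_salbutamol_thresholds, "standard_salbutamol_thresholds")
  if (maintenance_actuations_per_day < 0L) {
    stop("`maintenance_actuations_per_day` must be non-negative", call. = FALSE)
  }
  structure(
    list(
      smart_excess_thresholds = smart_excess_thresholds,
      smart_total_thresholds = smart_excess_thresholds + maintenance_actuations_per_day,
      standard_salbutamol_thresholds = standard_salbutamol_thresholds,
      maintenance_actuations_per_day = maintenance_actuations_per_day,
      smart_mode = smart_mode
    ),
    class = "threshold_config"
  )
}

#' @export
print.threshold_config <- function(x, ...) {
  cat("<threshold_config>\n")
  cat("  SMART total bud/form  (high/marked/extreme): >",
      paste(x$smart_total_thresholds, collapse = " / >"),
      sprintf(" [mode: %s]\n", x$smart_mode), sep = "")
  cat("  Standard salbutamol   (high/marked/extreme): >",
      paste(x$standard_salbutamol_thresholds, collapse = " / >"), "\n", sep = "")
  cat("  maintenance actuations/day:", x$maintenance_actuations_per_day, "\n")
  invisible(x)
}

#' Classify days of high, marked and extreme beta-agonist use
#'
#' Flags each day record at the three regimen-specific overuse levels.
#' Flags are cumulative: an extreme-use day is also a marked-use and a
#' high-use day, matching nested day-count reporting. `overuse_level` holds
#' the highest level attained (`"NONE"` when no threshold is exceeded).
#'
#' @param days Day records from [aggregate_days()] (columns
#'   `participant_id`, `arm`, `date`, `bud_form_actuations`,
#'   `salbutamol_actuations`).
#' @param config A [threshold_config()].
#' @return `days` with added logical columns `high`, `marked`, `extreme`
#'   and a character column `overuse_level`.
#' @examples
#' days <- tibble::tibble(
#'   participant_id = "P1", arm = "SMART",
#'   date = as.Date("2012-04-02") + 0:2,
#'   bud_form_actuations = c(12L, 13L, 21L), salbutamol_actuations = 0L
#' )
#' classify_days(days)[, c("date", "overuse_level")]
#' @export
classify_days <- function(days, config = threshold_config()) {
  stopifnot(inherits(config, "threshold_config"))
  req <- c("participant_id", "arm", "date",
           "bud_form_actuations", "salbutamol_actuations")
  missing_cols <- setdiff(req, names(days))
  if (length(missing_cols)) {
    stop("`days` is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(days$bud_form_actuations < 0L) || any(days$salbutamol_actuations < 0L)) {
    stop("actuation counts must be non-negative", call. = FALSE)
  }
  check_enum(days$arm, ARMS, "days", "arm")

  is_smart <- days$arm == "SMART"
  if (config$smart_mode == "total") {
    smart_x <- days$bud_form_actuations
    smart_cuts <- config$smart_total_thresholds
  } else {
    smart_x <- pmax(days$bud_form_actuations - config$maintenance_actuations_per_day, 0L)
    smart_cuts <- config$smart_excess_thresholds
  }
  x <- ifelse(is_smart, smart_x, days$salbutamol_actuations)
  cut1 <- ifelse(is_smart, smart_cuts[1L], config$standard_salbutamol_thresholds[1L])
  cut2 <- ifelse(is_smart, smart_cuts[2L], config$standard_salbutamol_thresholds[2L])
  cut3 <- ifelse(is_smart, smart_cuts[3L], config$standard_salbutamol_thresholds[3L])

  days$high <- x > cut1
  days$marked <- x > cut2
  days$extreme <- x > cut3
  days$overuse_level <- OVERUSE_LEVELS[1L + days$high + days$marked + days$extreme]
  days
}

#' Count overuse days per participant at a given level
#'
#' @param days Classified day records from [classify_days()].
#' @param level `"HIGH"`, `"MARKED"` or `"EXTREME"`. Because flags are
#'   cumulative, counting `"HIGH"` includes marked and extreme days.
#' @return A tibble with one row per participant present in `days`
#'   (participants with no overuse days report 0): `participant_id`, `arm`,
#'   `n_days`.
#' @export
count_overuse_days <- function(days, level = c("HIGH", "MARKED", "EXTREME")) {
  level <- match.arg(level)
  flag <- tolower(level)
  if (!flag %in% names(days)) {
    stop("`days` must be classified with classify_days() first", call. = FALSE)
  }
  days |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(arm = .data$arm[1L],
                     n_days = sum(.data[[flag]]),
                     .groups = "drop")
}
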