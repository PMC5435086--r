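#' Load and validate the four event tables of a monitored cohort
#'
#' Reads the actuation, medical-review, systemic-corticosteroid and
#' participant tables (as file paths or data frames), validates them against
#' the participant roster, and returns a cohort bundle ready for day-level
#' aggregation.
#'
#' Expected columns (headered delimited text, comma separator when read from
#' file):
#' * actuations: `participant_id, medication, timestamp` with medication one
#'   of `"BUD_FORM"`/`"SALBUTAMOL"` and ISO-8601 timestamps at 1-second
#'   resolution;
#' * reviews: `participant_id, date, setting` with setting one of
#'   `"PRIMARY_CARE"`, `"AFTER_HOURS"`, `"HOSPITAL"`;
#' * ocs: `participant_id, start_date, end_date` (one systemic
#'   corticosteroid course per row);
#' * participants: `participant_id, arm, monitor_start, monitor_end` with arm
#'   `"SMART"` or `"STANDARD"`.
#'
#' Structural violations (unknown participant ids, malformed timestamps,
#' salbutamol events recorded for a SMART-arm participant, inverted course
#' dates) are errors that name the offending rows. Actuations and reviews
#' whose date falls outside the participant's monitoring period are not
#' errors: they are dropped and reported row by row in the `rejected`
#' element of the returned bundle.
#'
#' @param actuations,reviews,ocs,participants Paths to CSV files or data
#'   frames with the columns described above.
#' @param tz Time zone in which actuation timestamps are interpreted and
#'   calendar days are cut (midnight to midnight). One study-local zone
#'   keeps the actuation stream commensurable with the date-based review
#'   and corticosteroid tables.
#' @return An object of class `overuse_cohort`: a list with elements
#'   `participants`, `actuations`, `reviews`, `ocs` (validated tibbles),
#'   `rejected` (per-row report of dropped out-of-period rows) and `tz`.
#' @examples
#' cohort <- load_events(
#'   actuations = data.frame(
#'     participant_id = "P1", medication = "BUD_FORM",
#'     timestamp = "2012-04-02 08:15:00"
#'   ),
#'   reviews = data.frame(
#'     participant_id = "P1", date = "2012-04-03", setting = "PRIMARY_CARE"
#'   ),
#'   ocs = data.frame(
#'     participant_id = character(), start_date = character(),
#'     end_date = character()
#'   ),
#'   participants = data.frame(
#'     participant_id = "P1", arm = "SMART",
#'     monitor_start = "2012-04-02", monitor_end = "2012-09-16"
#'   )
#' )
#' cohort
#' @export
load_events <- function(actuations, reviews, ocs, participants, tz = "UTC") {
  part <- read_table_arg(participants, "participants",
                         c("participant_id", "arm", "monitor_start", "monitor_end"))
  part$participant_id <- as.character(part$participant_id)
  part$arm <- as.character(part$arm)
  check_enum(part$arm, ARMS, "participants", "arm")
  part$monitor_start <- parse_date_col(part$monitor_start, "participants", "monitor_start")
  part$monitor_end <- parse_date_col(part$monitor_end, "participants", "monitor_end")
  if (anyDuplicated(part$participant_id)) {
    stop("duplicated participant_id in participant table: ",
         paste(unique(part$participant_id[duplicated(part$participant_id)]),
               collapse = ", "), call. = FALSE)
  }
  bad_span <- which(part$monitor_end < part$monitor_start)
  if (length(bad_span)) {
    stop("monitor_end precedes monitor_start for participant(s): ",
         paste(part$participant_id[bad_span], collapse = ", "), call. = FALSE)
  }

  act <- read_table_arg(actuations, "actuations",
                        c("participant_id", "medication", "timestamp"))
  act$participant_id <- as.character(act$participant_id)
  act$medication <- as.character(act$medication)
  check_enum(act$medication, MEDICATIONS, "actuations", "medication")
  check_known_ids(act$participant_id, part$participant_id, "actuations")
  act$timestamp <- parse_timestamp_col(act$timestamp, tz)

  ## Regimen invariant: a SMART participant carries no separate salbutamol
  ## inhaler, so salbutamol actuations cannot be valid for that arm.
  arm_of <- stats::setNames(part$arm, part$participant_id)
  smart_salb <- which(act$medication == "SALBUTAMOL" &
                        arm_of[act$participant_id] == "SMART")
  if (length(smart_salb)) {
    stop("rule violated: SALBUTAMOL events recorded for SMART-arm participant(s) ",
         paste(unique(act$participant_id[smart_salb]), collapse = ", "),
         " (rows ", paste(head(smart_salb, 10L), collapse = ", "), ")",
         call. = FALSE)
  }

  rev <- read_table_arg(reviews, "reviews",
                        c("participant_id", "date", "setting"))
  rev$participant_id <- as.character(rev$participant_id)
  rev$setting <- as.character(rev$setting)
  check_enum(rev$setting, REVIEW_SETTINGS, "reviews", "setting")
  check_known_ids(rev$participant_id, part$participant_id, "reviews")
  rev$date <- parse_date_col(rev$date, "reviews", "date")

  ocs_tbl <- read_table_arg(ocs, "ocs",
                            c("participant_id", "start_date", "end_date"))
  ocs_tbl$participant_id <- as.character(ocs_tbl$participant_id)
  check_known_ids(ocs_tbl$participant_id, part$participant_id, "ocs")
  ocs_tbl$start_date <- parse_date_col(ocs_tbl$start_date, "ocs", "start_date")
  ocs_tbl$end_date <- parse_date_col(ocs_tbl$end_date, "ocs", "end_date")
  bad_course <- which(ocs_tbl$end_date < ocs_tbl$start_date)
  if (length(bad_course)) {
    stop("ocs rows with end_date before start_date: ",
         paste(head(bad_course, 10L), collapse = ", "), call. = FALSE)
  }

  start_of <- stats::setNames(part$monitor_start, part$participant_id)
  end_of <- stats::setNames(part$monitor_end, part$participant_id)

  act_date <- as.Date(act$timestamp, tz = tz)
  act_out <- unname(act_date < start_of[act$participant_id] |
                      act_date > end_of[act$participant_id])
  rev_out <- unname(rev$date < start_of[rev$participant_id] |
                      rev$date > end_of[rev$participant_id])

  rejected <- dplyr::bind_rows(
    tibble::tibble(
      table = "actuations",
      row = which(act_out),
      participant_id = act$participant_id[act_out],
      value = format(act$timestamp[act_out], "%Y-%m-%d %H:%M:%S", tz = tz),
      reason = "timestamp outside monitoring period"
    ),
    tibble::tibble(
      table = "reviews",
      row = which(rev_out),
      participant_id = rev$participant_id[rev_out],
      value = format(rev$date[rev_out]),
      reason = "date outside monitoring period"
    )
  )
  if (nrow(rejected)) {
    message(nrow(rejected), " row(s) outside the monitoring period rejected (",
            sum(rejected$table == "actuations"), " actuations, ",
            sum(rejected$table == "reviews"), " reviews)")
  }

  structure(
    list(
      participants = tibble::as_tibble(part),
      actuations = tibble::as_tibble(act[!act_out, , drop = FALSE]),
      reviews = tibble::as_tibble(rev[!rev_out, , drop = FALSE]),
      ocs = tibble::as_tibble(ocs_tbl),
      rejected = rejected,
      tz = tz
    ),
    class = "overuse_cohort"
  )
}

#' @export
print.overuse_cohort <- function(x, ...) {
  cat("<overuse_cohort>\n")
  cat("  participants:", nrow(x$participants),
      sprintf("(%d SMART, %d STANDARD)",
              sum(x$participants$arm == "SMART"),
              sum(x$participants$arm == "STANDARD")), "\n")
  cat("  actuations:  ", nrow(x$actuations), "\n")
  cat("  reviews:     ", nrow(x$reviews), "\n")
  cat("  ocs courses: ", nrow(x$ocs), "\n")
  if (nrow(x$rejected)) cat("  rejected rows:", nrow(x$rejected), "\n")
  cat("  tz:          ", x$tz, "\n")
  invisible(x)
}

#' Aggregate actuation events into per-participant calendar-day records
#'
#' Produces one row per participant per calendar day of the monitoring
#' period, with the number of budesonide/formoterol and salbutamol
#' actuations whose timestamp falls on that day. Days without events are
#' explicit zero rows: downstream proportions need a day denominator.
#'
#' @param cohort An `overuse_cohort` from [load_events()].
#' @return A tibble with columns `participant_id`, `arm`, `date`,
#'   `bud_form_actuations`, `salbutamol_actuations`, sorted by participant
#'   and date; per-participant totals equal the validated event counts.
#' @export
aggregate_days <- function(cohort) {
  stopifnot(inherits(cohort, "overuse_cohort"))
  p <- cohort$participants
  ndays <- as.integer(p$monitor_end - p$monitor_start) + 1L
  grid <- tibble::tibble(
    participant_id = rep(p$participant_id, times = ndays),
    arm = rep(p$arm, times = ndays),
    date = rep(p$monitor_start, times = ndays) + (sequence(ndays) - 1L)
  )

  if (nrow(cohort$actuations)) {
    counts <- cohort$actuations |>
      dplyr::mutate(date = as.Date(.data$timestamp, tz = cohort$tz)) |>
      dplyr::count(.data$participant_id, .data$date, .data$medication) |>
      tidyr::pivot_wider(names_from = "medication", values_from = "n",
                         values_fill = 0L)
    for (med in MEDICATIONS) {
      if (!med %in% names(counts)) counts[[med]] <- 0L
    }
    grid <- dplyr::left_join(grid, counts,
                             by = c("participant_id", "date"))
    grid$BUD_FORM[is.na(grid$BUD_FORM)] <- 0L
    grid$SALBUTAMOL[is.na(grid$SALBUTAMOL)] <- 0L
  } else {
    grid$BUD_FORM <- 0L
    grid$SALBUTAMOL <- 0L
  }

  grid |>
    dplyr::rename(bud_form_actuations = "BUD_FORM",
                  salbutamol_actuations = "SALBUTAMOL") |>
    dplyr::arrange(.data$participant_id, .data$date)
}

## ---- internal helpers -------------------------------------------------

#' @noRd
read_table_arg <- function(x, what, required_cols) {
  tbl <- if (is.character(x) && length(x) == 1L) {
    readr::read_csv(x, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  } else if (is.data.frame(x)) {
    tibble::as_tibble(x)
  } else {
    stop("`", what, "` must be a file path or a data frame", call. = FALSE)
  }
  missing_cols <- setdiff(required_cols, names(tbl))
  if (length(missing_cols)) {
    stop(what, " table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tbl[required_cols]
}

#' @noRd
check_enum <- function(x, allowed, what, col) {
  bad <- which(!is.na(x) & !x %in% allowed)
  if (length(bad)) {
    stop(what, "$", col, " has invalid value(s) ",
         paste(unique(x[bad]), collapse = ", "),
         " (rows ", paste(head(bad, 10L), collapse = ", "), "); allowed: ",
         paste(allowed, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' @noRd
check_known_ids <- function(ids, known, what) {
  bad <- which(!ids %in% known)
  if (length(bad)) {
    stop("unknown participant id(s) in ", what, " table: ",
         paste(unique(ids[bad]), collapse = ", "),
         " (rows ", paste(head(bad, 10L), collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(ids)
}

#' Parse ISO-8601 date-times, reporting malformed rows by line number
#' @noRd
parse_timestamp_col <- function(x, tz) {
  if (inherits(x, "POSIXct")) {
    return(x)
  }
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = tz)
  remaining <- !is.na(x)
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")) {
    if (!any(remaining)) break
    parsed <- as.POSIXct(x[remaining], format = fmt, tz = tz)
    ok <- !is.na(parsed)
    out[which(remaining)[ok]] <- parsed[ok]
    remaining[remaining] <- !ok
  }
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    stop("malformed timestamp(s) in actuations table at line(s) ",
         paste(head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) sprintf(" (and %d more)", length(bad) - 10L),
         ": e.g. \"", x[bad[1L]], "\"", call. = FALSE)
  }
  if (anyNA(x)) {
    stop("missing timestamp(s) in actuations table at line(s) ",
         paste(head(which(is.na(x)), 10L), collapse = ", "), call. = FALSE)
  }
  out
}

#' @noRd
parse_date_col <- function(x, what, col) {
  if (inherits(x, "Date")) {
    if (anyNA(x)) {
      stop("missing ", col, " in ", what, " table at line(s) ",
           paste(head(which(is.na(x)), 10L), collapse = ", "), call. = FALSE)
    }
    return(x)
  }
  x <- as.character(x)
  out <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(is.na(out))
  if (length(bad)) {
    stop("malformed or missing ", col, " in ", what, " table at line(s) ",
         paste(head(bad, 10L), collapse = ", "),
         if (!anyNA(x)) paste0(": e.g. \"", x[bad[1L]], "\""),
         call. = FALSE)
  }
  out
}
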