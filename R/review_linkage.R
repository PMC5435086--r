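#' Was an index day followed by medical review within the 48-hour window?
#'
#' A day of overuse counts as reviewed when a medical-review attendance
#' falls on the index day itself or on the next calendar day ("within 1 to
#' 2 days" in action-plan terms). The same window is applied to both
#' regimens.
#'
#' @param index_dates Vector of index (overuse) dates.
#' @param review_dates Vector of the participant's review dates.
#' @param window_days Number of days after the index day still inside the
#'   window (default 1: index day or next day).
#' @return Logical vector along `index_dates`.
#' @examples
#' reviewed_within_window(as.Date("2012-04-06"),
#'                        as.Date(c("2012-04-07")))  # next day -> TRUE
#' @export
reviewed_within_window <- function(index_dates, review_dates, window_days = 1L) {
  if (!length(review_dates)) {
    return(rep(FALSE, length(index_dates)))
  }
  vapply(as.integer(as.Date(index_dates)), function(d) {
    any(as.integer(as.Date(review_dates)) >= d &
          as.integer(as.Date(review_dates)) <= d + window_days)
  }, logical(1L))
}

#' Build the stand-down ledger of protected dates
#'
#' After a medical review, overuse on the review day and in the 7 following
#' days is not counted as overuse without review (a "stand-down" period,
#' echoing the 7-day separation used to delimit severe exacerbations). A
#' further review during an open stand-down restarts the 7-day clock; since
#' every review date opens its own window, chained reviews extend
#' protection seamlessly. An overuse index day whose linked review happens
#' the *next* day is also protected, so the protected set is: the union of
#' `[r, r + standdown_days]` over all review dates `r`, plus every index
#' day with a review inside its 48-h window.
#'
#' A review more than `window_days` before an overuse day does not
#' retroactively excuse it except through its own still-open stand-down
#' window.
#'
#' @param review_dates The participant's review dates.
#' @param overuse_dates The participant's overuse (index) dates; used only
#'   to protect index days linked to a next-day review.
#' @param standdown_days Length of the stand-down tail after a review
#'   (default 7).
#' @param window_days Review window after an index day (default 1).
#' @return A `standdown_ledger` object with element `protected_dates`
#'   (sorted unique `Date`s).
#' @examples
#' led <- build_standdown_ledger(as.Date("2012-04-07"), as.Date("2012-04-06"))
#' led$protected_dates  # index day + review day + 7 days
#' @export
build_standdown_ledger <- function(review_dates, overuse_dates = as.Date(character()),
                                   standdown_days = 7L, window_days = 1L) {
  review_dates <- sort(unique(as.Date(review_dates)))
  overuse_dates <- sort(unique(as.Date(overuse_dates)))
  protected <- as.Date(integer(), origin = "1970-01-01")
  if (length(review_dates)) {
    protected <- review_dates[rep(seq_along(review_dates), each = standdown_days + 1L)] +
      rep(0:standdown_days, times = length(review_dates))
    if (length(overuse_dates)) {
      linked <- reviewed_within_window(overuse_dates, review_dates, window_days)
      protected <- c(protected, overuse_dates[linked])
    }
    protected <- sort(unique(protected))
  }
  structure(
    list(protected_dates = protected,
         review_dates = review_dates,
         standdown_days = standdown_days,
         window_days = window_days),
    class = "standdown_ledger"
  )
}

#' @export
print.standdown_ledger <- function(x, ...) {
  cat("<standdown_ledger> ", length(x$review_dates), " review(s), ",
      length(x$protected_dates), " protected date(s)\n", sep = "")
  invisible(x)
}

#' Link each overuse day to medical review under the stand-down rule
#'
#' For every day flagged at least high-use, determines whether a review
#' occurred within the 48-h window, whether the day sits inside a
#' stand-down protection window, and hence whether it is counted as
#' overuse without medical review:
#' `counted_as_unreviewed = !reviewed_within_48h & !in_standdown`.
#'
#' @param days Classified day records from [classify_days()].
#' @param reviews A review table (`participant_id`, `date`, ...) or an
#'   `overuse_cohort`, whose `reviews` element is used.
#' @param window_days,standdown_days See [build_standdown_ledger()].
#' @return A tibble with one row per overuse day: `participant_id`, `arm`,
#'   `date`, `overuse_level`, `high`, `marked`, `extreme`,
#'   `reviewed_within_48h`, `in_standdown`, `counted_as_unreviewed`.
#' @export
link_overuse_reviews <- function(days, reviews, window_days = 1L,
                                 standdown_days = 7L) {
  if (inherits(reviews, "overuse_cohort")) reviews <- reviews$reviews
  if (!"high" %in% names(days)) {
    stop("`days` must be classified with classify_days() first", call. = FALSE)
  }
  overuse <- days[days$high, , drop = FALSE]
  if (!nrow(overuse)) {
    return(tibble::tibble(
      participant_id = character(), arm = character(),
      date = as.Date(character()), overuse_level = character(),
      high = logical(), marked = logical(), extreme = logical(),
      reviewed_within_48h = logical(), in_standdown = logical(),
      counted_as_unreviewed = logical()
    ))
  }
  rev_by_pid <- split(as.Date(reviews$date), reviews$participant_id)
  pieces <- lapply(split(overuse, overuse$participant_id), function(od) {
    rv <- rev_by_pid[[od$participant_id[1L]]] %||% as.Date(character())
    st <- overuse_days_status(od$date, rv, window_days, standdown_days)
    od$reviewed_within_48h <- st$reviewed_within_48h
    od$in_standdown <- st$in_standdown
    od$counted_as_unreviewed <- st$counted_as_unreviewed
    od
  })
  out <- dplyr::bind_rows(pieces)
  keep <- c("participant_id", "arm", "date", "overuse_level",
            "high", "marked", "extreme",
            "reviewed_within_48h", "in_standdown", "counted_as_unreviewed")
  out <- out[, intersect(keep, names(out)), drop = FALSE]
  dplyr::arrange(out, .data$participant_id, .data$date)
}

#' Review status of a vector of overuse days for one participant
#'
#' Vector-level core of [link_overuse_reviews()]: given one participant's
#' overuse dates and review dates, applies the 48-h window and the
#' stand-down ledger and reports which days count as overuse without
#' medical review.
#'
#' @inheritParams build_standdown_ledger
#' @return A list with logical vectors (along `overuse_dates`)
#'   `reviewed_within_48h`, `in_standdown`, `counted_as_unreviewed`.
#' @export
overuse_days_status <- function(overuse_dates, review_dates,
                                window_days = 1L, standdown_days = 7L) {
  led <- build_standdown_ledger(review_dates, overuse_dates,
                                standdown_days = standdown_days,
                                window_days = window_days)
  reviewed <- reviewed_within_window(overuse_dates, review_dates, window_days)
  isd <- as.Date(overuse_dates) %in% led$protected_dates
  list(reviewed_within_48h = reviewed, in_standdown = isd,
       counted_as_unreviewed = !reviewed & !isd)
}

#' Per-participant unreviewed overuse-day counts and proportions
#'
#' Counts, at a given overuse level, the days counted as overuse without
#' medical review within 48 h, and the proportion relative to *all* overuse
#' days at that level (stand-down-protected days stay in the denominator).
#' The proportion is undefined (`NA`) for participants with no overuse day
#' at the level; such participants are excluded from cohort means.
#'
#' @param outcomes Per-overuse-day outcomes from [link_overuse_reviews()].
#' @param level `"HIGH"`, `"MARKED"` or `"EXTREME"`.
#' @param participants Optional participant table (or classified day
#'   records); when given, participants absent from `outcomes` are reported
#'   with zero counts.
#' @return A tibble: `participant_id`, `arm`, `overuse_days`,
#'   `unreviewed_days`, `proportion`.
#' @export
count_unreviewed_days <- function(outcomes, level = c("HIGH", "MARKED", "EXTREME"),
                                  participants = NULL) {
  level <- match.arg(level)
  flag <- tolower(level)
  out <- outcomes[outcomes[[flag]], , drop = FALSE] |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(arm = .data$arm[1L],
                     overuse_days = dplyr::n(),
                     unreviewed_days = sum(.data$counted_as_unreviewed),
                     .groups = "drop")
  if (!is.null(participants)) {
    roster <- dplyr::distinct(
      tibble::tibble(participant_id = participants$participant_id,
                     arm = participants$arm)
    )
    out <- dplyr::left_join(roster, out[setdiff(names(out), "arm")],
                            by = "participant_id")
    out$overuse_days[is.na(out$overuse_days)] <- 0L
    out$unreviewed_days[is.na(out$unreviewed_days)] <- 0L
  }
  out$proportion <- ifelse(out$overuse_days > 0,
                           out$unreviewed_days / out$overuse_days, NA_real_)
  dplyr::arrange(out, .data$participant_id)
}
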