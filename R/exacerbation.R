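#' Build severe-exacerbation episodes from corticosteroid course records
#'
#' A severe exacerbation is anchored by a systemic corticosteroid course of
#' at least `min_course_days` days (ATS/ERS criterion); Day 0 is the first
#' day of corticosteroid therapy. Courses separated by fewer than
#' `separation_days` days are treated as a single exacerbation: the gap is
#' measured from the last day of the earlier course to the first day of the
#' later course, and a merged episode keeps the earliest start as Day 0.
#' Courses shorter than `min_course_days` are dropped before merging.
#' Overlapping courses for one participant merge with a warning.
#'
#' @param ocs Corticosteroid course table (`participant_id`, `start_date`,
#'   `end_date`) or an `overuse_cohort`, whose `ocs` element is used.
#' @param min_course_days Minimum course length in days (default 3).
#' @param separation_days Minimum course gap, in days, for distinct
#'   episodes (default 7: a gap of exactly 7 days separates).
#' @return A tibble with one row per episode: `participant_id`,
#'   `episode_id`, `day0`, `course_start`, `course_end`, `n_courses`.
#' @examples
#' ocs <- data.frame(participant_id = "P1",
#'                   start_date = as.Date(c("2012-05-10", "2012-05-15")),
#'                   end_date = as.Date(c("2012-05-12", "2012-05-17")))
#' build_episodes(ocs)  # gap of 3 days: one merged episode, Day 0 = May 10
#' @export
build_episodes <- function(ocs, min_course_days = 3L, separation_days = 7L) {
  if (inherits(ocs, "overuse_cohort")) ocs <- ocs$ocs
  empty <- tibble::tibble(
    participant_id = character(), episode_id = character(),
    day0 = as.Date(character()), course_start = as.Date(character()),
    course_end = as.Date(character()), n_courses = integer()
  )
  if (!nrow(ocs)) return(empty)
  ocs <- tibble::tibble(
    participant_id = as.character(ocs$participant_id),
    start_date = as.Date(ocs$start_date),
    end_date = as.Date(ocs$end_date)
  )
  if (any(ocs$end_date < ocs$start_date)) {
    stop("ocs course with end_date before start_date", call. = FALSE)
  }
  ocs <- ocs[as.integer(ocs$end_date - ocs$start_date) + 1L >= min_course_days, ,
             drop = FALSE]
  if (!nrow(ocs)) return(empty)

  pieces <- lapply(split(ocs, ocs$participant_id), function(cc) {
    cc <- cc[order(cc$start_date, cc$end_date), , drop = FALSE]
    start <- cc$start_date[1L]
    end <- cc$end_date[1L]
    n <- 1L
    eps <- list()
    overlap <- FALSE
    for (i in seq_len(nrow(cc))[-1L]) {
      if (cc$start_date[i] <= end) {
        overlap <- TRUE
        end <- max(end, cc$end_date[i])
        n <- n + 1L
      } else if (as.integer(cc$start_date[i] - end) < separation_days) {
        end <- max(end, cc$end_date[i])
        n <- n + 1L
      } else {
        eps[[length(eps) + 1L]] <- list(start = start, end = end, n = n)
        start <- cc$start_date[i]
        end <- cc$end_date[i]
        n <- 1L
      }
    }
    eps[[length(eps) + 1L]] <- list(start = start, end = end, n = n)
    if (overlap) {
      warning("overlapping corticosteroid courses merged for participant ",
              cc$participant_id[1L], call. = FALSE)
    }
    tibble::tibble(
      participant_id = cc$participant_id[1L],
      episode_id = paste0(cc$participant_id[1L], "_E",
                          seq_along(eps)),
      day0 = as.Date(vapply(eps, function(e) as.character(e$start), character(1L))),
      course_start = as.Date(vapply(eps, function(e) as.character(e$start), character(1L))),
      course_end = as.Date(vapply(eps, function(e) as.character(e$end), character(1L))),
      n_courses = vapply(eps, function(e) e$n, integer(1L))
    )
  })
  dplyr::bind_rows(pieces) |>
    dplyr::arrange(.data$participant_id, .data$day0)
}

#' Flag which episodes enter the peri-exacerbation window analysis
#'
#' Repeat exacerbations whose Day 0 falls within `min_interval_days` of the
#' previous *included* episode's Day 0 (for the same participant) are
#' excluded from the window analysis to avoid overlapping data, but still
#' count as exacerbation events. A Day 0 interval of exactly
#' `min_interval_days` satisfies the minimum and is included. Episodes
#' listed in `no_data_episodes` (e.g. no recorded monitor data because a
#' non-study inhaler was used) are excluded with reason `no_monitor_data`
#' and do not anchor the interval rule.
#'
#' @param episodes Episodes from [build_episodes()].
#' @param min_interval_days Required Day 0 spacing (default 28).
#' @param no_data_episodes Character vector of `episode_id`s without
#'   recorded monitor data.
#' @return `episodes` with logical `included_in_window_analysis` and
#'   character `exclusion_reason` (`NA` when included).
#' @export
select_window_episodes <- function(episodes, min_interval_days = 28L,
                                   no_data_episodes = NULL) {
  if (!nrow(episodes)) {
    episodes$included_in_window_analysis <- logical()
    episodes$exclusion_reason <- character()
    return(episodes)
  }
  pieces <- lapply(split(episodes, episodes$participant_id), function(ep) {
    ep <- ep[order(ep$day0), , drop = FALSE]
    included <- logical(nrow(ep))
    reason <- rep(NA_character_, nrow(ep))
    last_day0 <- NULL
    for (i in seq_len(nrow(ep))) {
      if (ep$episode_id[i] %in% no_data_episodes) {
        reason[i] <- "no_monitor_data"
      } else if (!is.null(last_day0) &&
                 as.integer(ep$day0[i] - last_day0) < min_interval_days) {
        reason[i] <- "repeat_within_interval"
      } else {
        included[i] <- TRUE
        last_day0 <- ep$day0[i]
      }
    }
    ep$included_in_window_analysis <- included
    ep$exclusion_reason <- reason
    ep
  })
  dplyr::bind_rows(pieces) |>
    dplyr::arrange(.data$participant_id, .data$day0)
}

#' Extract the +/-14-day medication-use window around each episode
#'
#' Joins each episode to the participant's day records at offsets
#' `-window_days` to `+window_days` from Day 0. Offsets outside the
#' monitoring period are marked unobserved (`observed = FALSE`, counts
#' `NA`), not zero.
#'
#' @param episodes Episodes, normally after [select_window_episodes()].
#' @param day_records Day records from [aggregate_days()] (classification
#'   columns, if present, are carried along).
#' @param window_days Half-width of the window (default 14).
#' @return A tibble with one row per episode per offset: episode columns
#'   plus `offset`, `date`, `bud_form_actuations`, `salbutamol_actuations`,
#'   `observed`.
#' @export
extract_window <- function(episodes, day_records, window_days = 14L) {
  offsets <- seq(-window_days, window_days)
  n <- nrow(episodes)
  idx <- rep(seq_len(n), each = length(offsets))
  win <- tibble::tibble(
    episode_id = episodes$episode_id[idx],
    participant_id = episodes$participant_id[idx],
    offset = rep(offsets, times = n),
    date = rep(episodes$day0, each = length(offsets)) + rep(offsets, times = n)
  )
  if ("included_in_window_analysis" %in% names(episodes)) {
    win$included_in_window_analysis <- episodes$included_in_window_analysis[idx]
  }
  day_cols <- c("participant_id", "date", "arm",
                "bud_form_actuations", "salbutamol_actuations")
  win <- dplyr::left_join(win, day_records[, intersect(day_cols, names(day_records))],
                          by = c("participant_id", "date"))
  win$observed <- !is.na(win$bud_form_actuations)
  if ("arm" %in% names(win)) {
    arm_of <- day_records$arm[match(win$participant_id, day_records$participant_id)]
    win$arm <- arm_of
  }
  dplyr::arrange(win, .data$participant_id, .data$episode_id, .data$offset)
}

#' Median (IQR) medication-use profiles by offset
#'
#' Summarises the peri-exacerbation windows as per-offset medians and
#' interquartile ranges by arm and medication, over included episodes and
#' observed days only (offsets with no observed episode are absent from the
#' output, not zero). Quantiles average at discontinuities (type 2), so the
#' IQR of counts 2, 4, 6 is 2-6.
#'
#' @param windows Window rows from [extract_window()].
#' @return A tibble: `arm` (if available), `medication`, `offset`,
#'   `median`, `q1`, `q3`, `n`.
#' @export
profile_medians <- function(windows) {
  if ("included_in_window_analysis" %in% names(windows)) {
    windows <- windows[windows$included_in_window_analysis, , drop = FALSE]
  }
  long <- tidyr::pivot_longer(
    windows,
    cols = c("bud_form_actuations", "salbutamol_actuations"),
    names_to = "medication", values_to = "actuations"
  )
  long$medication <- ifelse(long$medication == "bud_form_actuations",
                            "BUD_FORM", "SALBUTAMOL")
  long <- long[long$observed, , drop = FALSE]
  grp <- intersect(c("arm", "medication", "offset"), names(long))
  long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      median = quantile2(.data$actuations, 0.5),
      q1 = quantile2(.data$actuations, 0.25),
      q3 = quantile2(.data$actuations, 0.75),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Detect dose dumping (>=100 actuations in a 3-hour period)
#'
#' Scans each participant's time-ordered actuation stream, per medication,
#' for any 3-hour window (anchored at an event, endpoints inclusive)
#' containing at least `threshold` actuations - the signature of a canister
#' being emptied rather than inhaled. Overlapping flagged windows coalesce
#' into a single flag spanning the events involved.
#'
#' @param actuations Actuation table (`participant_id`, `medication`,
#'   `timestamp`) or an `overuse_cohort`.
#' @param threshold Minimum actuations in the window (default 100).
#' @param window_hours Window length in hours (default 3).
#' @return A tibble: `participant_id`, `medication`, `window_start`,
#'   `window_end`, `actuation_count`.
#' @export
detect_dose_dumping <- function(actuations, threshold = 100L, window_hours = 3) {
  if (inherits(actuations, "overuse_cohort")) actuations <- actuations$actuations
  wsec <- window_hours * 3600
  empty <- tibble::tibble(
    participant_id = character(), medication = character(),
    window_start = as.POSIXct(character()), window_end = as.POSIXct(character()),
    actuation_count = integer()
  )
  if (!nrow(actuations)) return(empty)
  grp <- paste(actuations$participant_id, actuations$medication, sep = "\r")
  pieces <- lapply(split(seq_len(nrow(actuations)), grp), function(ix) {
    t <- sort(actuations$timestamp[ix])
    tn <- as.numeric(t)
    ## events in [t_i, t_i + wsec], via last index with tn <= tn_i + wsec
    last <- findInterval(tn + wsec, tn)
    cnt <- last - seq_along(tn) + 1L
    hit <- which(cnt >= threshold)
    if (!length(hit)) return(NULL)
    ## coalesce overlapping flagged spans [t_i, t_last(i)]
    s <- tn[hit]
    e <- tn[last[hit]]
    keep_s <- s[1L]
    keep_e <- e[1L]
    out_s <- numeric()
    out_e <- numeric()
    for (k in seq_along(hit)[-1L]) {
      if (s[k] <= keep_e) {
        keep_e <- max(keep_e, e[k])
      } else {
        out_s <- c(out_s, keep_s); out_e <- c(out_e, keep_e)
        keep_s <- s[k]; keep_e <- e[k]
      }
    }
    out_s <- c(out_s, keep_s); out_e <- c(out_e, keep_e)
    tibble::tibble(
      participant_id = actuations$participant_id[ix[1L]],
      medication = actuations$medication[ix[1L]],
      window_start = as.POSIXct(out_s, origin = "1970-01-01",
                                tz = attr(t, "tzone") %||% "UTC"),
      window_end = as.POSIXct(out_e, origin = "1970-01-01",
                              tz = attr(t, "tzone") %||% "UTC"),
      actuation_count = vapply(seq_along(out_s), function(j) {
        sum(tn >= out_s[j] & tn <= out_e[j])
      }, integer(1L))
    )
  })
  res <- dplyr::bind_rows(pieces)
  if (!nrow(res)) return(empty)
  dplyr::arrange(res, .data$participant_id, .data$medication, .data$window_start)
}

#' Overuse days in the 14 days before a severe exacerbation
#'
#' Counts the overuse days at a given level that fall in offsets -14 to -1
#' of any included episode (Day 0 itself is "post"), as a percentage of all
#' overuse days at that level in the supplied outcomes, and the fraction of
#' those pre-exacerbation overuse days that were counted as unreviewed.
#' Filter `outcomes` to one arm to obtain arm-specific percentages.
#'
#' @param episodes Episodes after [select_window_episodes()].
#' @param outcomes Per-overuse-day outcomes from [link_overuse_reviews()].
#' @param level `"HIGH"`, `"MARKED"` or `"EXTREME"`.
#' @param window_days Length of the pre-exacerbation window (default 14).
#' @return A one-row tibble: `level`, `n_pre`, `n_total`, `pct`,
#'   `n_pre_unreviewed`, `pct_unreviewed`.
#' @export
preexacerbation_overuse_fraction <- function(episodes, outcomes,
                                             level = c("HIGH", "MARKED", "EXTREME"),
                                             window_days = 14L) {
  level <- match.arg(level)
  flag <- tolower(level)
  if ("included_in_window_analysis" %in% names(episodes)) {
    episodes <- episodes[episodes$included_in_window_analysis, , drop = FALSE]
  }
  ou <- outcomes[outcomes[[flag]], , drop = FALSE]
  n_total <- nrow(ou)
  pre_keys <- character()
  if (nrow(episodes)) {
    offs <- seq(-window_days, -1L)
    pre_keys <- unique(paste(
      rep(episodes$participant_id, each = length(offs)),
      rep(episodes$day0, each = length(offs)) + rep(offs, times = nrow(episodes))
    ))
  }
  is_pre <- paste(ou$participant_id, ou$date) %in% pre_keys
  n_pre <- sum(is_pre)
  n_pre_unrev <- sum(ou$counted_as_unreviewed[is_pre])
  tibble::tibble(
    level = level,
    n_pre = n_pre,
    n_total = n_total,
    pct = if (n_total > 0) 100 * n_pre / n_total else 0,
    n_pre_unreviewed = n_pre_unrev,
    pct_unreviewed = if (n_pre > 0) 100 * n_pre_unrev / n_pre else NA_real_
  )
}

#' Highest daily medication use before and after Day 0
#'
#' For each included episode, finds the maximum daily actuations over the
#' pre (-14 to -1) and post (0 to +14) windows, using observed days only.
#' For Standard-arm episodes it also reports the budesonide/formoterol
#' count on the day of maximal salbutamol use (first such day on ties) and
#' how many episodes took more than 8, or zero, budesonide/formoterol
#' actuations on that day.
#'
#' @param windows Window rows from [extract_window()] (with `arm`).
#' @return A list with `per_episode` (one row per episode and period) and
#'   `summary` (median and range by arm and period, plus the Standard-arm
#'   companion counts).
#' @export
highest_use_summary <- function(windows) {
  if ("included_in_window_analysis" %in% names(windows)) {
    windows <- windows[windows$included_in_window_analysis, , drop = FALSE]
  }
  windows <- windows[windows$observed, , drop = FALSE]
  windows$period <- ifelse(windows$offset < 0, "pre", "post")
  per_episode <- windows |>
    dplyr::group_by(.data$participant_id, .data$episode_id, .data$arm,
                    .data$period) |>
    dplyr::summarise(
      max_bud_form = max(.data$bud_form_actuations),
      max_salbutamol = max(.data$salbutamol_actuations),
      bud_form_on_max_salb_day =
        .data$bud_form_actuations[which.max(.data$salbutamol_actuations)],
      n_days_observed = dplyr::n(),
      .groups = "drop"
    )
  summary <- per_episode |>
    dplyr::group_by(.data$arm, .data$period) |>
    dplyr::summarise(
      n_episodes = dplyr::n(),
      reliever = .data$arm[1L],
      reliever_median = ifelse(.data$arm[1L] == "SMART",
                               quantile2(.data$max_bud_form, 0.5),
                               quantile2(.data$max_salbutamol, 0.5)),
      reliever_min = ifelse(.data$arm[1L] == "SMART",
                            min(.data$max_bud_form), min(.data$max_salbutamol)),
      reliever_max = ifelse(.data$arm[1L] == "SMART",
                            max(.data$max_bud_form), max(.data$max_salbutamol)),
      companion_median = ifelse(.data$arm[1L] == "STANDARD",
                                quantile2(.data$bud_form_on_max_salb_day, 0.5),
                                NA_real_),
      companion_min = ifelse(.data$arm[1L] == "STANDARD",
                             min(.data$bud_form_on_max_salb_day), NA_real_),
      companion_max = ifelse(.data$arm[1L] == "STANDARD",
                             max(.data$bud_form_on_max_salb_day), NA_real_),
      n_companion_gt8 = ifelse(.data$arm[1L] == "STANDARD",
                               sum(.data$bud_form_on_max_salb_day > 8), NA_integer_),
      n_companion_zero = ifelse(.data$arm[1L] == "STANDARD",
                                sum(.data$bud_form_on_max_salb_day == 0), NA_integer_),
      .groups = "drop"
    )
  summary$reliever <- ifelse(summary$arm == "SMART", "BUD_FORM", "SALBUTAMOL")
  list(per_episode = per_episode, summary = summary)
}
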