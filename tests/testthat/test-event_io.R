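test_that("well-formed tables pass through load_events intact", {
  part <- make_participants(2, "SMART", days = 28L)
  act <- make_actuations(
    rep(part$participant_id, c(3, 2)), "BUD_FORM",
    paste(d(c(1, 1, 5, 2, 9)), "08:00:00")
  )
  rev <- tibble::tibble(participant_id = part$participant_id[1],
                        date = d(3), setting = "PRIMARY_CARE")
  ocs <- empty_tbl()$ocs
  cohort <- load_events(act, rev, ocs, part)
  expect_s3_class(cohort, "overuse_cohort")
  expect_equal(nrow(cohort$participants), 2L)
  expect_equal(nrow(cohort$actuations), 5L)
  expect_equal(nrow(cohort$rejected), 0L)

  # same result when read back from CSV (string timestamps, ISO-8601)
  dir <- withr::local_tempdir()
  act_csv <- file.path(dir, "act.csv")
  act_out <- act
  act_out$timestamp <- format(act_out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  readr::write_csv(act_out, act_csv)
  readr::write_csv(rev, file.path(dir, "rev.csv"))
  readr::write_csv(ocs, file.path(dir, "ocs.csv"))
  readr::write_csv(part, file.path(dir, "part.csv"))
  cohort2 <- load_events(act_csv, file.path(dir, "rev.csv"),
                         file.path(dir, "ocs.csv"), file.path(dir, "part.csv"))
  expect_equal(cohort2$actuations$timestamp, cohort$actuations$timestamp)
})

test_that("rows outside the monitoring period are rejected with a report", {
  part <- make_participants(1, "SMART", days = 10L)  # days 1..10
  act <- make_actuations(
    part$participant_id[c(1, 1)], "BUD_FORM",
    paste(d(c(0, 5)), "10:00:00")  # day 0 precedes monitor_start
  )
  expect_message(
    cohort <- load_events(act, empty_tbl()$reviews, empty_tbl()$ocs, part),
    "rejected"
  )
  expect_equal(nrow(cohort$actuations), 1L)
  expect_equal(nrow(cohort$rejected), 1L)
  expect_equal(cohort$rejected$row, 1L)
  expect_match(cohort$rejected$reason, "outside monitoring period")
})

test_that("structural violations are errors naming the rule and rows", {
  part <- make_participants(1, "SMART", days = 10L)
  salb <- make_actuations(part$participant_id, "SALBUTAMOL",
                          paste(d(2), "10:00:00"))
  expect_error(
    load_events(salb, empty_tbl()$reviews, empty_tbl()$ocs, part),
    "SALBUTAMOL.*SMART"
  )

  unknown <- make_actuations("GHOST", "BUD_FORM", paste(d(2), "10:00:00"))
  expect_error(
    load_events(unknown, empty_tbl()$reviews, empty_tbl()$ocs, part),
    "unknown participant id.*GHOST"
  )

  bad_ts <- tibble::tibble(participant_id = rep(part$participant_id, 2),
                           medication = "BUD_FORM",
                           timestamp = c("2012-04-02T10:00:00", "not-a-time"))
  expect_error(
    load_events(bad_ts, empty_tbl()$reviews, empty_tbl()$ocs, part),
    "malformed timestamp.*line\\(s\\) 2"
  )

  bad_ocs <- tibble::tibble(participant_id = part$participant_id,
                            start_date = d(5), end_date = d(3))
  expect_error(
    load_events(empty_tbl()$actuations, empty_tbl()$reviews, bad_ocs, part),
    "end_date before start_date"
  )
})

test_that("aggregate_days zero-fills and cuts days at midnight", {
  part <- make_participants(1, "SMART", days = 2L)  # days 1..2
  act <- make_actuations(
    rep(part$participant_id, 7), "BUD_FORM",
    paste(d(1), c("01:00:00", "05:00:00", "09:00:00", "13:00:00", "23:59:59",
                  "17:00:00", "21:00:00"))
  )
  days <- aggregate_days(load_events(act, empty_tbl()$reviews,
                                     empty_tbl()$ocs, part))
  expect_equal(days$bud_form_actuations, c(7L, 0L))

  # one second either side of midnight lands on different days
  act2 <- make_actuations(
    rep(part$participant_id, 2), "BUD_FORM",
    c(paste(d(1), "23:59:59"), paste(d(2), "00:00:01"))
  )
  days2 <- aggregate_days(load_events(act2, empty_tbl()$reviews,
                                      empty_tbl()$ocs, part))
  expect_equal(days2$bud_form_actuations, c(1L, 1L))

  # a participant with no events yields all-zero day records
  part168 <- make_participants(1, "STANDARD", days = 168L)
  days3 <- aggregate_days(load_events(empty_tbl()$actuations,
                                      empty_tbl()$reviews, empty_tbl()$ocs,
                                      part168))
  expect_equal(nrow(days3), 168L)
  expect_true(all(days3$bud_form_actuations == 0L))
  expect_true(all(days3$salbutamol_actuations == 0L))
})

test_that("day aggregation conserves events and ignores row order", {
  withr::local_seed(101)
  part <- dplyr::bind_rows(make_participants(3, "SMART", days = 20L),
                           make_participants(3, "STANDARD", days = 20L))
  n <- 400L
  pid <- sample(part$participant_id, n, replace = TRUE)
  arm <- part$arm[match(pid, part$participant_id)]
  med <- ifelse(arm == "SMART", "BUD_FORM",
                sample(c("BUD_FORM", "SALBUTAMOL"), n, replace = TRUE))
  act <- make_actuations(
    pid, med,
    as.POSIXct(paste(d(sample(1:20, n, replace = TRUE)),
                     sprintf("%02d:%02d:%02d", sample(0:23, n, TRUE),
                             sample(0:59, n, TRUE), sample(0:59, n, TRUE))),
               tz = "UTC")
  )
  cohort <- load_events(act, empty_tbl()$reviews, empty_tbl()$ocs, part)
  days <- aggregate_days(cohort)
  expect_equal(sum(days$bud_form_actuations) + sum(days$salbutamol_actuations), n)

  # per participant x medication x date totals agree with a plain recount
  counts <- oracle_day_counts(cohort$actuations)
  long <- tidyr::pivot_longer(days, dplyr::ends_with("actuations"),
                              names_to = "med", values_to = "n")
  long$med <- ifelse(long$med == "bud_form_actuations", "BUD_FORM", "SALBUTAMOL")
  long <- long[long$n > 0, ]
  expect_equal(sort(paste(long$participant_id, long$date, long$med)),
               sort(names(counts)))
  expect_equal(long$n[match(names(counts),
                            paste(long$participant_id, long$date, long$med))],
               as.integer(counts), ignore_attr = TRUE)

  # permutation invariance
  shuffled <- act[sample(n), ]
  days2 <- aggregate_days(load_events(shuffled, empty_tbl()$reviews,
                                      empty_tbl()$ocs, part))
  expect_equal(days2, days)
})
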