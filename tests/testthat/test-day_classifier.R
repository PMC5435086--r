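test_that("regimen-specific thresholds classify days as published", {
  cases <- tibble::tribble(
    ~arm,       ~bud, ~salb, ~level,
    "SMART",     13L,    0L, "HIGH",     # just over the >12 total limit
    "SMART",     12L,    0L, "NONE",     # strict inequality at the boundary
    "SMART",     17L,    0L, "MARKED",
    "SMART",     21L,    0L, "EXTREME",
    "STANDARD",   0L,   17L, "HIGH",
    "STANDARD",   0L,   16L, "NONE",
    "STANDARD",   0L,   33L, "EXTREME",
    "STANDARD",  30L,   10L, "NONE"      # bud/form ignored in the Standard arm
  )
  days <- make_days(sprintf("P%02d", seq_len(nrow(cases))), cases$arm,
                    rep(d(1), nrow(cases)), cases$bud, cases$salb)
  out <- classify_days(days)
  expect_equal(out$overuse_level, cases$level)
  # cumulative flags: extreme implies marked implies high
  expect_true(all(!out$extreme | out$marked))
  expect_true(all(!out$marked | out$high))
})

test_that("smart_mode excess reproduces the total-mode rule at default maintenance", {
  days <- make_days("P1", "SMART", d(1:30), bud = sample(0:30, 30, replace = TRUE))
  total <- classify_days(days, threshold_config(smart_mode = "total"))
  excess <- classify_days(days, threshold_config(smart_mode = "excess"))
  expect_equal(total$overuse_level, excess$overuse_level)
})

test_that("count_overuse_days counts flagged days per participant", {
  # five days: high, high+marked, none, high+marked+extreme, none
  days <- make_days("P1", "SMART", d(1:5), bud = c(13L, 17L, 4L, 21L, 0L))
  days <- dplyr::bind_rows(days, make_days("P2", "SMART", d(1:5), bud = 4L))
  out <- classify_days(days)
  expect_equal(count_overuse_days(out, "HIGH")$n_days, c(3L, 0L))
  expect_equal(count_overuse_days(out, "MARKED")$n_days, c(2L, 0L))
  expect_equal(count_overuse_days(out, "EXTREME")$n_days, c(1L, 0L))
  expect_error(count_overuse_days(out, "SEVERE"))
})

test_that("nesting and threshold monotonicity hold on random days", {
  withr::local_seed(202)
  for (rep in 1:20) {
    n <- 60L
    days <- make_days(
      sample(sprintf("P%02d", 1:5), n, replace = TRUE),
      sample(ARMS <- c("SMART", "STANDARD"), n, replace = TRUE),
      d(sample(1:400, n)), bud = sample(0:40, n, TRUE),
      salb = sample(0:40, n, TRUE)
    )
    out <- classify_days(days)
    expect_true(all(out$extreme <= out$marked & out$marked <= out$high))

    raised <- classify_days(days, threshold_config(
      smart_excess_thresholds = c(9L, 13L, 17L),
      standard_salbutamol_thresholds = c(17L, 25L, 33L)
    ))
    for (flag in c("high", "marked", "extreme")) {
      expect_true(all(raised[[flag]] <= out[[flag]]))
    }
  }
})

test_that("classification agrees with a brute-force recount from raw events", {
  cohort <- generate_cohort(small_config(), seed = 303)
  bundle <- load_events(cohort$actuations, cohort$reviews, cohort$ocs,
                        cohort$participants)
  days <- classify_days(aggregate_days(bundle))

  # recount each flagged day straight from the event stream
  counts <- oracle_day_counts(bundle$actuations)
  flagged <- days[days$high, ]
  for (i in seq_len(min(nrow(flagged), 200L))) {
    row <- flagged[i, ]
    key <- paste(row$participant_id, row$date,
                 if (row$arm == "SMART") "BUD_FORM" else "SALBUTAMOL")
    n_events <- if (key %in% names(counts)) as.integer(counts[[key]]) else 0L
    cut <- if (row$arm == "SMART") 12L else 16L
    expect_gt(n_events, cut)
  }
  # and no unflagged day crosses its threshold
  unflagged <- days[!days$high, ]
  smart_keys <- paste(unflagged$participant_id[unflagged$arm == "SMART"],
                      unflagged$date[unflagged$arm == "SMART"], "BUD_FORM")
  expect_true(all(counts[names(counts) %in% smart_keys] <= 12L))
  std_keys <- paste(unflagged$participant_id[unflagged$arm == "STANDARD"],
                    unflagged$date[unflagged$arm == "STANDARD"], "SALBUTAMOL")
  expect_true(all(counts[names(counts) %in% std_keys] <= 16L))
})
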