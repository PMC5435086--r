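ocs_tbl <- function(pid, starts, ends) {
  tibble::tibble(participant_id = pid, start_date = d(starts),
                 end_date = d(ends))
}

test_that("episode construction applies the 3-day and 7-day rules", {
  # a single 4-day course is one episode anchored at its first day
  ep <- build_episodes(ocs_tbl("P1", 10, 13))
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$day0, d(10))

  # courses 2 days apart merge; Day 0 stays at the earliest start
  ep <- build_episodes(ocs_tbl(rep("P1", 2), c(10, 15), c(12, 17)))
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$day0, d(10))
  expect_equal(ep$n_courses, 2L)

  # a 12-day gap keeps the courses as separate exacerbations
  ep <- build_episodes(ocs_tbl(rep("P1", 2), c(10, 25), c(12, 27)))
  expect_equal(nrow(ep), 2L)

  # a gap of exactly 7 days separates ("separated by 7 days or more")
  ep <- build_episodes(ocs_tbl(rep("P1", 2), c(10, 19), c(12, 21)))
  expect_equal(nrow(ep), 2L)
  ep <- build_episodes(ocs_tbl(rep("P1", 2), c(10, 18), c(12, 20)))
  expect_equal(nrow(ep), 1L)

  # a 2-day course is not a severe exacerbation
  expect_equal(nrow(build_episodes(ocs_tbl("P1", 10, 11))), 0L)

  # overlapping courses merge with a warning
  expect_warning(
    ep <- build_episodes(ocs_tbl(rep("P1", 2), c(10, 12), c(14, 16))),
    "overlapping"
  )
  expect_equal(nrow(ep), 1L)
})

test_that("episode construction is idempotent and order-invariant", {
  withr::local_seed(606)
  for (i in 1:25) {
    n <- sample(2:6, 1)
    starts <- sort(sample(1:120, n))
    lens <- sample(2:8, n, replace = TRUE)
    ocs <- ocs_tbl(rep("P1", n), starts, starts + lens - 1)
    ep1 <- suppressWarnings(build_episodes(ocs))
    ep2 <- suppressWarnings(build_episodes(ocs[sample(n), ]))
    expect_equal(ep1, ep2)
    if (nrow(ep1)) {
      # feeding the merged episodes back in changes nothing
      again <- suppressWarnings(build_episodes(
        ocs_tbl(ep1$participant_id, as.integer(ep1$course_start - epoch),
                as.integer(ep1$course_end - epoch))
      ))
      expect_equal(again$day0, ep1$day0)
    }
  }
})

test_that("window inclusion enforces the 28-day interval and no-data exclusions", {
  # 35 episodes, one of which starts 20 days after its predecessor
  ocs <- dplyr::bind_rows(
    ocs_tbl(sprintf("S%02d", 1:33), seq(10, 10 + 32 * 4, by = 4),
            seq(13, 13 + 32 * 4, by = 4)),
    ocs_tbl(rep("S34", 2), c(10, 30), c(13, 33))
  )
  ep <- select_window_episodes(build_episodes(ocs))
  expect_equal(nrow(ep), 35L)
  expect_equal(sum(ep$included_in_window_analysis), 34L)
  expect_equal(ep$exclusion_reason[!ep$included_in_window_analysis],
               "repeat_within_interval")

  # 66 episodes: 3 repeats within 28 days, 2 without monitor data -> 61
  ocs <- dplyr::bind_rows(
    ocs_tbl(sprintf("T%02d", 1:60), rep(c(10, 50, 90), 20), rep(c(13, 53, 93), 20)),
    ocs_tbl(rep(c("T61", "T62", "T63"), each = 2),
            rep(c(10, 25), 3), rep(c(13, 28), 3))
  )
  ep <- build_episodes(ocs)
  expect_equal(nrow(ep), 66L)
  sel <- select_window_episodes(ep, no_data_episodes = c("T01_E1", "T02_E1"))
  expect_equal(sum(sel$included_in_window_analysis), 61L)
  expect_equal(sort(unique(sel$exclusion_reason[!sel$included_in_window_analysis])),
               c("no_monitor_data", "repeat_within_interval"))

  # a Day 0 interval of exactly 28 days satisfies the minimum
  ep <- select_window_episodes(build_episodes(
    ocs_tbl(rep("P1", 2), c(10, 38), c(13, 41))
  ))
  expect_true(all(ep$included_in_window_analysis))

  # a single episode is always included
  ep <- select_window_episodes(build_episodes(ocs_tbl("P1", 10, 13)))
  expect_true(ep$included_in_window_analysis)
})

test_that("window extraction truncates at monitoring bounds, not to zero", {
  days <- make_days("P1", "SMART", d(1:40), bud = 4L)
  ep <- select_window_episodes(build_episodes(ocs_tbl("P1", 21, 24)))
  win <- extract_window(ep, days)
  expect_equal(nrow(win), 29L)
  expect_true(all(win$observed))
  expect_equal(unique(win$bud_form_actuations), 4L)  # flat profile

  # Day 0 five days into monitoring: offsets -14..-6 unobserved
  ep2 <- select_window_episodes(build_episodes(ocs_tbl("P1", 6, 9)))
  win2 <- extract_window(ep2, days)
  expect_equal(sum(!win2$observed), 9L)
  expect_true(all(is.na(win2$bud_form_actuations[!win2$observed])))
  expect_equal(win2$offset[!win2$observed], -14:-6)
})

test_that("profile medians use averaging quantiles and drop absent offsets", {
  days <- dplyr::bind_rows(
    make_days("P1", "SMART", d(1:40), bud = 2L),
    make_days("P2", "SMART", d(1:40), bud = 4L),
    make_days("P3", "SMART", d(1:40), bud = 6L)
  )
  ep <- select_window_episodes(build_episodes(
    ocs_tbl(c("P1", "P2", "P3"), 21, 24)
  ))
  prof <- profile_medians(extract_window(ep, days))
  bud0 <- prof[prof$medication == "BUD_FORM" & prof$offset == 0, ]
  expect_equal(bud0$median, 4)
  expect_equal(c(bud0$q1, bud0$q3), c(2, 6))
  expect_equal(bud0$n, 3L)

  # single episode: median and IQR collapse to the value
  prof1 <- profile_medians(extract_window(
    select_window_episodes(build_episodes(ocs_tbl("P1", 21, 24))),
    make_days("P1", "SMART", d(1:40), bud = 5L)
  ))
  expect_true(all(prof1$median[prof1$medication == "BUD_FORM"] == 5))
  expect_true(all(prof1$q1 == prof1$q3))

  # offsets outside monitoring are absent rather than zero
  prof2 <- profile_medians(extract_window(
    select_window_episodes(build_episodes(ocs_tbl("P1", 6, 9))),
    make_days("P1", "SMART", d(1:40), bud = 5L)
  ))
  expect_equal(sort(unique(prof2$offset)), -5:14)
})

test_that("dose dumping flags 100 actuations in 3 h and respects the boundary", {
  burst <- function(n, span_sec, t0 = "2012-04-05 10:00:00") {
    make_actuations(rep("P1", n), "SALBUTAMOL",
                    as.POSIXct(t0, tz = "UTC") + seq(0, span_sec, length.out = n))
  }
  expect_equal(nrow(detect_dose_dumping(burst(100, 600))), 1L)
  expect_equal(nrow(detect_dose_dumping(burst(99, 600))), 0L)
  # 100 actuations evenly spread over 3 h 1 min: no 3-h window holds them all
  expect_equal(nrow(detect_dose_dumping(burst(100, 181 * 60))), 0L)
  flag <- detect_dose_dumping(burst(120, 600))
  expect_gte(flag$actuation_count, 100L)
})

test_that("dose-dump detector matches the O(n^2) pair scan on random fixtures", {
  withr::local_seed(707)
  for (i in 1:60) {
    t0 <- as.POSIXct("2012-04-05 00:00:00", tz = "UTC")
    scatter <- runif(sample(50:150, 1), 0, 86400)
    n_burst <- sample(c(0L, 90L, 100L, 130L), 1, prob = c(.3, .3, .2, .2))
    burst_start <- runif(1, 0, 70000)
    burst <- runif(n_burst, burst_start, burst_start + runif(1, 300, 12000))
    times <- t0 + sort(c(scatter, burst))
    act <- make_actuations(rep("P1", length(times)), "SALBUTAMOL", times)
    got <- detect_dose_dumping(act)
    want <- oracle_dose_dump(times)
    expect_equal(nrow(got), nrow(want), info = sprintf("fixture %d", i))
    if (nrow(want)) {
      expect_equal(as.numeric(got$window_start), want$start)
      expect_equal(as.numeric(got$window_end), want$end)
      expect_equal(got$actuation_count, want$count)
    }
  }
})

test_that("pre-exacerbation overuse fractions count offsets -14..-1 only", {
  # 10 participants with a high day 5 days before their episode; 3 reviewed
  days <- dplyr::bind_rows(lapply(sprintf("P%02d", 1:10), function(p) {
    make_days(p, "SMART", d(1:40), bud = c(rep(4L, 19), 13L, rep(4L, 20)))
  }))
  days <- classify_days(days)
  reviews <- tibble::tibble(participant_id = sprintf("P%02d", 1:3),
                            date = d(20), setting = "PRIMARY_CARE")
  out <- link_overuse_reviews(days, reviews)
  ep <- select_window_episodes(build_episodes(
    ocs_tbl(sprintf("P%02d", 1:10), 25, 28)
  ))
  frac <- preexacerbation_overuse_fraction(ep, out, "HIGH")
  expect_equal(frac$n_pre, 10L)
  expect_equal(frac$n_total, 10L)
  expect_equal(frac$pct, 100)
  expect_equal(frac$n_pre_unreviewed, 7L)
  expect_equal(frac$pct_unreviewed, 70)

  # Day 0 itself is "post": an overuse day on Day 0 is not pre-exacerbation
  days0 <- classify_days(make_days("P01", "SMART", d(1:40),
                                   bud = c(rep(4L, 24), 13L, rep(4L, 15))))
  out0 <- link_overuse_reviews(days0, reviews[0, ])
  ep0 <- select_window_episodes(build_episodes(ocs_tbl("P01", 25, 28)))
  expect_equal(preexacerbation_overuse_fraction(ep0, out0, "HIGH")$n_pre, 0L)

  # no episodes: zero numerator and zero percentage
  frac0 <- preexacerbation_overuse_fraction(ep[0, ], out, "HIGH")
  expect_equal(frac0$n_pre, 0L)
  expect_equal(frac0$pct, 0)
})

test_that("highest-use summary takes per-episode maxima over pre and post windows", {
  bud <- rep(2L, 40)
  salb <- rep(1L, 40)
  salb[18] <- 25L   # offset -7: pre-window max
  bud[18] <- 9L     # companion bud/form on the max-salbutamol day
  salb[30] <- 40L   # offset +5: post-window max
  days <- make_days("P1", "STANDARD", d(1:40), bud = bud, salb = salb)
  ep <- select_window_episodes(build_episodes(ocs_tbl("P1", 25, 28)))
  hs <- highest_use_summary(extract_window(ep, days))
  pre <- hs$per_episode[hs$per_episode$period == "pre", ]
  post <- hs$per_episode[hs$per_episode$period == "post", ]
  expect_equal(pre$max_salbutamol, 25L)
  expect_equal(pre$bud_form_on_max_salb_day, 9L)
  expect_equal(post$max_salbutamol, 40L)
  s <- hs$summary[hs$summary$period == "pre", ]
  expect_equal(s$reliever_median, 25)
  expect_equal(s$n_companion_gt8, 1L)
  expect_equal(s$n_companion_zero, 0L)

  # an all-zero window yields a maximum of 0, not NA
  days0 <- make_days("P2", "STANDARD", d(1:40), bud = 0L, salb = 0L)
  ep0 <- select_window_episodes(build_episodes(ocs_tbl("P2", 25, 28)))
  hs0 <- highest_use_summary(extract_window(ep0, days0))
  expect_true(all(hs0$per_episode$max_salbutamol == 0L))
})
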