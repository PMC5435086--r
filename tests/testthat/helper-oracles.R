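# Independent brute-force oracles. These recompute, from first principles
# and by plain scanning, quantities the package computes by construction
# (set-based ledgers, findInterval windows), and are deliberately written
# as per-item loops.

# For every overuse day, scan all review dates and recompute 48-h review
# and stand-down protection directly from the rule statement.
oracle_unreviewed <- function(overuse_dates, review_dates,
                              window_days = 1L, standdown_days = 7L) {
  od <- as.integer(as.Date(overuse_dates))
  rv <- as.integer(as.Date(review_dates))
  counted <- logical(length(od))
  for (i in seq_along(od)) {
    reviewed <- FALSE
    protected <- FALSE
    for (r in rv) {
      if (r >= od[i] && r <= od[i] + window_days) reviewed <- TRUE
      if (od[i] >= r && od[i] <= r + standdown_days) protected <- TRUE
      if (r == od[i] + window_days) protected <- TRUE  # index day of a linked review
    }
    counted[i] <- !reviewed && !protected
  }
  counted
}

# O(n^2) pair scan for the dose-dumping rule: anchor every event, count
# events within the window by scanning all pairs, then merge overlapping
# flagged spans. Returns a data frame of merged (start, end, count).
oracle_dose_dump <- function(times, threshold = 100L, window_sec = 3 * 3600) {
  t <- sort(as.numeric(times))
  spans <- NULL
  for (i in seq_along(t)) {
    inw <- which(t >= t[i] & t <= t[i] + window_sec)
    if (length(inw) >= threshold) {
      spans <- rbind(spans, c(t[i], t[max(inw)]))
    }
  }
  if (is.null(spans)) {
    return(data.frame(start = numeric(), end = numeric(), count = integer()))
  }
  spans <- spans[order(spans[, 1]), , drop = FALSE]
  merged <- spans[1, , drop = FALSE]
  if (nrow(spans) > 1) {
    for (k in 2:nrow(spans)) {
      last <- nrow(merged)
      if (spans[k, 1] <= merged[last, 2]) {
        merged[last, 2] <- max(merged[last, 2], spans[k, 2])
      } else {
        merged <- rbind(merged, spans[k, , drop = FALSE])
      }
    }
  }
  data.frame(
    start = merged[, 1], end = merged[, 2],
    count = vapply(seq_len(nrow(merged)), function(j) {
      sum(t >= merged[j, 1] & t <= merged[j, 2])
    }, integer(1L))
  )
}

# Recount day-level actuation totals straight from raw events with table().
oracle_day_counts <- function(actuations, tz = "UTC") {
  key <- paste(actuations$participant_id,
               as.Date(actuations$timestamp, tz = tz),
               actuations$medication)
  table(key)
}
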