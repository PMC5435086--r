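# Shared fixture builders. Dates are written relative to an arbitrary study
# epoch so examples read as "day 5", "day 6" etc.

epoch <- as.Date("2012-04-01")

d <- function(n) epoch + n

make_participants <- function(n, arm = "SMART", days = 28L, start = d(1)) {
  tibble::tibble(
    participant_id = sprintf("%s%03d", substr(arm, 1, 2), seq_len(n)),
    arm = arm,
    monitor_start = start,
    monitor_end = start + days - 1L
  )
}

make_actuations <- function(participant_id, medication, timestamps) {
  tibble::tibble(
    participant_id = participant_id,
    medication = medication,
    timestamp = as.POSIXct(timestamps, tz = "UTC")
  )
}

# Day records as classify_days() expects them.
make_days <- function(participant_id, arm, dates, bud = 0L, salb = 0L) {
  tibble::tibble(
    participant_id = participant_id,
    arm = arm,
    date = dates,
    bud_form_actuations = as.integer(rep_len(bud, length(dates))),
    salbutamol_actuations = as.integer(rep_len(salb, length(dates)))
  )
}

empty_tbl <- function(...) {
  list(
    actuations = tibble::tibble(participant_id = character(),
                                medication = character(),
                                timestamp = as.POSIXct(character(), tz = "UTC")),
    reviews = tibble::tibble(participant_id = character(),
                             date = as.Date(character()),
                             setting = character()),
    ocs = tibble::tibble(participant_id = character(),
                         start_date = as.Date(character()),
                         end_date = as.Date(character()))
  )
}

# A small cohort for pipeline-level tests: full machinery, desk scale.
small_config <- function(...) {
  cohort_config(n_smart = 40L, n_standard = 40L, n_days = 84L, ...)
}
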