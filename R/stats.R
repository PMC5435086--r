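#' Relative risk from a 2x2 contingency table (Wald interval)
#'
#' Simple contingency-table analysis of a binary outcome between arms:
#' `RR = (events_a / n_a) / (events_b / n_b)` with the log-scale Wald
#' standard error `sqrt(1/events_a - 1/n_a + 1/events_b - 1/n_b)`, a 95%
#' interval `exp(log RR +/- 1.96 SE)` and a two-sided p-value from the
#' log-RR Wald statistic. If either arm has zero events, 0.5 is added to
#' all four cells (continuity correction) and the result is flagged.
#'
#' @param events_a,n_a Events and denominator in arm A (convention: SMART).
#' @param events_b,n_b Events and denominator in arm B (Standard).
#' @param conf_level Confidence level (default 0.95).
#' @return An `arm_comparison` object: `estimate`, `ci_low`, `ci_high`,
#'   `p_value`, `method = "RELATIVE_RISK_WALD"`, `corrected`.
#' @examples
#' relative_risk(84, 151, 68, 152)  # RR 1.24 (0.99-1.56)
#' @export
relative_risk <- function(events_a, n_a, events_b, n_b, conf_level = 0.95) {
  stopifnot(length(events_a) == 1L, length(events_b) == 1L,
            n_a > 0, n_b > 0, events_a >= 0, events_b >= 0,
            events_a <= n_a, events_b <= n_b)
  corrected <- events_a == 0 || events_b == 0
  if (corrected) {
    events_a <- events_a + 0.5
    events_b <- events_b + 0.5
    n_a <- n_a + 0.5
    n_b <- n_b + 0.5
  }
  est <- (events_a / n_a) / (events_b / n_b)
  se <- sqrt(1 / events_a - 1 / n_a + 1 / events_b - 1 / n_b)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  new_arm_comparison(
    estimate = est,
    ci_low = exp(log(est) - z * se),
    ci_high = exp(log(est) + z * se),
    p_value = 2 * stats::pnorm(-abs(log(est) / se)),
    method = "RELATIVE_RISK_WALD",
    corrected = corrected
  )
}

#' Between-arm rate ratio via quasi-Poisson regression with exposure offset
#'
#' Fits the log-linear model `count ~ arm` with `offset(log(exposure))` by
#' Poisson regression, then adjusts for over-dispersion by scaling the
#' standard error with the square root of the Pearson dispersion
#' (chi-square / residual df), the quasi-likelihood convention. With equal
#' exposures the point estimate is the ratio of mean counts, arm A vs arm
#' B. If one arm has no events at all, an aggregate continuity-corrected
#' estimate (0.5 added to each arm total) is returned with a flag.
#'
#' @param counts_a,counts_b Per-participant event counts (days of overuse,
#'   exacerbations, ...) in each arm.
#' @param exposure_a,exposure_b Per-participant exposure (days of
#'   treatment); recycled to the length of the counts.
#' @param dispersion Optional fixed dispersion; `NULL` (default) estimates
#'   it from the Pearson residuals. `dispersion = 1` reproduces the
#'   textbook Poisson Wald interval.
#' @param conf_level Confidence level (default 0.95).
#' @return An `arm_comparison` object with `method =
#'   "QUASIPOISSON_RATE_RATIO"` and the `dispersion` used.
#' @examples
#' rate_ratio(c(rep(1, 35), rep(0, 116)), 168,
#'            c(rep(1, 66), rep(0, 86)), 168)
#' @export
rate_ratio <- function(counts_a, exposure_a, counts_b, exposure_b,
                       dispersion = NULL, conf_level = 0.95) {
  stopifnot(length(counts_a) >= 1L, length(counts_b) >= 1L,
            all(counts_a >= 0), all(counts_b >= 0))
  exposure_a <- rep_len(exposure_a, length(counts_a))
  exposure_b <- rep_len(exposure_b, length(counts_b))
  stopifnot(all(exposure_a > 0), all(exposure_b > 0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)

  if (sum(counts_a) == 0 || sum(counts_b) == 0) {
    ca <- sum(counts_a) + 0.5
    cb <- sum(counts_b) + 0.5
    est <- (ca / sum(exposure_a)) / (cb / sum(exposure_b))
    se <- sqrt(1 / ca + 1 / cb)
    return(new_arm_comparison(
      estimate = est,
      ci_low = exp(log(est) - z * se),
      ci_high = exp(log(est) + z * se),
      p_value = 2 * stats::pnorm(-abs(log(est) / se)),
      method = "QUASIPOISSON_RATE_RATIO",
      dispersion = NA_real_,
      corrected = TRUE
    ))
  }

  if (length(counts_a) < 2L || length(counts_b) < 2L) {
    stop("rate_ratio() needs at least 2 participants per arm", call. = FALSE)
  }
  df <- data.frame(
    count = c(counts_a, counts_b),
    exposure = c(exposure_a, exposure_b),
    arm = factor(rep(c("A", "B"), c(length(counts_a), length(counts_b))),
                 levels = c("B", "A"))
  )
  fit <- stats::glm(count ~ arm + offset(log(exposure)),
                    family = stats::poisson(), data = df,
                    control = stats::glm.control(epsilon = 1e-12, maxit = 50L))
  co <- stats::coef(fit)[["armA"]]
  se0 <- sqrt(stats::vcov(fit)["armA", "armA"])
  disp <- dispersion %||%
    (sum(stats::residuals(fit, type = "pearson")^2) / fit$df.residual)
  se <- se0 * sqrt(disp)
  new_arm_comparison(
    estimate = exp(co),
    ci_low = exp(co - z * se),
    ci_high = exp(co + z * se),
    p_value = 2 * stats::pnorm(-abs(co / se)),
    method = "QUASIPOISSON_RATE_RATIO",
    dispersion = disp,
    corrected = FALSE
  )
}

#' Descriptive summary of per-participant proportions
#'
#' Mean, SD, median, IQR and range over participants, dropping `NA`s (the
#' undefined proportions of participants without any overuse day, so the
#' summary covers participants with at least one overuse episode only).
#' Quantiles average at discontinuities (type 2); the SD of a single value
#' is reported as 0.
#'
#' @param x Numeric vector of proportions (or any per-participant
#'   statistic), `NA` allowed.
#' @return A one-row tibble: `n`, `mean`, `sd`, `median`, `q1`, `q3`,
#'   `min`, `max`.
#' @export
proportion_summary <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) {
    return(tibble::tibble(n = 0L, mean = NA_real_, sd = NA_real_,
                          median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                          min = NA_real_, max = NA_real_))
  }
  tibble::tibble(
    n = length(x),
    mean = mean(x),
    sd = sd0(x),
    median = quantile2(x, 0.5),
    q1 = quantile2(x, 0.25),
    q3 = quantile2(x, 0.75),
    min = min(x),
    max = max(x)
  )
}

#' @noRd
new_arm_comparison <- function(estimate, ci_low, ci_high, p_value, method,
                               dispersion = NA_real_, corrected = FALSE) {
  structure(
    list(estimate = estimate, ci_low = ci_low, ci_high = ci_high,
         p_value = p_value, method = method, dispersion = dispersion,
         corrected = corrected),
    class = "arm_comparison"
  )
}

#' @export
print.arm_comparison <- function(x, ...) {
  lab <- switch(x$method,
                RELATIVE_RISK_WALD = "Relative risk (Wald)",
                QUASIPOISSON_RATE_RATIO = "Rate ratio (quasi-Poisson)",
                x$method)
  cat(sprintf("%s %.2f (95%% CI %.2f-%.2f), p = %.3g",
              lab, x$estimate, x$ci_low, x$ci_high, x$p_value))
  if (!is.na(x$dispersion)) cat(sprintf(", dispersion %.2f", x$dispersion))
  if (x$corrected) cat(" [continuity corrected]")
  cat("\n")
  invisible(x)
}

#' @noRd
as_comparison_row <- function(x, outcome, level = NA_character_) {
  tibble::tibble(
    outcome = outcome, level = level, method = x$method,
    estimate = x$estimate, ci_low = x$ci_low, ci_high = x$ci_high,
    p_value = x$p_value, dispersion = x$dispersion, corrected = x$corrected
  )
}
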