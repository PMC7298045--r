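#' Aggregate time series container
#'
#' @param condition storage temperature, degC.
#' @param days non-negative integer days, strictly increasing, day 0 present.
#' @param percent_aggregate percent aggregate per day, finite, in [0, 100].
#' @return object of class `aggregate_series`.
#' @export
aggregate_series <- function(condition, days, percent_aggregate) {
  if (length(days) != length(percent_aggregate))
    stop_input("days and percent_aggregate must have equal length")
  if (is.unsorted(days, strictly = TRUE)) stop_input("days must be strictly increasing")
  if (days[1] != 0) stop_input("day 0 must be present")
  if (any(!is.finite(percent_aggregate)) ||
      any(percent_aggregate < 0 | percent_aggregate > 100))
    stop_input("percent_aggregate must be finite and within [0, 100]")
  structure(list(condition = condition, days = as.integer(days),
                 percent_aggregate = percent_aggregate),
            class = "aggregate_series")
}

#' Aggregation change and rate over a storage window
#'
#' @param series an [aggregate_series] with >= 2 time points.
#' @return list: `delta_percent` (last minus first) and `rate_percent_per_day`
#'   (ordinary least-squares slope of percent vs day).
#' @export
aggregation_delta <- function(series) {
  if (length(series$days) < 2L) stop_input("need >= 2 time points")
  fit <- lm(series$percent_aggregate ~ series$days)
  list(delta_percent = series$percent_aggregate[length(series$days)] -
         series$percent_aggregate[1L],
       rate_percent_per_day = unname(coef(fit)[2]))
}

#' Accelerated-stress acceptance criterion
#'
#' Passes when the increase in percent aggregate over the 28-day window at
#' 40 degC is strictly below `limit_percent` (default 1%). The criterion uses
#' the change from time zero, not the absolute level.
#'
#' @param series_40C an [aggregate_series] covering >= 28 days.
#' @param limit_percent strict upper limit on the delta, default 1.
#' @return list of class `stress_verdict`: `pass` (logical, `NA` when data
#'   are insufficient), `delta_percent`, `status`.
#' @export
passes_stress_criterion <- function(series_40C, limit_percent = 1.0) {
  if (max(series_40C$days) < 28L)
    return(structure(list(pass = NA, delta_percent = NA_real_,
                          status = "insufficient data",
                          limit_percent = limit_percent),
                     class = "stress_verdict"))
  d <- aggregation_delta(series_40C)$delta_percent
  structure(list(pass = d < limit_percent, delta_percent = d,
                 status = "ok", limit_percent = limit_percent),
            class = "stress_verdict")
}

#' @export
print.stress_verdict <- function(x, ...) {
  cat(sprintf("<stress_verdict> %s (delta %.2f%%, limit %.2f%%)\n",
              if (is.na(x$pass)) x$status else if (x$pass) "PASS" else "FAIL",
              x$delta_percent, x$limit_percent))
  invisible(x)
}

#' Simulate an aggregate time series
#'
#' Linear growth from `start_percent` at `slope` percent/day with additive
#' Gaussian noise (day 0 kept noise-free as the normalisation point).
#'
#' @param condition storage temperature, degC.
#' @param start_percent aggregate level at day 0.
#' @param slope percent aggregate gained per day.
#' @param days sampling days, default `c(0, 14, 28)`.
#' @param noise_sd percent, default 0.05.
#' @param seed RNG seed for noisy series.
#' @return an [aggregate_series].
#' @export
simulate_aggregate_series <- function(condition, start_percent, slope,
                                      days = c(0, 14, 28), noise_sd = 0.05,
                                      seed = NULL) {
  y <- start_percent + slope * days
  if (noise_sd > 0) {
    if (is.null(seed)) stop_input("seed required for noisy simulation")
    eps <- withr_rnorm(seed, length(y), noise_sd)
    eps[1] <- 0
    y <- y + eps
  }
  aggregate_series(condition, days, pmin(pmax(y, 0), 100))
}

#' Aggregate series CSV I/O
#' @param series an [aggregate_series].
#' @param path CSV path (`condition_C`, `day`, `percent_aggregate`).
#' @export
write_aggregate_csv <- function(series, path) {
  write.csv(data.frame(condition_C = series$condition, day = series$days,
                       percent_aggregate = series$percent_aggregate),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_aggregate_csv
#' @export
read_aggregate_csv <- function(path) {
  tab <- read.csv(path)
  aggregate_series(tab$condition_C[1], tab$day, tab$percent_aggregate)
}
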