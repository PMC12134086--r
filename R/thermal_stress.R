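#' Daily mean temperatures from a logger series
#'
#' Calendar-day (UTC) arithmetic means.  The logger interval is inferred
#' from the median timestamp spacing; days with fewer than half the
#' expected readings are flagged.
#'
#' @param series A `temperature_series` (data frame with `timestamp`,
#'   `temp_c`), timestamps strictly increasing.
#' @return Data frame: `date`, `daily_mean`, `n_readings`, `flagged`.
#' @export
daily_means <- function(series) {
  if (nrow(series) == 0L) stop("empty temperature series", call. = FALSE)
  ts <- series$timestamp
  if (is.unsorted(as.numeric(ts), strictly = TRUE)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  out_of_range <- series$temp_c < 10 | series$temp_c > 40
  if (any(out_of_range)) {
    warning(sum(out_of_range), " reading(s) outside the plausible 10-40 degC range",
            call. = FALSE)
  }
  day <- as.Date(ts, tz = "UTC")
  mean_by <- tapply(series$temp_c, day, mean)
  n_by <- tapply(series$temp_c, day, length)
  interval_min <- stats::median(diff(as.numeric(ts))) / 60
  expected <- 1440 / interval_min
  data.frame(
    date = as.Date(names(mean_by)),
    daily_mean = as.numeric(mean_by),
    n_readings = as.integer(n_by),
    flagged = as.integer(n_by) < expected / 2,
    row.names = NULL
  )
}

#' Bleaching threshold from the Maximum Monthly Mean
#'
#' NOAA convention: threshold = MMM + 1 deg C.
#'
#' @param mmm Maximum Monthly Mean temperature (deg C).
#' @return Threshold temperature (deg C).
#' @examples
#' bleaching_threshold(30.9)  # 31.9
#' @export
bleaching_threshold <- function(mmm) {
  if (!is.finite(mmm)) stop("'mmm' must be finite", call. = FALSE)
  mmm + 1.0
}

#' Degree Heating Weeks from daily mean temperatures
#'
#' NOAA convention on daily data: the daily hotspot is the anomaly above
#' the MMM when that anomaly is at least 1 deg C (else 0), and DHW on day
#' t is the hotspot sum over the trailing 84-day (12-week) window divided
#' by 7, in deg C-weeks.  Days before a full window is available have
#' undefined (`NA`) DHW; a series shorter than 84 days is flagged partial
#' rather than silently truncated.  Flagged or missing days are linearly
#' interpolated from neighbours when the gap is at most 2 days; longer
#' gaps leave the affected windows flagged.
#'
#' @param daily Output of [daily_means()] (or a data frame with `date`,
#'   `daily_mean`).
#' @param mmm Maximum Monthly Mean temperature (deg C); default 30.9.
#' @return Object of class `thermal_stress`: list with `mmm`, `threshold`,
#'   `daily` (data frame `date`, `daily_mean`, `hotspot`, `dhw`),
#'   `partial_window` flag and `max_dhw`.
#' @export
compute_dhw <- function(daily, mmm = 30.9) {
  if (!all(c("date", "daily_mean") %in% names(daily))) {
    stop("'daily' needs columns date, daily_mean", call. = FALSE)
  }
  d <- daily[order(daily$date), , drop = FALSE]
  # regularize to a complete day grid
  grid <- data.frame(date = seq(min(d$date), max(d$date), by = "day"))
  d <- merge(grid, d, by = "date", all.x = TRUE)
  bad <- is.na(d$daily_mean)
  if ("flagged" %in% names(d)) bad <- bad | (!is.na(d$flagged) & d$flagged)

  gap_flag <- FALSE
  if (any(bad)) {
    r <- rle(bad)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    x <- d$daily_mean
    x[bad] <- NA
    for (i in seq_along(r$values)) {
      if (!r$values[i]) next
      if (r$lengths[i] <= 2 && starts[i] > 1 && ends[i] < nrow(d)) {
        lo <- starts[i] - 1L; hi <- ends[i] + 1L
        w <- seq_len(r$lengths[i]) / (hi - lo)
        x[starts[i]:ends[i]] <- x[lo] * (1 - w) + x[hi] * w
      } else {
        gap_flag <- TRUE
      }
    }
    d$daily_mean <- x
  }

  anom <- d$daily_mean - mmm
  hotspot <- ifelse(!is.na(anom) & anom >= 1, anom, 0)
  hotspot[is.na(d$daily_mean)] <- NA
  n <- length(hotspot)
  partial <- n < 84
  if (partial) {
    warning("series shorter than the 84-day DHW window; DHW undefined throughout",
            call. = FALSE)
    dhw <- rep(NA_real_, n)
  } else {
    # trailing 84-day rolling sum / 7
    roll <- stats::filter(hotspot, rep(1, 84), sides = 1)
    dhw <- as.numeric(roll) / 7
  }
  structure(list(
    mmm = mmm,
    threshold = bleaching_threshold(mmm),
    daily = data.frame(date = d$date, daily_mean = d$daily_mean,
                       hotspot = hotspot, dhw = dhw),
    partial_window = partial || gap_flag,
    max_dhw = if (all(is.na(dhw))) NA_real_ else max(dhw, na.rm = TRUE)
  ), class = "thermal_stress")
}

#' @export
print.thermal_stress <- function(x, ...) {
  cat(sprintf("Thermal stress: MMM %.1f degC, bleaching threshold %.1f degC\n",
              x$mmm, x$threshold))
  cat(sprintf("  %d days; max DHW %.2f degC-weeks%s\n", nrow(x$daily),
              x$max_dhw, if (x$partial_window) " (partial window)" else ""))
  invisible(x)
}

#' First date the DHW series reaches a stress level
#'
#' @param result A `thermal_stress` object.
#' @param level Stress level in deg C-weeks (NOAA benchmarks: 4 =
#'   bleaching likely, 8 = mortality likely).
#' @return Earliest date with `dhw >= level`, or `NA` if never reached.
#' @export
first_exceedance <- function(result, level) {
  stopifnot(inherits(result, "thermal_stress"))
  dhw <- result$daily$dhw
  hit <- which(!is.na(dhw) & dhw >= level)
  if (!length(hit)) return(as.Date(NA))
  result$daily$date[hit[1L]]
}

#' Write thermal-stress artifacts
#'
#' @param result A `thermal_stress` object.
#' @param csv_path Path for the per-day CSV (date, daily_mean, hotspot, dhw).
#' @param json_path Optional path for a JSON summary (max DHW, first dates
#'   exceeding 4 and 8 deg C-weeks).
#' @return Invisibly, the paths written.
#' @export
write_thermal <- function(result, csv_path, json_path = NULL) {
  stopifnot(inherits(result, "thermal_stress"))
  utils::write.csv(result$daily, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      mmm = result$mmm,
      threshold = result$threshold,
      max_dhw = result$max_dhw,
      first_dhw4 = format(first_exceedance(result, 4)),
      first_dhw8 = format(first_exceedance(result, 8)),
      partial_window = result$partial_window
    ), json_path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  }
  invisible(c(csv = csv_path, json = json_path))
}
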