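#' @title Daily weather input
#' @description Reading and validation of daily weather series, relative
#'   humidity reconstruction from temperatures, and a seeded synthetic
#'   generator standing in for gridded observational datasets.
#' @name weather
NULL

#' Read a daily weather series from a delimited text file
#'
#' Expects a comma-separated file with a header naming at least `date`
#' (ISO-8601), `tmax`, and `tmin` (degrees C); an `rh` column (percent) is
#' optional and reconstructed with [rh_from_temps()] when absent. The mean
#' temperature `tmean = (tmax + tmin) / 2` is derived. Dates must be strictly
#' increasing with no gaps; violations are reported with row numbers.
#'
#' @param path Path to the file.
#' @param cell_id Identifier attached to the series (defaults to the file
#'   name).
#' @return A `weather_series`: data.frame with columns `date`, `tmax`,
#'   `tmin`, `tmean`, `rh`, and attributes `cell_id` and `provenance`.
#' @export
read_weather <- function(path, cell_id = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "tmax", "tmin")
  if (!all(need %in% names(df)))
    stop("weather file '", path, "' must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  dates <- as.Date(df$date)
  bad <- which(is.na(dates) | !is.finite(df$tmax) | !is.finite(df$tmin))
  if (length(bad))
    stop("weather file '", path, "': unparseable row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  dd <- diff(as.integer(dates))
  if (any(dd <= 0))
    stop("weather file '", path, "': dates not strictly increasing at row(s) ",
         paste(utils::head(which(dd <= 0) + 1L, 5), collapse = ", "), call. = FALSE)
  if (any(dd > 1)) {
    i <- which(dd > 1)[1]
    stop("weather file '", path, "': gap after ", dates[i],
         " (missing ", dates[i] + 1, ")", call. = FALSE)
  }
  bad_t <- which(df$tmin > df$tmax)
  if (length(bad_t))
    stop("weather file '", path, "': tmin > tmax at row(s) ",
         paste(utils::head(bad_t, 5), collapse = ", "), call. = FALSE)
  tmean <- (df$tmax + df$tmin) / 2
  rh_given <- "rh" %in% names(df) && !all(is.na(df$rh))
  rh <- if (rh_given) df$rh else rh_from_temps(tmean, df$tmin)
  out <- data.frame(date = dates, tmax = df$tmax, tmin = df$tmin,
                    tmean = tmean, rh = pmin(100, pmax(0, rh)))
  structure(out, class = c("weather_series", "data.frame"),
            cell_id = cell_id,
            provenance = paste0("file:", path, if (!rh_given) " (rh reconstructed)"))
}

#' Reconstruct relative humidity from temperatures
#'
#' Assumes the daily minimum temperature approximates the dew point:
#' `RH = 100 * em / es` with saturated vapor pressure
#' `es = 610.78 exp(17.269 T / (237.3 + T))` evaluated at `tmean` and the
#' ambient vapor pressure `em` at `tmin`, clamped to \[0, 100\].
#'
#' @param tmean Mean daily temperature, C (vectorized).
#' @param tmin Minimum daily temperature, C (vectorized).
#' @return Relative humidity, percent.
#' @examples
#' rh_from_temps(20, 10)  # ~52.5
#' @export
rh_from_temps <- function(tmean, tmin) {
  if (any(tmin > tmean))
    stop("rh_from_temps: tmin must not exceed tmean", call. = FALSE)
  svp <- function(T) 610.78 * exp(17.269 * T / (237.3 + T))
  pmin(100, pmax(0, 100 * svp(tmin) / svp(tmean)))
}

# stated regimes: annual mean and amplitude of the temperature sinusoid (C),
# diurnal range (C), RH mean/amplitude (%), RH phase relative to temperature
.synth_profiles <- list(
  tropical  = list(t_mean = 26, t_amp = 3,  diurnal = 8,  rh_mean = 75, rh_amp = 10, rh_antiphase = FALSE),
  temperate = list(t_mean = 12, t_amp = 10, diurnal = 10, rh_mean = 70, rh_amp = 15, rh_antiphase = TRUE),
  desert    = list(t_mean = 25, t_amp = 10, diurnal = 14, rh_mean = 25, rh_amp = 10, rh_antiphase = TRUE)
)

#' Generate a seeded synthetic daily weather series
#'
#' Daily mean temperature follows a sinusoidal seasonal cycle with Gaussian
#' noise, `tmean(t) = m + A sin(2 pi (t - t0) / 365) + e_t`, with `tmax/tmin =
#' tmean +/- diurnal/2`. Relative humidity follows its own seasonal cycle,
#' anti-phased with temperature for the temperate and desert regimes (dry
#' summers), plus noise, clamped to \[5, 100\]. Profiles: `tropical`
#' (m = 26 C, A = 3 C), `temperate` (m = 12 C, A = 10 C), `desert` (m = 25 C,
#' A = 10 C, RH mean 25%). Fully reproducible for a given `seed`.
#'
#' @param profile `"tropical"`, `"temperate"`, `"desert"`, or `"custom"`.
#' @param years Number of 365-day years (>= 1).
#' @param seed Integer seed for the noise.
#' @param noise_sd SD of daily temperature noise, C (default 2).
#' @param rh_noise_sd SD of daily RH noise, percent (default 5).
#' @param custom For `profile = "custom"`, a list like the built-in profiles
#'   (`t_mean`, `t_amp`, `diurnal`, `rh_mean`, `rh_amp`, `rh_antiphase`).
#' @param start Start date (default `"2001-01-01"`).
#' @param cell_id Identifier attached to the series.
#' @return A `weather_series` (see [read_weather()]).
#' @export
synth_weather <- function(profile = c("tropical", "temperate", "desert", "custom"),
                          years = 1, seed = 1, noise_sd = 2, rh_noise_sd = 5,
                          custom = NULL, start = "2001-01-01",
                          cell_id = paste0("synthetic:", profile[1], ":", seed)) {
  profile <- match.arg(profile)
  stopifnot(years >= 1)
  p <- if (identical(profile, "custom")) {
    stopifnot(is.list(custom))
    custom
  } else {
    .synth_profiles[[profile]]
  }
  n <- as.integer(365 * years)
  t <- seq_len(n)
  phase <- sin(2 * pi * (t - 110) / 365)   # warmest ~day 200 (N hemisphere)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  tmean <- p$t_mean + p$t_amp * phase + stats::rnorm(n, 0, noise_sd)
  rh_phase <- if (isTRUE(p$rh_antiphase)) -phase else phase
  rh <- p$rh_mean + p$rh_amp * rh_phase + stats::rnorm(n, 0, rh_noise_sd)
  out <- data.frame(date = as.Date(start) + t - 1L,
                    tmax = tmean + p$diurnal / 2,
                    tmin = tmean - p$diurnal / 2,
                    tmean = tmean,
                    rh = pmin(100, pmax(5, rh)))
  structure(out, class = c("weather_series", "data.frame"),
            cell_id = cell_id,
            provenance = paste0("synthetic:", profile, ":", seed))
}

#' Write a weather series to CSV
#'
#' Round-trips through [read_weather()] (the derived `tmean` is recomputed on
#' read).
#'
#' @param series A `weather_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weather <- function(series, path) {
  utils::write.csv(
    data.frame(date = series$date, tmax = series$tmax, tmin = series$tmin,
               rh = series$rh),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
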