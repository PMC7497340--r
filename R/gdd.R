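# Growing-degree-day (thermal time) axis.

#' Daily growing degree days
#'
#' GDD for one day is `(Tmax' + Tmin')/2 - 10`, where both temperatures are
#' first floored at the 10 degree C base temperature and capped at 30 degree
#' C. The result is therefore always in \[0, 20\].
#'
#' @param tmax,tmin daily maximum / minimum temperature (degree C); vectors
#'   are accepted elementwise.
#' @return Numeric vector of daily GDD values.
#' @examples
#' daily_gdd(35, 5)   # 10
#' daily_gdd(8, 4)    # 0
#' daily_gdd(28, 16)  # 12
#' @export
daily_gdd <- function(tmax, tmin) {
  if (length(tmax) != length(tmin))
    stop("tmax and tmin must have equal length", call. = FALSE)
  if (any(tmin > tmax))
    stop("tmin greater than tmax", call. = FALSE)
  clamp <- function(x) pmin(pmax(x, 10), 30)
  (clamp(tmax) + clamp(tmin)) / 2 - 10
}

#' Cumulative growing degree days between two dates
#'
#' Sums [daily_gdd()] from the planting date through the target date,
#' inclusive of both end days.
#'
#' @param weather data.frame with columns `date` (Date or coercible), `tmin`,
#'   `tmax`.
#' @param planting_date,target_date dates delimiting the accumulation window.
#' @return Cumulative GDD (numeric scalar).
#' @export
cumulative_gdd <- function(weather, planting_date, target_date) {
  check_columns(weather, c("date", "tmin", "tmax"), "weather table")
  planting_date <- as.Date(planting_date)
  target_date <- as.Date(target_date)
  if (target_date < planting_date)
    stop("target_date precedes planting_date", call. = FALSE)
  dates <- as.Date(weather$date)
  wanted <- seq(planting_date, target_date, by = "day")
  idx <- match(wanted, dates)
  if (anyNA(idx))
    stop(sprintf("weather table does not cover %d day(s) in [%s, %s]",
                 sum(is.na(idx)), format(planting_date), format(target_date)),
         call. = FALSE)
  sum(daily_gdd(weather$tmax[idx], weather$tmin[idx]))
}

#' Cumulative GDD schedule for a set of flight dates
#'
#' @param weather daily weather table (`date`, `tmin`, `tmax`).
#' @param planting_date planting date.
#' @param flight_dates vector of imaging dates.
#' @return data.frame with `date` and cumulative `gdd` per flight.
#' @export
gdd_schedule <- function(weather, planting_date, flight_dates) {
  flight_dates <- as.Date(flight_dates)
  data.frame(date = flight_dates,
             gdd = vapply(flight_dates, function(d)
               cumulative_gdd(weather, planting_date, d), numeric(1)))
}
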