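#' Read a daily temperature forcing series
#'
#' Reads a delimited text file (comma or tab, autodetected) with a date (or
#' day-offset) column and a temperature column, and interpolates it linearly
#' onto a gap-free 1-day grid starting at day 0. Internal gaps are filled by
#' linear interpolation; missing values at the ends cannot be interpolated
#' and are an error.
#'
#' @param path Path to the delimited file.
#' @param date_col,temp_col Column names holding dates (ISO dates or numeric
#'   day offsets) and water temperature in degrees Celsius.
#' @return A `deb_forcing` tibble with columns `day` (0-based, 1-day steps)
#'   and `temp_c`, carrying a `start_doy` attribute (day of year of day 0,
#'   when dates were calendar dates) and a `source` attribute.
#' @export
read_forcing <- function(path, date_col = "date", temp_col = "temp_C") {
  line1 <- readLines(path, n = 1)
  sep <- if (grepl("\t", line1)) "\t" else ","
  df <- utils::read.delim(path, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!date_col %in% names(df)) {
    stop("date column `", date_col, "` not found in ", path, call. = FALSE)
  }
  if (!temp_col %in% names(df)) {
    stop("temperature column `", temp_col, "` not found in ", path,
         call. = FALSE)
  }
  raw_dates <- df[[date_col]]
  start_doy <- NA_integer_
  if (is.numeric(raw_dates)) {
    day <- raw_dates - min(raw_dates)
  } else {
    parsed <- tryCatch(as.Date(as.character(raw_dates)),
                       error = function(e) as.Date(rep(NA, length(raw_dates))))
    if (any(is.na(parsed))) stop("unparseable dates in ", path, call. = FALSE)
    day <- as.numeric(parsed - min(parsed))
    start_doy <- as.integer(strftime(min(parsed), "%j"))
  }
  temp <- as.numeric(df[[temp_col]])
  if (all(is.na(temp))) stop("temperature column is entirely missing",
                             call. = FALSE)
  ord <- order(day)
  day <- day[ord]; temp <- temp[ord]
  if (is.na(temp[1]) || is.na(temp[length(temp)])) {
    stop("leading/trailing missing temperatures cannot be interpolated",
         call. = FALSE)
  }
  keep <- !is.na(temp)
  grid <- seq(0, max(day))
  temp_i <- if (length(grid) == 1) temp[keep][1] else
    stats::approx(day[keep], temp[keep], xout = grid)$y
  new_forcing(grid, temp_i, source = "file", start_doy = start_doy)
}

#' Synthetic seasonal temperature profile
#'
#' A deterministic annual sinusoid standing in for coastal sea-surface
#' temperature: `T(t) = (T_min + T_max)/2 + (T_max - T_min)/2 *
#' cos(2*pi*(doy - day_of_peak)/365)`, evaluated at daily resolution over the
#' simulation window. With the defaults (16-29 degC, peak on day-of-year 227,
#' window starting May 1) it emulates a Yellow Sea pond culture season.
#'
#' @param t_min,t_max Annual minimum and maximum temperature (degC);
#'   `t_min < t_max` is required.
#' @param day_of_peak Day of year on which the sinusoid peaks.
#' @param horizon Length of the series in days (the series covers days
#'   `0..horizon`).
#' @param start_day_of_year Day of year mapped to simulation day 0
#'   (121 = May 1 in a non-leap year).
#' @return A `deb_forcing` tibble (see [read_forcing()]).
#' @examples
#' f <- seasonal_forcing(horizon = 180)
#' range(f$temp_c)
#' @export
seasonal_forcing <- function(t_min = 16, t_max = 29, day_of_peak = 227,
                             horizon = 185, start_day_of_year = 121) {
  if (!(t_min < t_max)) stop("t_min must be below t_max", call. = FALSE)
  if (horizon < 1) stop("horizon must be at least 1 day", call. = FALSE)
  day <- seq(0, horizon)
  doy <- start_day_of_year + day
  temp <- (t_min + t_max) / 2 +
    (t_max - t_min) / 2 * cos(2 * pi * (doy - day_of_peak) / 365)
  new_forcing(day, temp, source = "synthetic",
              start_doy = as.integer(start_day_of_year))
}

new_forcing <- function(day, temp_c, source, start_doy = NA_integer_) {
  if (any(temp_c <= -2 | temp_c >= 40)) {
    stop("temperatures outside the (-2, 40) degC sanity band", call. = FALSE)
  }
  out <- tibble::tibble(day = as.numeric(day), temp_c = as.numeric(temp_c))
  attr(out, "source") <- source
  attr(out, "start_doy") <- start_doy
  class(out) <- c("deb_forcing", class(out))
  out
}

#' Arrhenius temperature correction
#'
#' Dimensionless factor `c(T) = exp(TA/T_ref - TA/T)` scaling all
#' physiological rates from the reference temperature to the ambient
#' temperature. Equals 1 at `T_ref` and increases strictly with `T` for
#' positive `TA`. A single `TA` corrects every rate in the model
#' (assimilation, mobilization, maintenance and gonad conversion).
#'
#' @param temp_k Absolute temperature(s), K.
#' @param p A `deb_params` object supplying `TA` and `T_ref`.
#' @return Numeric vector of correction factors.
#' @examples
#' arrhenius_factor(298.15, deb_params())  # 1
#' @export
arrhenius_factor <- function(temp_k, p = deb_params()) {
  if (any(temp_k <= 0)) {
    stop("absolute temperature must be positive", call. = FALSE)
  }
  exp(p$TA / p$T_ref - p$TA / temp_k)
}

# temperature at arbitrary simulation times, linear between daily knots
forcing_at <- function(forcing, t) {
  if (nrow(forcing) == 1) return(rep(forcing$temp_c, length(t)))
  stats::approx(forcing$day, forcing$temp_c, xout = t, rule = 1)$y
}

#' Write a forcing series to delimited text
#'
#' @param forcing A `deb_forcing` tibble.
#' @param path Output path; written as `date,temp_C` CSV with numeric day
#'   offsets in the date column.
#' @return `path`, invisibly.
#' @export
write_forcing <- function(forcing, path) {
  utils::write.csv(data.frame(date = forcing$day, temp_C = forcing$temp_c),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
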