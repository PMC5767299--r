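#' Climate profiles
#'
#' A climate profile describes the sole external forcing factor of the
#' simulator: the average daily temperature. Two kinds are supported:
#' `"constant"` (the same temperature every day, used for laboratory-like
#' mark-release scenarios) and `"sinusoidal"` (a smooth skewed annual curve
#' attaining a prescribed minimum, maximum and annual mean over a 365-day
#' year).
#'
#' The sinusoidal curve is
#' \deqn{T(d) = t_{mean} + c_1 \cos\theta + c_2 \cos 2\theta, \quad
#'       \theta = 2\pi (d - d_{peak}) / 365,}
#' with \eqn{c_1, c_2} solved so that the annual maximum equals `t_max`
#' (attained at `d_peak`, mid-summer) and the annual minimum equals `t_min`.
#' Because both harmonics average to zero over a whole year, the annual mean
#' equals `t_mean` exactly. Years are 365 days; leap days are ignored and
#' multi-year runs repeat the annual pattern with period 365.
#'
#' @param kind `"constant"` or `"sinusoidal"`.
#' @param t_const Constant daily temperature (degrees C), constant kind only.
#' @param t_min,t_max,t_mean Annual minimum, maximum and mean (degrees C),
#'   sinusoidal kind only.
#' @param d_peak Day of year of the warmest day (default 210, mid-summer).
#' @return An object of class `medfly_climate`.
#' @examples
#' daily_temperature(climate_const(25), 40)
#' range(temperature_series(climate_med(), 1:365)$temp_c)
#' @export
climate_profile <- function(kind = c("constant", "sinusoidal"),
                            t_const = NULL,
                            t_min = NULL, t_max = NULL, t_mean = NULL,
                            d_peak = 210) {
  kind <- match.arg(kind)
  if (kind == "constant") {
    stopifnot(is.numeric(t_const), length(t_const) == 1L, is.finite(t_const))
    prof <- list(kind = "constant", t_const = t_const,
                 t_min = t_const, t_max = t_const, t_mean = t_const,
                 period_days = 365L)
  } else {
    stopifnot(is.numeric(t_min), is.numeric(t_max), is.numeric(t_mean))
    if (!(t_min <= t_mean && t_mean <= t_max)) {
      stop("climate profile requires t_min <= t_mean <= t_max", call. = FALSE)
    }
    # c1 + c2 = t_max - t_mean (peak), -c1 + c2 = t_min - t_mean (trough).
    c1 <- (t_max - t_min) / 2
    c2 <- (t_max + t_min) / 2 - t_mean
    if (abs(c2) >= c1 / 4 && c1 > 0) {
      # interior extrema would appear; the skew the anchors imply is too strong
      stop("t_mean too far from (t_min + t_max)/2 for a smooth annual curve",
           call. = FALSE)
    }
    prof <- list(kind = "sinusoidal", t_const = NULL,
                 t_min = t_min, t_max = t_max, t_mean = t_mean,
                 c1 = c1, c2 = c2, d_peak = d_peak, period_days = 365L)
  }
  structure(prof, class = "medfly_climate")
}

#' @rdname climate_profile
#' @export
climate_med <- function() {
  climate_profile("sinusoidal", t_min = 11, t_max = 27, t_mean = 20)
}

#' @rdname climate_profile
#' @param temp Constant temperature (degrees C).
#' @export
climate_const <- function(temp) climate_profile("constant", t_const = temp)

#' @rdname climate_profile
#' @export
climate_opt <- function() {
  climate_profile("sinusoidal", t_min = 20, t_max = 25, t_mean = 22.9)
}

#' @export
print.medfly_climate <- function(x, ...) {
  if (x$kind == "constant") {
    cat(sprintf("<medfly_climate> constant %.1f C\n", x$t_const))
  } else {
    cat(sprintf("<medfly_climate> sinusoidal min %.1f / mean %.1f / max %.1f C (peak day %d)\n",
                x$t_min, x$t_mean, x$t_max, as.integer(x$d_peak)))
  }
  invisible(x)
}

#' Average daily temperature for a day of year
#'
#' @param profile A [climate_profile()].
#' @param day_of_year Day index (>= 1); days beyond 365 wrap around the
#'   annual cycle.
#' @return Temperature in degrees C (vectorised over `day_of_year`).
#' @export
daily_temperature <- function(profile, day_of_year) {
  stopifnot(inherits(profile, "medfly_climate"))
  if (any(day_of_year < 1)) stop("day_of_year must be >= 1", call. = FALSE)
  d <- ((day_of_year - 1) %% 365) + 1
  if (profile$kind == "constant") {
    return(rep(profile$t_const, length(d)))
  }
  th <- 2 * pi * (d - profile$d_peak) / 365
  profile$t_mean + profile$c1 * cos(th) + profile$c2 * cos(2 * th)
}

#' Daily temperature series as a tibble
#'
#' @inheritParams daily_temperature
#' @param days Integer vector of simulation days (default one year).
#' @return A tibble with columns `day` and `temp_c`.
#' @export
temperature_series <- function(profile, days = 1:365) {
  tibble::tibble(day = as.integer(days),
                 temp_c = daily_temperature(profile, days))
}

#' Temperature-to-activity scalar
#'
#' Maps average daily temperature to a single multiplier in \[0, 1\] shared
#' by adult activity-dependent processes (movement intensity, realized daily
#' fecundity). The scalar is 1 on the optimal plateau 20--25 C, falls
#' linearly to 0 at 11 C on the cold side (winter arrest of fly activity),
#' and declines linearly on the hot side to 0.6 at 32 C (hot summer days
#' only mildly depress activity) and onward to 0 at 45 C.
#'
#' @param temperature Temperature in degrees C (vectorised).
#' @return Activity multiplier in \[0, 1\].
#' @examples
#' activity_scalar(c(11, 16, 22.5, 27, 32))
#' @export
activity_scalar <- function(temperature) {
  stopifnot(all(is.finite(temperature)))
  t <- temperature
  a <- numeric(length(t))
  cold <- t > 11 & t < 20
  a[cold] <- (t[cold] - 11) / 9
  a[t >= 20 & t <= 25] <- 1
  hot <- t > 25 & t <= 32
  a[hot] <- 1 - 0.4 * (t[hot] - 25) / 7
  vhot <- t > 32
  a[vhot] <- pmax(0, 0.6 * (1 - (t[vhot] - 32) / 13))
  a
}
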