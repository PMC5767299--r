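#' Default host and non-host trait table
#'
#' Four host tree types jointly provide suitable fruit through most of the
#' year; a fifth "non-host" column describes trees that attract flies mildly
#' but bear no usable fruit. Traits per host: relative incidence among host
#' sectors (always 1:1:1:1), suitability for immature development (an
#' immature-survival multiplier), seasonal attractiveness bounds (percent),
#' length of the fruit-availability window (days), harvest day of year and
#' harvest accuracy (fraction of ripe fruit removed at harvest).
#'
#' @return A tibble with one row per host type plus a `nonhost` row.
#' @examples
#' host_table()
#' @export
host_table <- function() {
  tibble::tibble(
    host_id            = c(1L, 2L, 3L, 4L, NA_integer_),
    host               = c("host1", "host2", "host3", "host4", "nonhost"),
    relative_incidence = c(0.25, 0.25, 0.25, 0.25, NA),
    suitability        = c(0.60, 0.70, 0.90, 0.80, 0),
    attractiveness_max = c(70, 90, 100, 65, 29),
    attractiveness_min = c(25, 29, 28, 23, 13),
    fruit_availability = c(80, 65, 70, 85, NA),
    harvest_day        = c(90L, 170L, 250L, 350L, NA_integer_),
    harvest_accuracy   = c(0.65, 0.75, 0.80, 0.70, NA)
  )
}

# Signed day offset from a host's harvest day, wrapped to (-182.5, 182.5].
.day_offset <- function(day, harvest_day) {
  ((day - harvest_day + 182.5) %% 365) - 182.5
}

#' Daily host phenology state
#'
#' Attractiveness and normalised fruit availability of a host on a given day
#' of year. Both follow an asymmetric bell around the harvest day: a slow
#' half-Gaussian rise spanning the fruit-availability window before
#' harvest, and a much faster half-Gaussian decline (30% of the window)
#' over the unpicked remainder after it. With the four packaged hosts the
#' bells overlap so that fruit is available somewhere on every day of the
#' year (the continuous host succession of sub-tropical horticulture). Attractiveness moves between the host's seasonal minimum and
#' maximum; the fruit fraction is the normalised bell itself (0 outside the
#' window, 1 at the harvest-day peak). Harvest removal is applied separately
#' by [apply_harvest()]. Non-host trees have no fruit and an attractiveness
#' oscillating mildly within 13--29% over the season.
#'
#' @param host One row of [host_table()] (a list or one-row data frame).
#' @param day_of_year Day of year (vectorised; wraps at 365).
#' @return A tibble with columns `day`, `attractiveness` (percent) and
#'   `fruit_fraction` (0--1, before harvest removal).
#' @examples
#' h3 <- dplyr::filter(host_table(), host == "host3")
#' daily_host_state(h3, h3$harvest_day)  # in-window peak
#' @export
daily_host_state <- function(host, day_of_year) {
  host <- as.list(host)
  d <- ((day_of_year - 1) %% 365) + 1
  if (is.na(host$host_id %||% NA)) {
    att <- 21 + 8 * sin(2 * pi * d / 365)
    return(tibble::tibble(day = d, attractiveness = att, fruit_fraction = 0))
  }
  bell <- .phenology_bell(d, host$harvest_day, host$fruit_availability)
  att <- host$attractiveness_min +
    (host$attractiveness_max - host$attractiveness_min) * bell
  tibble::tibble(day = d, attractiveness = att, fruit_fraction = bell)
}

# Normalised asymmetric bell: 0 outside the window, 1 at harvest day.
# Rise span = the full availability window before harvest, fall span
# 0.3 * window after; each side a half-Gaussian truncated at 2 sigma
# (= its span), so fruit is genuinely available through the whole window.
.phenology_bell <- function(day, harvest_day, window) {
  off <- .day_offset(day, harvest_day)
  rise <- window
  fall <- 0.3 * window
  b <- numeric(length(off))
  up <- off >= -rise & off <= 0
  b[up] <- exp(-0.5 * (2 * off[up] / rise)^2)
  dn <- off > 0 & off <= fall
  b[dn] <- exp(-0.5 * (2 * off[dn] / fall)^2)
  b
}
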