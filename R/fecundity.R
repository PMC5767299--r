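FECUNDITY_LIFETIME <- 742   # lifetime egg envelope, eggs/female
FECUNDITY_DAILY_MAX <- 16   # daily egg ceiling

#' Age-dependent maximum daily fecundity envelope
#'
#' Maximum eggs a female can lay per day as a function of physiological
#' age: zero while young (ages 1--10), a linear rise to the 16-egg daily
#' ceiling at age 20, a plateau at 16 through the peak ages 20--35, and a
#' linear decline whose endpoint is solved (deterministically, cached) so
#' that the envelope summed over integer ages equals the 742-egg lifetime
#' total. Realized daily fecundity is a clipped normal draw around this
#' envelope scaled by the temperature activity scalar, see
#' [potential_daily_fecundity()].
#'
#' @param phys_age Physiological age in optimal-equivalent days (vectorised).
#' @return Maximum eggs/day (0--16).
#' @examples
#' sum(fecundity_envelope(1:170))  # 742
#' @export
fecundity_envelope <- function(phys_age) {
  L <- .fecundity_tail_length()
  a <- phys_age
  f <- numeric(length(a))
  rise <- a > 10 & a < 20
  f[rise] <- FECUNDITY_DAILY_MAX * (a[rise] - 10) / 10
  f[a >= 20 & a <= 35] <- FECUNDITY_DAILY_MAX
  fall <- a > 35 & a < 35 + L
  f[fall] <- FECUNDITY_DAILY_MAX * (1 - (a[fall] - 35) / L)
  pmax(f, 0)
}

.fecundity_tail_length <- function() {
  if (!is.null(.calib_env$fec_tail)) return(.calib_env$fec_tail)
  base <- function(L) {
    a <- 1:MAX_PHYS_AGE
    f <- numeric(MAX_PHYS_AGE)
    rise <- a > 10 & a < 20
    f[rise] <- FECUNDITY_DAILY_MAX * (a[rise] - 10) / 10
    f[a >= 20 & a <= 35] <- FECUNDITY_DAILY_MAX
    fall <- a > 35 & a < 35 + L
    f[fall] <- FECUNDITY_DAILY_MAX * (1 - (a[fall] - 35) / L)
    sum(f)
  }
  L <- stats::uniroot(function(L) base(L) - FECUNDITY_LIFETIME,
                      c(10, 130), tol = 1e-10)$root
  .calib_env$fec_tail <- L
  L
}

FECUNDITY_REALIZATION <- 0.9   # field realization of the lab envelope
OOGENESIS_EXPONENT <- 2.5      # temperature sensitivity of daily egg output

#' Potential daily fecundity draw
#'
#' Integer egg load a female is ready to lay today: zero for young
#' (pre-maturity) females, otherwise a normal draw (SD 2) centred on the
#' age-dependent maximum envelope scaled by three factors, rounded and
#' clipped to \[0, 16\], and capped so the cumulative lifetime total never
#' exceeds 742. The factors: the `realization` fraction (on-farm realized
#' fecundity is well below the laboratory maximum envelope: host finding,
#' feeding interruptions and egg resorption), the oogenesis pace (egg
#' maturation inside the female follows the maturation temperature clock,
#' relative to 25 C: raised to a sensitivity exponent of 2.5 on the cool
#' side, where egg output falls more steeply than maturation itself, and
#' entering linearly on the warm side, where the metabolic speed-up is
#' largely offset by the declining activity scalar -- the mild hot-summer
#' barrier),
#' and the activity scalar (hot days mildly depress oviposition activity).
#' The realization fraction and the sensitivity exponent are the two free
#' demographic constants, calibrated once against the propagule invasion
#' experiments and frozen.
#'
#' @param phys_age Physiological ages (vectorised over females).
#' @param temperature Degrees C (scalar, today's mean).
#' @param cumulative_eggs Eggs already laid by each female.
#' @param sd Daily individual variation (SD of the normal draw).
#' @param realization Field-realization fraction of the maximum envelope.
#' @return Integer egg counts.
#' @export
potential_daily_fecundity <- function(phys_age, temperature, cumulative_eggs = 0,
                                      sd = 2,
                                      realization = FECUNDITY_REALIZATION) {
  n <- length(phys_age)
  pace <- maturation_rate(temperature) / maturation_rate(25)
  oog <- ifelse(pace < 1, pace^OOGENESIS_EXPONENT, pace)
  mu <- realization * fecundity_envelope(phys_age) *
    activity_scalar(temperature) * oog
  eggs <- round(stats::rnorm(n, mu, sd))
  eggs <- pmin(FECUNDITY_DAILY_MAX, pmax(0, eggs))
  eggs[phys_age < MATURITY_AGE] <- 0
  as.integer(pmin(eggs, pmax(0, FECUNDITY_LIFETIME - cumulative_eggs)))
}

#' Crowding factor for oviposition
#'
#' Egg laying is unaffected at low to moderate sector infestation and
#' declines linearly beyond 30% infestation, to 0.5 at full infestation:
#' `1 - 0.5 * max(0, infestation - 0.3) / 0.7`.
#'
#' @param infestation Sector fruit-infestation fraction in \[0, 1\].
#' @return Multiplier in \[0.5, 1\].
#' @export
crowding_factor <- function(infestation) {
  1 - 0.5 * pmax(0, infestation - 0.3) / 0.7
}

#' Realize oviposition into a sector
#'
#' Eggs are laid only where fruit is available; the realized clutch is a
#' binomial thinning of the potential egg load by a fruit-availability
#' acceptance that saturates (full clutch once the sector's fruit fraction
#' reaches 30% of peak, proportionally fewer below) times the crowding
#' factor.
#'
#' @param potential_eggs Integer potential egg loads (vectorised).
#' @param fruit_fraction Sector fruit fractions in \[0, 1\].
#' @param infestation Sector infestation fractions in \[0, 1\].
#' @return Integer realized egg counts.
#' @export
oviposit <- function(potential_eggs, fruit_fraction, infestation = 0) {
  stopifnot(all(potential_eggs >= 0))
  acc <- pmin(1, pmax(0, fruit_fraction) / 0.3)
  p <- acc * crowding_factor(infestation)
  laid <- stats::rbinom(length(potential_eggs), potential_eggs, pmax(0, p))
  laid[fruit_fraction <= 0] <- 0L
  as.integer(laid)
}
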