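#' Immature stage parameters
#'
#' Temperature-dependent duration ranges (days) and survival ranges
#' (fractions) for the three immature stages, plus the combined in-soil
#' extrinsic mortality applied at pupal emergence. Durations attain their
#' short bound at the warm anchor (30 C) and their long bound at the cool
#' anchor (13 C); development is suspended below 11 C.
#'
#' @return A tibble with one row per stage.
#' @export
stage_params <- function() {
  tibble::tibble(
    stage        = c("egg", "larva", "pupa"),
    duration_min = c(3, 8, 9),
    duration_max = c(11, 55, 67),
    survival_min = c(0.60, 0.19, 0.26),
    survival_max = c(0.90, 0.80, 0.70)
  )
}

IN_SOIL_MORTALITY <- 0.30   # extrinsic in-soil loss at pupal emergence
DEV_T_COLD <- 13            # cool anchor: slowest development
DEV_T_WARM <- 30            # warm anchor: fastest development
DEV_T_CUTOFF <- 11          # below this, development is suspended
MATURITY_AGE <- 11          # physiological age at onset of maturity
MAX_PHYS_AGE <- 170         # senescence truncation age, days
MEAN_LIFESPAN <- 79.1       # intrinsic mean lifespan at optimum, days

#' Temperature-dependent stage duration
#'
#' Duration interpolates linearly in temperature between the cool anchor
#' (13 C, the long bound) and the warm anchor (30 C, the short bound),
#' clamped at the short bound above 30 C; below 11 C development is
#' suspended (`Inf`). Under fluctuating temperatures the engine accumulates
#' daily increments `1/stage_duration` (rate summation) until a stage
#' completes.
#'
#' @param stage `"egg"`, `"larva"` or `"pupa"`.
#' @param temperature Degrees C (vectorised).
#' @return Duration in days (possibly `Inf`).
#' @examples
#' stage_duration("egg", c(13, 30))   # 11, 3
#' stage_duration("pupa", 21.5)       # 38
#' @export
stage_duration <- function(stage, temperature) {
  p <- stage_params()
  i <- match(stage, p$stage)
  if (any(is.na(i))) stop("unknown stage: ", stage, call. = FALSE)
  dmin <- p$duration_min[i]; dmax <- p$duration_max[i]
  t <- pmin(temperature, DEV_T_WARM)
  d <- dmax + (t - DEV_T_COLD) / (DEV_T_WARM - DEV_T_COLD) * (dmin - dmax)
  d[temperature < DEV_T_CUTOFF] <- Inf
  d
}

#' Temperature-dependent stage survival
#'
#' Transition survival varies linearly across its range: at the minimum
#' bound at 13 C, rising to the maximum bound at the start of the optimal
#' plateau (20 C), flat across 20--25 C, and declining linearly back toward
#' the minimum bound by 36.5 C (heat stress degrades in-fruit and in-soil
#' survival more slowly than cold).
#'
#' @inheritParams stage_duration
#' @return Survival fraction.
#' @export
stage_survival <- function(stage, temperature) {
  p <- stage_params()
  i <- match(stage, p$stage)
  if (any(is.na(i))) stop("unknown stage: ", stage, call. = FALSE)
  smin <- p$survival_min[i]; smax <- p$survival_max[i]
  t <- temperature
  f <- numeric(length(t) * 0 + max(length(t), length(i)))
  t <- rep_len(t, length(f)); smin <- rep_len(smin, length(f))
  smax <- rep_len(smax, length(f))
  f[] <- smin
  cold <- t > 13 & t < 20
  f[cold] <- (smin + (smax - smin) * (t - 13) / 7)[cold]
  f[t >= 20 & t <= 25] <- smax[t >= 20 & t <= 25]
  hot <- t > 25 & t < 36.5
  f[hot] <- (smax - (smax - smin) * (t - 25) / 11.5)[hot]
  pmax(f, smin)
}

# ---- Gompertz senescence --------------------------------------------------

# Calibrations are deterministic solves; cache them per session.
.calib_env <- new.env(parent = emptyenv())

#' Calibrated Gompertz senescence parameters
#'
#' Daily intrinsic death probability at the optimal temperature is
#' \eqn{h(t) = \min(1, a e^{b t})} at adult age `t` days, with
#' \eqn{a = e^{-170 b}} so that the hazard reaches exactly 1 at the
#' truncation age of 170 days (no fly outlives it), and the shape `b`
#' solved so that the mean of the induced lifespan distribution is 79.1
#' days. The solve is deterministic and cached.
#'
#' @return A list with elements `a`, `b`, `truncation_age`, `mean_lifespan`.
#' @export
gompertz_params <- function() {
  if (!is.null(.calib_env$gompertz)) return(.calib_env$gompertz)
  mean_ls <- function(b) {
    h <- pmin(1, exp(-MAX_PHYS_AGE * b) * exp(b * seq_len(MAX_PHYS_AGE)))
    sum(c(1, cumprod(1 - h)[seq_len(MAX_PHYS_AGE - 1L)]))
  }
  b <- stats::uniroot(function(b) mean_ls(b) - MEAN_LIFESPAN,
                      c(1e-4, 0.5), tol = 1e-12)$root
  out <- list(a = exp(-MAX_PHYS_AGE * b), b = b,
              truncation_age = MAX_PHYS_AGE, mean_lifespan = mean_ls(b))
  .calib_env$gompertz <- out
  out
}

#' Intrinsic (senescence) daily death probability
#'
#' The Gompertz daily hazard at a given adult age, scaled by the
#' temperature-dependent senescence multiplier [senescence_multiplier()]
#' and capped at 1. At 170 days the hazard is 1 regardless of temperature.
#'
#' @param age Adult age in days (>= 0, vectorised).
#' @param temperature Degrees C (default the 22.5 C optimum, multiplier 1).
#' @return Daily death probability in \[0, 1\].
#' @examples
#' intrinsic_hazard(c(10, 50, 170))
#' @export
intrinsic_hazard <- function(age, temperature = 22.5) {
  if (any(age < 0)) stop("age must be >= 0", call. = FALSE)
  g <- gompertz_params()
  k <- senescence_multiplier(temperature)
  h <- pmin(1, k * g$a * exp(g$b * age))
  h[age >= MAX_PHYS_AGE] <- 1
  h
}

#' Intrinsic survival curve at the optimum
#'
#' Probability of surviving senescence beyond a given adult age at the
#' optimal temperature with no extrinsic mortality.
#'
#' @param age Adult age in days (vectorised, interpolated between integer days).
#' @return Survival probability; 0 beyond 170 days.
#' @export
intrinsic_survival <- function(age) {
  g <- gompertz_params()
  h <- pmin(1, g$a * exp(g$b * seq_len(MAX_PHYS_AGE)))
  S <- c(1, cumprod(1 - h))
  stats::approx(0:MAX_PHYS_AGE, S, xout = pmin(age, MAX_PHYS_AGE), rule = 2)$y
}

# Expected adult longevity (days) under hazard multiplier k and a constant
# extrinsic daily risk m: E[T] = sum_{t>=0} P(T > t).
.expected_longevity <- function(k, m) {
  g <- gompertz_params()
  h <- pmin(1, k * g$a * exp(g$b * seq_len(3000)))
  h[seq_len(3000) >= MAX_PHYS_AGE] <- 1
  S <- c(1, cumprod(1 - h))
  sum(S * (1 - m)^(0:3000))
}

# Table of realized mean longevities with 2% extrinsic risk used to anchor
# the senescence multiplier at the three reference temperatures.
.LONGEVITY_ANCHORS <- c("20" = 35.1, "25" = 26.7, "30" = 16.9)
EXTRINSIC_RISK <- 0.02

#' Temperature-dependent senescence hazard multiplier
#'
#' Temperature modulates senescence as a multiplier k(T) on the Gompertz
#' hazard: k = 1 at the 22.5 C optimum, and k at the 20, 25 and 30 C
#' anchors is solved (1-D root find, cached) so that the expected adult
#' longevity under a 2% constant extrinsic daily risk equals the realized
#' mean longevities 35.1, 26.7 and 16.9 days. Between anchors log k is
#' interpolated linearly in temperature; below 20 C the cold-side slope is
#' extrapolated (cold stress raises mortality) and above 30 C k is held at
#' its 30 C value.
#'
#' @param temperature Degrees C (vectorised).
#' @return Multiplier k(T) > 0.
#' @export
senescence_multiplier <- function(temperature) {
  an <- .senescence_anchors()
  tt <- c(20, 22.5, 25, 30)
  lk <- c(an$logk20, 0, an$logk25, an$logk30)
  t <- pmax(20, pmin(temperature, 30))
  exp(stats::approx(tt, lk, xout = t, rule = 2)$y)
}

.senescence_anchors <- function() {
  if (!is.null(.calib_env$sen)) return(.calib_env$sen)
  solve_k <- function(target) {
    stats::uniroot(function(k) .expected_longevity(k, EXTRINSIC_RISK) - target,
                   c(1e-3, 1e4), tol = 1e-10)$root
  }
  k20 <- solve_k(.LONGEVITY_ANCHORS[["20"]])
  k25 <- solve_k(.LONGEVITY_ANCHORS[["25"]])
  k30 <- solve_k(.LONGEVITY_ANCHORS[["30"]])
  sen <- list(logk20 = log(k20), logk25 = log(k25), logk30 = log(k30))
  .calib_env$sen <- sen
  sen
}

#' Temperature-dependent maturation rate
#'
#' Daily increment of the physiological (maturation) age clock, in
#' optimal-equivalent days per calendar day. Anchored so that the onset of
#' maturity (physiological age 11) is reached in 16, 9 and 6 calendar days
#' at constant 20, 25 and 30 C, with rate 1 at the 22.5 C optimum; linear
#' between anchors, 0 at and below the 11 C activity cutoff, clamped above
#' 30 C.
#'
#' @param temperature Degrees C (vectorised).
#' @return Physiological days gained per calendar day.
#' @examples
#' ceiling(11 / maturation_rate(c(20, 25, 30)))   # 16, 9, 6 days
#' @export
maturation_rate <- function(temperature) {
  tt <- c(DEV_T_CUTOFF, 20, 22.5, 25, 30)
  rr <- c(0, MATURITY_AGE / 16, 1, MATURITY_AGE / 9, MATURITY_AGE / 6)
  t <- pmin(temperature, 30)
  r <- stats::approx(tt, rr, xout = pmax(t, DEV_T_CUTOFF), rule = 2)$y
  r[temperature <= DEV_T_CUTOFF] <- 0
  r
}

#' Maturity category from physiological age
#'
#' Physiological-age bands: 1--10 young, 11--45 mature, 46--75 old, 76+
#' very old.
#'
#' @param phys_age Physiological age in optimal-equivalent days (>= 0).
#' @return Factor with levels young, mature, old, very_old.
#' @export
maturity_category <- function(phys_age) {
  if (any(phys_age < 0)) stop("phys_age must be >= 0", call. = FALSE)
  cut(phys_age, c(-Inf, 11, 46, 76, Inf),
      labels = c("young", "mature", "old", "very_old"), right = FALSE)
}

#' Demographic calibration report
#'
#' All deterministically calibrated demographic constants: the Gompertz
#' parameters, the senescence multipliers and implied expected longevities
#' at the anchor temperatures (with and without the 2% extrinsic risk),
#' and the maturation rates.
#'
#' @return A list suitable for `jsonlite::write_json()`.
#' @export
demography_calibration <- function() {
  g <- gompertz_params()
  k <- senescence_multiplier(c(20, 25, 30))
  list(
    gompertz = g,
    senescence_multiplier = list(t20 = k[1], t25 = k[2], t30 = k[3]),
    expected_longevity_extrinsic_2pct =
      list(t20 = .expected_longevity(k[1], EXTRINSIC_RISK),
           t25 = .expected_longevity(k[2], EXTRINSIC_RISK),
           t30 = .expected_longevity(k[3], EXTRINSIC_RISK)),
    expected_longevity_no_extrinsic =
      list(t20 = .expected_longevity(k[1], 0),
           t25 = .expected_longevity(k[2], 0),
           t30 = .expected_longevity(k[3], 0)),
    maturation_rate = list(t20 = maturation_rate(20), t25 = maturation_rate(25),
                           t30 = maturation_rate(30)),
    maturation_days = ceiling(MATURITY_AGE / maturation_rate(c(20, 25, 30))),
    fecundity_envelope_total = sum(fecundity_envelope(1:MAX_PHYS_AGE))
  )
}

# ---- immature cohorts -----------------------------------------------------

# Daily survival during cold developmental arrest (T below 13 C): torpid
# immatures have low metabolic demand; pupae overwinter best in the soil.
WINTER_DAILY_SURVIVAL <- c(egg = 0.97, larva = 0.985, pupa = 0.992)

#' Daily within-stage survival rate
#'
#' Stage mortality accumulates with exposure: the daily survival
#' probability is `stage_survival(stage, T)^(1 / stage_duration(stage, T))`,
#' so that a stage completed at constant temperature realises exactly its
#' cumulative transition survival, while cohorts developing slowly pay
#' mortality for every day of exposure. Below 13 C development is arrested
#' or nearly so and cold-torpid stages switch to flat overwintering daily
#' survival rates (eggs 0.97, larvae 0.985, pupae 0.992 per day), so winters
#' decimate -- but do not always annihilate -- the immature stock.
#'
#' @inheritParams stage_duration
#' @return Daily survival probability.
#' @export
stage_daily_survival <- function(stage, temperature) {
  s <- stage_survival(stage, pmax(temperature, DEV_T_COLD))^
    (1 / stage_duration(stage, pmax(temperature, DEV_T_COLD)))
  cold <- temperature < DEV_T_COLD
  if (any(cold)) {
    w <- rep_len(WINTER_DAILY_SURVIVAL[stage], length(s))
    s[cold] <- w[cold]
  }
  s
}

#' Advance immature cohorts by one day
#'
#' Each cohort is first thinned binomially by the daily survival rate
#' [stage_daily_survival()], then gains `1 / stage_duration(stage, T)`
#' development progress (rate summation; no progress below the 11 C
#' cutoff). Cohorts reaching progress 1 transition: the count is thinned by
#' the host suitability of the natal sector, the pupal transition is
#' additionally thinned by the 30% in-soil extrinsic mortality, and
#' survivors move to the next stage with progress reset to 0. Pupal
#' survivors are returned as emergers (both sexes) rather than kept as
#' cohorts. At constant temperature the cumulative thinning across a stage
#' equals `stage_survival(stage, T) * suitability` (times the in-soil
#' factor for pupae).
#'
#' @param cohorts Tibble with columns `sector`, `stage` (1 egg, 2 larva,
#'   3 pupa), `count`, `progress`, `suitability`.
#' @param temperature Degrees C (scalar, today's mean).
#' @return A list: `cohorts` (advanced tibble, zero-count rows dropped) and
#'   `emerged` (tibble `sector`, `count` of newly emerged adults).
#' @export
advance_immatures <- function(cohorts, temperature) {
  if (nrow(cohorts) == 0L) {
    return(list(cohorts = cohorts,
                emerged = tibble::tibble(sector = integer(), count = integer())))
  }
  stages <- c("egg", "larva", "pupa")
  dur <- stage_duration(stages, rep(temperature, 3))
  sdaily <- stage_daily_survival(stages, rep(temperature, 3))
  cohorts$count <- stats::rbinom(nrow(cohorts), cohorts$count,
                                 sdaily[cohorts$stage])
  cohorts$progress <- cohorts$progress + 1 / dur[cohorts$stage]
  done <- cohorts$progress >= 1 & cohorts$count > 0L
  emerged <- tibble::tibble(sector = integer(), count = integer())
  if (any(done)) {
    p <- cohorts$suitability[done]
    p[cohorts$stage[done] == 3L] <- p[cohorts$stage[done] == 3L] * (1 - IN_SOIL_MORTALITY)
    surv <- stats::rbinom(sum(done), cohorts$count[done], pmin(1, pmax(0, p)))
    to_pupae <- cohorts$stage[done] < 3L
    cohorts$count[done] <- surv
    cohorts$progress[done] <- 0
    cohorts$stage[done] <- cohorts$stage[done] + 1L
    em <- which(done)[!to_pupae]
    if (length(em)) {
      emerged <- tibble::tibble(sector = cohorts$sector[em],
                                count = cohorts$count[em])
      emerged <- emerged[emerged$count > 0L, ]
      cohorts$count[em] <- 0L
    }
  }
  list(cohorts = cohorts[cohorts$count > 0L, ], emerged = emerged)
}

EMERGENCE_SPAN <- 30L      # days over which one pupal cohort's adults emerge
EMERGENCE_FRONT_P <- NULL  # geometric weight solved below

#' Staggered adult emergence schedule
#'
#' Adults emerging from one batch of pupae leave the soil staggered over a
#' 30-day span (within the observed 25--40 day range), with geometrically
#' decaying daily weights tuned so that 75% emerge during the first 10
#' days. Counts are multinomial draws; their sum is exactly `n`.
#'
#' @param n Number of emerging adults (>= 0).
#' @param start_day Simulation day of the first emergence.
#' @return A tibble `day`, `count` (rows with zero count dropped).
#' @export
emergence_schedule <- function(n, start_day) {
  if (n == 0L) return(tibble::tibble(day = integer(), count = integer()))
  p <- 1 - 0.25^(1 / 10)  # 1 - (1-p)^10 = 0.75
  w <- p * (1 - p)^(0:(EMERGENCE_SPAN - 1L))
  cnt <- as.integer(stats::rmultinom(1, n, w))
  keep <- cnt > 0L
  tibble::tibble(day = start_day + (0:(EMERGENCE_SPAN - 1L))[keep],
                 count = cnt[keep])
}
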