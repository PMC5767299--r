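TRAP_BASE_RISK <- 0.05        # daily capture risk, fresh bait, in-sector
TRAP_REBAIT_INTERVAL <- 60L   # days between bait changes
TRAP_DAILY_DECLINE <- 0.005   # daily multiplicative bait efficacy decline

#' Bait efficacy as a function of bait age
#'
#' Lure attractiveness declines multiplicatively by 0.5% per day
#' (`(1 - 0.005)^age`), resetting to 1 when the trap is re-baited every 60
#' days.
#'
#' @param bait_age Days since the last bait change (>= 0, vectorised).
#' @return Efficacy fraction in (0, 1\].
#' @examples
#' bait_efficacy(c(0, 60))   # 1, 0.995^60 = 0.740
#' @export
bait_efficacy <- function(bait_age) {
  if (any(bait_age < 0)) stop("bait_age must be >= 0", call. = FALSE)
  (1 - TRAP_DAILY_DECLINE)^bait_age
}

#' Age-dependent female responsiveness to food-baited traps
#'
#' Piecewise-linear responsiveness over physiological age through the
#' observed anchors: 40% at emergence, rising to a 100% peak at early
#' maturity (age 15), declining to 50% at 45 days (6--7 weeks old) and on
#' down to a 15% floor from age 76 (very old) onward. Because the curve
#' runs on the physiological-age axis it rescales automatically with the
#' temperature-dependent maturation pace.
#'
#' @param phys_age Physiological age (>= 0, vectorised).
#' @return Responsiveness fraction in \[0.15, 1\].
#' @examples
#' female_responsiveness(c(0, 15, 45, 120))
#' @export
female_responsiveness <- function(phys_age) {
  stats::approx(x = c(0, 15, 45, 76),
                y = c(0.40, 1.00, 0.50, 0.15),
                xout = pmax(phys_age, 0), rule = 2)$y
}

#' Build trap state from a landscape
#'
#' @param landscape A `medfly_landscape` with `trap_id` placed.
#' @return A tibble `trap_id`, `sector`, `bait_age`, `distance` (nominal
#'   distance from the release point for validation layouts, else NA).
#' @export
init_traps <- function(landscape) {
  idx <- which(!is.na(landscape$trap_id))
  tr <- tibble::tibble(trap_id = landscape$trap_id[idx],
                       sector = landscape$sector[idx])
  tr <- tr[order(tr$trap_id), ]
  dist <- attr(landscape, "trap_distance")
  tr$distance <- if (!is.null(dist)) dist[tr$trap_id] else NA_real_
  tr$bait_age <- 0L
  tr
}

#' Service traps: bait ageing and scheduled re-baiting
#'
#' Bait age increments daily and resets to 0 every 60 days (so bait age at
#' trial time never exceeds 59).
#'
#' @param traps Trap tibble from [init_traps()].
#' @param day Simulation day (1-based).
#' @return The trap tibble with updated `bait_age`.
#' @export
service_traps <- function(traps, day) {
  traps$bait_age <- (day - 1L) %% TRAP_REBAIT_INTERVAL
  traps
}

#' Daily capture trials
#'
#' Capture requires activity around the lure, in two forms. Each arrival
#' into a trap's sector during the day's errand is an independent capture
#' trial with per-trial probability
#' `0.05 * bait_efficacy(bait_age) * responsiveness(phys_age)` (always at
#' most 5%). In addition, a female residing in a trap sector that currently
#' bears fruit forages there and runs one resident trial per day, scaled by
#' the temperature activity scalar (no foraging during winter arrest);
#' females sheltering in a barren trap sector are not exposed. The day's capture probability is
#' `1 - (1 - p)^trials`. The trap's effective range is confined to its own
#' 625 m2 sector. Without a visit matrix, one trial is run for females
#' ending the day in a trap sector.
#'
#' @param sector Current sector per female (NA for emigrated).
#' @param phys_age Physiological ages.
#' @param traps Trap tibble (serviced for today).
#' @param visits Optional n x n_traps matrix of daily visit counts from
#'   [daily_relocation()].
#' @param searching Logical per female: host-searching (food-deprived)
#'   females respond maximally to the food lure (responsiveness 1)
#'   regardless of age.
#' @param trap_fruit Logical per trap: does the trap's sector currently
#'   bear fruit (enables resident foraging trials)?
#' @param activity Activity scalar for resident foraging trials (see
#'   [activity_scalar()]).
#' @return A list: `captured` (logical per female), `trap_id` (NA or the
#'   capturing trap).
#' @export
attempt_capture <- function(sector, phys_age, traps, visits = NULL,
                            searching = FALSE, trap_fruit = FALSE,
                            activity = 1) {
  n <- length(sector)
  captured <- logical(n)
  trap_of <- rep(NA_integer_, n)
  if (n == 0L || nrow(traps) == 0L) {
    return(list(captured = captured, trap_id = trap_of))
  }
  eff <- bait_efficacy(traps$bait_age)
  if (is.null(visits)) {
    visits <- matrix(0L, n, nrow(traps))
    m <- match(sector, traps$sector)
    hitcol <- which(!is.na(m))
    visits[cbind(hitcol, m[hitcol])] <- 1L
  }
  resp <- female_responsiveness(phys_age)
  resp[rep_len(searching, n)] <- 1
  trap_fruit <- rep_len(trap_fruit, nrow(traps))
  for (t in seq_len(nrow(traps))) {
    v <- visits[, t]
    if (trap_fruit[t] && activity > 0) {
      res <- sector == traps$sector[t] & v == 0L
      res[is.na(res)] <- FALSE
      v[res] <- min(1, activity)
    }
    exposed <- which(v > 0 & !captured)
    if (!length(exposed)) next
    p1 <- TRAP_BASE_RISK * eff[t] * resp[exposed]
    pday <- 1 - (1 - p1)^v[exposed]
    hit <- stats::runif(length(exposed)) < pday
    captured[exposed[hit]] <- TRUE
    trap_of[exposed[hit]] <- traps$trap_id[t]
  }
  list(captured = captured, trap_id = trap_of)
}
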