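#' Movement and boundary-exchange parameters
#'
#' Daily movement is emulated as a sequence of hops between neighbouring
#' sectors rather than a parametric dispersal kernel: each active female
#' performs `k ~ Poisson(mean_hops * movement_pace(T) * maturity factor)`
#' hops to one of the 8 adjacent sectors, chosen with probability
#' proportional to `(attractiveness + baseline)^exponent`. Long lifetime
#' displacements (the observed 200--700 m dispersion range) emerge from hop
#' accumulation. The defaults are the calibrated kernel: they were tuned
#' once against the mark-release dispersal statistics at 25 C (90% presence
#' radius and area, explorers beyond the site, 75--600 m trap catches,
#' realized longevity) and then frozen; `scripts/calibrate_movement.R`
#' reproduces the sweep. The maturity multipliers encode the tephritid
#' dispersal-then-station-keeping pattern: young females range most (with
#' strong within-day persistence), mature females hold station around
#' oviposition hosts, and post-reproductive females resume moderate
#' wandering.
#'
#' Hops across the site boundary are temporary explorations: with
#' probability `return_prob` the female returns the same day, otherwise she
#' emigrates permanently. When immigration is enabled the expected number
#' of immigrants is `in_out_ratio` (0.25) per emigrant.
#'
#' Individual flies differ consistently in mobility: each female carries a
#' lifetime mobility multiplier drawn at emergence from a gamma distribution
#' with mean 1 and shape `hop_dispersion` (individual daily values generated
#' around a cohort mean with spread). Small shapes give a sedentary majority
#' plus a mobile minority, which concentrates lifetime presence near the
#' release point while still producing the long observed dispersal tail.
#'
#' @param mean_hops Mean hops per day for a mature female at full activity.
#' @param hop_dispersion Gamma shape of the individual mobility multiplier
#'   (`Inf` = identical females).
#' @param baseline Baseline added to sector attractiveness (percent points).
#' @param exponent Attractiveness weighting exponent.
#' @param maturity_factor Hop-rate multipliers for the four maturity bands.
#' @param persistence Within-day directional persistence (von Mises-style
#'   concentration) per maturity band: each female draws one heading per day
#'   and neighbour choice is additionally weighted by
#'   `exp(persistence * cos(angle - heading))`. High persistence for young
#'   females makes their dispersal errands near-ballistic daily runs (the
#'   dispersal phase); zero persistence gives undirected local foraging.
#' @param search_factor Hop-rate multiplier for host-searching females
#'   (mature females without usable fruit in their sector range widely,
#'   with young-phase persistence, until they strike a fruiting sector).
#' @param outside_attract Attractiveness assumed for off-site terrain.
#' @param return_prob Same-day return probability for boundary crossers.
#' @param in_out_ratio Immigrants per emigrant when immigration is enabled.
#' @return A list of movement parameters.
#' @export
movement_params <- function(mean_hops = 2.6,
                            hop_dispersion = 1,
                            baseline = 10,
                            exponent = 1,
                            maturity_factor = c(young = 1.2, mature = 0.56,
                                                old = 0.6, very_old = 0.45),
                            persistence = c(young = 4, mature = 0,
                                            old = 0, very_old = 0),
                            search_factor = 3,
                            outside_attract = 0,
                            return_prob = 0.8,
                            in_out_ratio = 0.25) {
  stopifnot(in_out_ratio >= 0, in_out_ratio <= 1,
            return_prob >= 0, return_prob <= 1)
  as.list(environment())
}

# 8-neighbour index matrix for the 40x40 grid; 0 marks off-grid.
.neighbour_matrix <- function() {
  if (!is.null(.calib_env$nbr)) return(.calib_env$nbr)
  n <- GRID_N
  row <- rep(0:(n - 1L), each = n)
  col <- rep(0:(n - 1L), times = n)
  off <- rbind(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
               c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  m <- matrix(0L, n * n, 8L)
  for (j in 1:8) {
    r2 <- row + off[j, 1]; c2 <- col + off[j, 2]
    ok <- r2 >= 0L & r2 < n & c2 >= 0L & c2 < n
    m[ok, j] <- r2[ok] * n + c2[ok] + 1L
  }
  .calib_env$nbr <- m
  m
}

#' One day of relocation for a cohort of females
#'
#' Vectorised daily movement: draws per-female hop counts, performs the
#' hops over the attractiveness field, and resolves boundary crossings.
#' Females at zero activity (cold days) stay put.
#'
#' @param sector Integer vector of current sector indices (one per female).
#' @param phys_age Physiological ages (drives the maturity multiplier).
#' @param mobility Per-female lifetime mobility multipliers (default 1).
#' @param searching Logical per female: mature females without fruit in
#'   their current sector search for oviposition hosts, moving with an
#'   elevated hop rate and young-phase directional persistence, and
#'   settling as soon as a hop lands on usable fruit.
#' @param fruit_fraction Optional per-sector fruit availability used by
#'   searching females to settle.
#' @param attractiveness Per-sector attractiveness (length 1600).
#' @param temperature Degrees C (scalar).
#' @param params [movement_params()].
#' @param trap_sectors Optional integer vector of trap sector indices; when
#'   given, the result carries a per-female count of arrivals into each trap
#'   sector during the day's errand, used for capture exposure (capture
#'   requires active flight toward the lure, so sedentary or winter-arrested
#'   flies are not exposed).
#' @return A list: `sector` (final sectors; NA for emigrants), `emigrated`
#'   (logical), `crossed_boundary` (logical: explored beyond the site
#'   today), and `trap_visits` (n x length(trap_sectors) matrix, if
#'   requested).
#' @export
daily_relocation <- function(sector, phys_age, attractiveness, temperature,
                             params = movement_params(), mobility = 1,
                             trap_sectors = NULL, searching = FALSE,
                             fruit_fraction = NULL) {
  n <- length(sector)
  pace <- movement_pace(temperature)
  nt <- length(trap_sectors)
  visits <- if (nt) matrix(0L, n, nt) else NULL
  out <- list(sector = sector, emigrated = logical(n),
              crossed_boundary = logical(n), trap_visits = visits)
  if (n == 0L || pace <= 0) return(out)
  mclass <- as.integer(maturity_category(phys_age))
  searching <- rep_len(searching, n)
  mclass[searching] <- 1L   # searchers take the young-phase persistence
  mf <- params$maturity_factor[mclass]
  mf[searching] <- params$search_factor %||% 2
  k <- stats::rpois(n, params$mean_hops * pace * mf * rep_len(mobility, n))
  if (all(k == 0L)) return(out)
  nbr <- .neighbour_matrix()
  wfield <- (pmax(attractiveness, 0) + params$baseline)^params$exponent
  w_out <- (params$outside_attract + params$baseline)^params$exponent
  kappa <- params$persistence[mclass]
  theta <- stats::runif(n, 0, 2 * pi)
  dirw <- exp(kappa * (cos(theta) %o% cos(.NBR_ANGLE) +
                         sin(theta) %o% sin(.NBR_ANGLE)))
  cur <- sector
  alive_move <- rep(TRUE, n)
  for (h in seq_len(max(k))) {
    mv <- which(k >= h & alive_move)
    if (length(mv) == 0L) break
    nb <- nbr[cur[mv], , drop = FALSE]
    w <- matrix(w_out, nrow(nb), 8L)
    on <- nb > 0L
    w[on] <- wfield[nb[on]]
    w <- w * dirw[mv, , drop = FALSE]
    pick <- .sample_cols(w)
    dest <- nb[cbind(seq_along(mv), pick)]
    off <- dest == 0L
    if (any(off)) {
      mo <- mv[off]
      out$crossed_boundary[mo] <- TRUE
      ret <- stats::runif(length(mo)) < params$return_prob
      # returners stay in their current sector and end the day's errand
      alive_move[mo] <- FALSE
      out$emigrated[mo[!ret]] <- TRUE
    }
    stay_on <- mv[!off]
    cur[stay_on] <- dest[!off]
    if (!is.null(fruit_fraction) && length(stay_on)) {
      found <- stay_on[searching[stay_on] &
                         fruit_fraction[cur[stay_on]] >= 0.05]
      alive_move[found] <- FALSE
    }
    if (nt && length(stay_on)) for (t in seq_len(nt)) {
      arr <- stay_on[cur[stay_on] == trap_sectors[t]]
      visits[arr, t] <- visits[arr, t] + 1L
    }
  }
  cur[out$emigrated] <- NA_integer_
  out$sector <- cur
  out$trap_visits <- visits
  out
}

#' Boundary exchange: immigrants compensating emigration
#'
#' When immigration is enabled, each emigrant is balanced by an expected
#' `in_out_ratio` immigrants (binomial draw), initialised at a random edge
#' sector with physiological and adult ages sampled from the current
#' population.
#'
#' @param n_emigrants Number of emigrants today.
#' @param params [movement_params()].
#' @param immigration Logical; when `FALSE` (validation scenarios) no
#'   immigrants arrive.
#' @return Integer number of immigrants to create.
#' @export
boundary_exchange <- function(n_emigrants, params = movement_params(),
                              immigration = TRUE) {
  if (!immigration || n_emigrants == 0L) return(0L)
  stats::rbinom(1L, n_emigrants, params$in_out_ratio)
}

#' Temperature scaling of daily movement intensity
#'
#' Hop counts scale with the relative metabolic pace of the fly,
#' `maturation_rate(T) / maturation_rate(25)`: zero at and below the 11 C
#' winter cutoff and rising monotonically through 30 C. Dispersal
#' statistics therefore increase with temperature over 20--30 C even though
#' lifespans shorten, matching the observed ordering of presence areas.
#'
#' @param temperature Degrees C (vectorised).
#' @return Hop-rate multiplier (1 at 25 C).
#' @export
movement_pace <- function(temperature) {
  maturation_rate(temperature) / maturation_rate(25)
}

# Angles of the 8 neighbour offsets (same order as .neighbour_matrix rows).
.NBR_ANGLE <- atan2(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))

# Edge sector indices (site perimeter), for initialising immigrants.
.edge_sectors <- function() {
  if (!is.null(.calib_env$edge)) return(.calib_env$edge)
  n <- GRID_N
  row <- rep(0:(n - 1L), each = n)
  col <- rep(0:(n - 1L), times = n)
  e <- which(row == 0L | row == n - 1L | col == 0L | col == n - 1L)
  .calib_env$edge <- e
  e
}
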