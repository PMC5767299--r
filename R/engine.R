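#' Scenario configuration
#'
#' Bundles everything one replicate needs: the landscape (with traps
#' placed), the climate profile, the founding cohort, process switches and
#' run control. Invasion presets follow the standard protocol: a single
#' propagule of 100 females arriving as 200 larvae (1:1 sexes) in infested
#' fruit abandoned near the site centre on day 90 of the year, four
#' detection traps, oviposition and immigration on, 2% adult extrinsic
#' daily risk, 100 weeks (700 days) horizon, and establishment declared
#' when the female population across all stages reaches 3,000.
#'
#' @param landscape A `medfly_landscape` with traps placed.
#' @param climate A [climate_profile()].
#' @param founder_larvae Larvae (both sexes) in the founding propagule.
#' @param release_adults Adult females released on day 1 (validation mode;
#'   overrides `founder_larvae` when > 0).
#' @param origin `"center"` or a sector index; propagules land in the
#'   nearest host-containing sector.
#' @param start_day_of_year Day of year of simulation day 1.
#' @param oviposition,immigration Process switches.
#' @param extrinsic_risk Adult extrinsic daily mortality risk.
#' @param duration_days Simulation horizon in days.
#' @param establishment_threshold Female population (all stages, immatures
#'   counted at the 1:1 sex ratio) that terminates a replicate as
#'   established; `Inf` disables the halt.
#' @param movement [movement_params()].
#' @return A `medfly_scenario` list.
#' @export
scenario_config <- function(landscape, climate,
                            founder_larvae = 200L,
                            release_adults = 0L,
                            origin = "center",
                            start_day_of_year = 90L,
                            oviposition = TRUE,
                            immigration = TRUE,
                            extrinsic_risk = EXTRINSIC_RISK,
                            duration_days = 700L,
                            establishment_threshold = 3000,
                            movement = movement_params()) {
  stopifnot(inherits(landscape, "medfly_landscape"),
            inherits(climate, "medfly_climate"),
            extrinsic_risk >= 0, extrinsic_risk <= 1)
  origin_sector <- .resolve_origin(landscape, origin)
  cfg <- list(landscape = landscape, climate = climate,
              founder_larvae = as.integer(founder_larvae),
              release_adults = as.integer(release_adults),
              origin_sector = origin_sector,
              start_day_of_year = as.integer(start_day_of_year),
              oviposition = oviposition, immigration = immigration,
              extrinsic_risk = extrinsic_risk,
              duration_days = as.integer(duration_days),
              establishment_threshold = establishment_threshold,
              movement = movement,
              phen_cache = new.env(parent = emptyenv()))
  structure(cfg, class = "medfly_scenario")
}

.resolve_origin <- function(landscape, origin) {
  centre <- .sector_index(GRID_N %/% 2L, GRID_N %/% 2L)
  if (is.numeric(origin)) return(as.integer(origin))
  stopifnot(origin == "center")
  if (landscape$cover[centre] == "host") return(centre)
  host <- which(landscape$cover == "host")
  if (length(host) == 0L) return(centre)
  d2 <- (landscape$row[host] - landscape$row[centre])^2 +
    (landscape$col[host] - landscape$col[centre])^2
  host[which.min(d2)]
}

#' @rdname scenario_config
#' @param site Landscape preset name (`"farm"`, `"urban1"`..`"urban4"`).
#' @param climate_name One of `"med"`, `"opt"`, `"const20"`, `"const25"`,
#'   `"const30"`.
#' @param landscape_seed Seed for landscape generation and trap placement
#'   (shared by all replicates of the scenario).
#' @param ... Passed on to `scenario_config()`.
#' @export
scenario_invasion <- function(site = "farm", climate_name = "med",
                              landscape_seed = 1L, ...) {
  climate <- switch(climate_name,
                    med = climate_med(), opt = climate_opt(),
                    const20 = climate_const(20), const25 = climate_const(25),
                    const30 = climate_const(30),
                    stop("unknown climate preset: ", climate_name))
  ls <- generate_landscape(site, seed = landscape_seed)
  ls <- place_detection_traps(ls, seed = landscape_seed)
  scenario_config(ls, climate, ...)
}

#' @rdname scenario_config
#' @param temperature Constant temperature for the validation scenario.
#' @param n_females Released cohort size.
#' @export
scenario_validation <- function(temperature = 25, extrinsic_risk = EXTRINSIC_RISK,
                                n_females = 1000L, duration_days = 175L, ...) {
  ls <- place_validation_traps(homogeneous_landscape())
  scenario_config(ls, climate_const(temperature),
                  founder_larvae = 0L, release_adults = n_females,
                  origin = .sector_index(GRID_N %/% 2L, GRID_N %/% 2L),
                  start_day_of_year = 1L,
                  oviposition = FALSE, immigration = FALSE,
                  extrinsic_risk = extrinsic_risk,
                  duration_days = duration_days,
                  establishment_threshold = Inf, ...)
}

# Fate codes for adult females.
FATE <- c(alive = 0L, dead_intrinsic = 1L, dead_extrinsic = 2L,
          trapped = 3L, emigrated = 4L)

#' Initialize a simulation state
#'
#' Sets up the replicate state: the founding larval cohort (invasion mode)
#' or the released adult cohort (validation mode) at the origin sector,
#' trap state, phenology caches and empty records. All randomness consumes
#' the current RNG stream; call `set.seed()` (or use [run_simulation()],
#' which seeds for you) for reproducibility.
#'
#' @param config A `medfly_scenario`.
#' @return An environment of class `medfly_state`.
#' @export
initialize_invasion <- function(config) {
  st <- new.env(parent = emptyenv())
  st$cfg <- config
  ls <- config$landscape
  st$traps <- init_traps(ls)
  st$day <- 0L
  n0 <- config$release_adults
  st$fem <- list(
    sector = rep(config$origin_sector, n0),
    age = rep(0, n0), m_age = rep(0, n0),
    status = rep(FATE[["alive"]], n0),
    emergence_day = rep(1L, n0), death_day = rep(NA_integer_, n0),
    cum_eggs = rep(0L, n0), crossed = rep(FALSE, n0),
    trap_id = rep(NA_integer_, n0),
    mobility = .draw_mobility(n0, config$movement)
  )
  if (config$founder_larvae > 0L) {
    # founding larvae develop inside the abandoned infested fruit itself,
    # so their substrate suitability does not depend on the landing sector
    st$cohorts <- tibble::tibble(
      sector = config$origin_sector, stage = 2L,
      count = config$founder_larvae, progress = 0,
      suitability = 0.75
    )
  } else {
    st$cohorts <- tibble::tibble(sector = integer(), stage = integer(),
                                 count = integer(), progress = numeric(),
                                 suitability = numeric())
  }
  st$pending <- list(day = integer(), sector = integer(), count = integer())
  st$presence <- integer(nrow(ls))
  st$window_eggs <- numeric(nrow(ls))
  st$capacity <- pmax(1, 2000 * ls$canopy_coverage / 100)
  st$trap_events <- list(day = integer(), trap_id = integer(), count = integer())
  st$rec <- list(day = integer(), day_of_year = integer(), temp_c = numeric(),
                 eggs = integer(), larvae = integer(), pupae = integer(),
                 adults = integer(), catches = integer(),
                 female_equiv = numeric())
  st$termination <- "horizon"
  st$termination_day <- NA_integer_
  class(st) <- "medfly_state"
  st
}

# Cached per-sector phenology for a day of year (shared across replicates
# of a scenario; landscape and host table are fixed per scenario).
.phenology_for <- function(config, doy) {
  key <- as.character(doy)
  cache <- config$phen_cache
  if (!is.null(cache[[key]])) return(cache[[key]])
  ph <- landscape_phenology(config$landscape, doy)
  ph <- apply_harvest(ph, config$landscape, doy)
  out <- list(attractiveness = ph$attractiveness,
              fruit_fraction = ph$fruit_fraction)
  cache[[key]] <- out
  out
}

#' Advance the simulation by one day
#'
#' Executes the fixed daily event order: temperature lookup, phenology and
#' harvest update, immature development and stage transitions, staggered
#' adult emergence, adult ageing with intrinsic (Gompertz) and extrinsic
#' mortality, movement and boundary exchange, oviposition, trap servicing
#' and capture trials, and recording.
#'
#' @param state A `medfly_state` from [initialize_invasion()].
#' @return The state, invisibly (mutated in place).
#' @export
run_day <- function(state) {
  st <- state
  cfg <- st$cfg
  st$day <- st$day + 1L
  day <- st$day
  doy <- ((cfg$start_day_of_year + day - 2L) %% 365L) + 1L
  temp <- daily_temperature(cfg$climate, doy)

  ph <- .phenology_for(cfg, doy)
  st$window_eggs[ph$fruit_fraction <= 0] <- 0

  ## harvest removes ripe fruit together with the eggs and larvae inside it
  if (nrow(st$cohorts)) {
    hosts <- attr(cfg$landscape, "hosts") %||% host_table()
    hv <- hosts[!is.na(hosts$harvest_day) & hosts$harvest_day == doy, ]
    if (nrow(hv)) {
      for (i in seq_len(nrow(hv))) {
        in_fruit <- st$cohorts$stage <= 2L &
          cfg$landscape$host_id[st$cohorts$sector] %in% hv$host_id[i]
        if (any(in_fruit)) {
          st$cohorts$count[in_fruit] <- stats::rbinom(
            sum(in_fruit), st$cohorts$count[in_fruit], 1 - hv$harvest_accuracy[i])
        }
      }
      st$cohorts <- st$cohorts[st$cohorts$count > 0L, ]
    }
  }

  ## immature development & transitions
  adv <- advance_immatures(st$cohorts, temp)
  st$cohorts <- adv$cohorts
  if (nrow(adv$emerged)) {
    for (i in seq_len(nrow(adv$emerged))) {
      sch <- emergence_schedule(adv$emerged$count[i], day + 1L)
      if (nrow(sch)) {
        st$pending$day <- c(st$pending$day, sch$day)
        st$pending$sector <- c(st$pending$sector, rep(adv$emerged$sector[i], nrow(sch)))
        st$pending$count <- c(st$pending$count, sch$count)
      }
    }
  }

  ## emergence due today: 1:1 sex ratio, only females become agents
  due <- st$pending$day == day
  if (any(due)) {
    n_new_f <- stats::rbinom(sum(due), st$pending$count[due], 0.5)
    spawn_sector <- rep(st$pending$sector[due], n_new_f)
    keep <- !due
    st$pending$day <- st$pending$day[keep]
    st$pending$sector <- st$pending$sector[keep]
    st$pending$count <- st$pending$count[keep]
    if (length(spawn_sector)) {
      .spawn_females(st, spawn_sector, day,
                     age = 0, m_age = 0, cum_eggs = 0L,
                     mobility = .draw_mobility(length(spawn_sector), cfg$movement))
    }
  }

  fem <- st$fem
  alive <- which(fem$status == FATE[["alive"]])

  ## ageing and mortality
  if (length(alive)) {
    fem$age[alive] <- fem$age[alive] + 1
    fem$m_age[alive] <- fem$m_age[alive] + maturation_rate(temp)
    h <- intrinsic_hazard(fem$age[alive], temp)
    u <- stats::runif(length(alive))
    die_int <- u < h
    risk <- cfg$extrinsic_risk * .exposure_weight(fem$mobility[alive])
    # ranging host search is conspicuous: elevated predation exposure
    if (!is.null(st$searching) && length(st$move_index)) {
      idx <- match(st$move_index[st$searching], alive)
      idx <- idx[!is.na(idx)]
      risk[idx] <- pmin(1, 1.5 * risk[idx])
    }
    die_ext <- !die_int & stats::runif(length(alive)) < risk
    fem$status[alive[die_int]] <- FATE[["dead_intrinsic"]]
    fem$status[alive[die_ext]] <- FATE[["dead_extrinsic"]]
    fem$death_day[alive[die_int | die_ext]] <- day
    alive <- alive[!(die_int | die_ext)]
  }

  ## movement & boundary exchange
  n_emig <- 0L
  st$trap_visits <- NULL
  st$move_index <- integer()
  if (length(alive)) {
    st$move_index <- alive
    searching <- cfg$oviposition &
      ph$fruit_fraction[fem$sector[alive]] < 0.05 &
      fem$m_age[alive] >= MATURITY_AGE
    st$searching <- searching
    mv <- daily_relocation(fem$sector[alive], fem$m_age[alive],
                           ph$attractiveness, temp, cfg$movement,
                           mobility = fem$mobility[alive],
                           trap_sectors = st$traps$sector,
                           searching = searching,
                           fruit_fraction = ph$fruit_fraction)
    st$trap_visits <- mv$trap_visits
    fem$sector[alive] <- mv$sector
    fem$crossed[alive] <- fem$crossed[alive] | mv$crossed_boundary
    em <- mv$emigrated
    n_emig <- sum(em)
    if (n_emig) {
      fem$status[alive[em]] <- FATE[["emigrated"]]
      fem$death_day[alive[em]] <- day
      alive <- alive[!em]
    }
  }
  n_imm <- boundary_exchange(n_emig, cfg$movement, cfg$immigration)
  if (n_imm > 0L && length(alive)) {
    donor <- sample(alive, n_imm, replace = TRUE)
    st$fem <- fem
    .spawn_females(st, sample(.edge_sectors(), n_imm, replace = TRUE), day,
                   age = fem$age[donor], m_age = fem$m_age[donor],
                   cum_eggs = fem$cum_eggs[donor],
                   mobility = fem$mobility[donor])
    fem <- st$fem
    alive <- which(fem$status == FATE[["alive"]])
  }

  ## presence bookkeeping (one presence-day per alive female)
  if (length(alive)) {
    tab <- tabulate(fem$sector[alive], nbins = length(st$presence))
    st$presence <- st$presence + tab
  }

  ## oviposition
  if (cfg$oviposition && length(alive)) {
    sec <- fem$sector[alive]
    fruit <- ph$fruit_fraction[sec]
    candidate <- which(fruit > 0 & fem$m_age[alive] >= MATURITY_AGE)
    if (length(candidate)) {
      ai <- alive[candidate]
      infest <- pmin(1, st$window_eggs[sec[candidate]] / st$capacity[sec[candidate]])
      pot <- potential_daily_fecundity(fem$m_age[ai], temp, fem$cum_eggs[ai])
      laid <- oviposit(pot, fruit[candidate], infest)
      fem$cum_eggs[ai] <- fem$cum_eggs[ai] + laid
      pos <- laid > 0L
      if (any(pos)) {
        by_sec <- rowsum(laid[pos], sec[candidate][pos])
        secs <- as.integer(rownames(by_sec))
        st$window_eggs[secs] <- st$window_eggs[secs] + by_sec[, 1]
        st$cohorts <- tibble::add_row(
          st$cohorts, sector = secs, stage = 1L,
          count = as.integer(by_sec[, 1]), progress = 0,
          suitability = cfg$landscape$suitability[secs])
      }
    }
  }

  ## trap servicing & capture trials
  st$traps <- service_traps(st$traps, day)
  if (length(alive) && nrow(st$traps)) {
    vis <- st$trap_visits
    srch <- FALSE
    if (!is.null(vis)) {
      keep <- match(alive, st$move_index)
      vis <- vis[keep, , drop = FALSE]
      vis[is.na(keep), ] <- 0L
      srch <- st$searching[keep]
      srch[is.na(keep)] <- FALSE
    }
    cap <- attempt_capture(fem$sector[alive], fem$m_age[alive], st$traps,
                           visits = vis, searching = srch,
                           trap_fruit = ph$fruit_fraction[st$traps$sector] >= 0.05,
                           activity = activity_scalar(temp))
    caught <- which(cap$captured)
    if (length(caught)) {
      fem$status[alive[caught]] <- FATE[["trapped"]]
      fem$death_day[alive[caught]] <- day
      fem$trap_id[alive[caught]] <- cap$trap_id[caught]
      ev <- table(cap$trap_id[caught])
      st$trap_events$day <- c(st$trap_events$day, rep(day, length(ev)))
      st$trap_events$trap_id <- c(st$trap_events$trap_id, as.integer(names(ev)))
      st$trap_events$count <- c(st$trap_events$count, as.integer(ev))
      alive <- alive[!cap$captured]
    }
  }
  st$fem <- fem

  ## recording
  n_eggs <- sum(st$cohorts$count[st$cohorts$stage == 1L])
  n_larv <- sum(st$cohorts$count[st$cohorts$stage == 2L])
  n_pup <- sum(st$cohorts$count[st$cohorts$stage == 3L]) + sum(st$pending$count)
  n_ad <- length(alive)
  feq <- 0.5 * (n_eggs + n_larv + n_pup) + n_ad
  r <- st$rec
  r$day <- c(r$day, day); r$day_of_year <- c(r$day_of_year, doy)
  r$temp_c <- c(r$temp_c, temp)
  r$eggs <- c(r$eggs, n_eggs); r$larvae <- c(r$larvae, n_larv)
  r$pupae <- c(r$pupae, n_pup); r$adults <- c(r$adults, n_ad)
  r$catches <- c(r$catches, sum(st$fem$death_day == day &
                                  st$fem$status == FATE[["trapped"]], na.rm = TRUE))
  r$female_equiv <- c(r$female_equiv, feq)
  st$rec <- r

  ## termination checks
  if (feq >= st$cfg$establishment_threshold) {
    st$termination <- "established"; st$termination_day <- day
  } else if (n_ad == 0L && n_eggs + n_larv + n_pup == 0L) {
    st$termination <- "extinct"; st$termination_day <- day
  }
  invisible(st)
}

# Extrinsic (predation) risk weight: exposure scales with individual
# mobility (mean 1 over the mobility distribution), so natural enemies
# disproportionately remove the mobile, far-ranging flies.
.exposure_weight <- function(mobility) {
  pmin(2, 0.5 + 0.5 * mobility)
}

.draw_mobility <- function(n, params) {
  shp <- params$hop_dispersion %||% Inf
  if (!is.finite(shp)) return(rep(1, n))
  stats::rgamma(n, shape = shp, rate = shp)
}

.spawn_females <- function(st, sector, day, age, m_age, cum_eggs, mobility = 1) {
  n <- length(sector)
  f <- st$fem
  f$sector <- c(f$sector, sector)
  f$age <- c(f$age, rep_len(age, n))
  f$m_age <- c(f$m_age, rep_len(m_age, n))
  f$status <- c(f$status, rep(FATE[["alive"]], n))
  f$emergence_day <- c(f$emergence_day, rep(day, n))
  f$death_day <- c(f$death_day, rep(NA_integer_, n))
  f$cum_eggs <- c(f$cum_eggs, rep_len(as.integer(cum_eggs), n))
  f$crossed <- c(f$crossed, rep(FALSE, n))
  f$trap_id <- c(f$trap_id, rep(NA_integer_, n))
  f$mobility <- c(f$mobility, rep_len(mobility, n))
  st$fem <- f
  invisible(st)
}

#' Run one replicate
#'
#' Runs the daily loop until the horizon, establishment or extinction, and
#' collects the replicate record.
#'
#' @param config A `medfly_scenario`.
#' @param seed Integer seed for this replicate's RNG stream.
#' @return A `medfly_run` list: `daily` (tibble of daily counts), `females`
#'   (per-female tibble), `trap_events`, `presence` (40 x 40 matrix of
#'   lifetime presence-days), `termination`, `termination_day`, `seed`.
#' @export
run_simulation <- function(config, seed = 1L) {
  set.seed(seed)
  st <- initialize_invasion(config)
  for (d in seq_len(config$duration_days)) {
    run_day(st)
    if (st$termination != "horizon") break
  }
  fem <- st$fem
  females <- tibble::tibble(
    id = seq_along(fem$sector), sector = fem$sector,
    emergence_day = fem$emergence_day, death_day = fem$death_day,
    age_at_death = ifelse(is.na(fem$death_day), NA_real_, fem$age),
    phys_age = fem$m_age,
    fate = names(FATE)[fem$status + 1L],
    cumulative_eggs = fem$cum_eggs,
    crossed_boundary = fem$crossed, trap_id = fem$trap_id
  )
  structure(list(
    daily = tibble::as_tibble(st$rec),
    females = females,
    trap_events = tibble::as_tibble(st$trap_events),
    traps = st$traps,
    presence = matrix(st$presence, GRID_N, GRID_N, byrow = TRUE),
    origin_sector = config$origin_sector,
    termination = st$termination,
    termination_day = if (is.na(st$termination_day)) st$day else st$termination_day,
    days_run = st$day,
    seed = seed
  ), class = "medfly_run")
}

#' Run a replicate series
#'
#' Executes `n` replicates of a scenario, each with a seed derived from the
#' master seed, and attaches the across-replicate summary. Identical
#' `(config, master_seed)` reproduce identical outputs.
#'
#' @param config A `medfly_scenario`.
#' @param n Number of replicates (15 for the invasion presets, 5 for
#'   auxiliary validation runs).
#' @param master_seed Integer master seed.
#' @return A `medfly_replicates` object (list of `medfly_run` + metadata).
#' @export
run_replicates <- function(config, n = 15L, master_seed = 1L) {
  stopifnot(n >= 1L)
  runs <- lapply(seq_len(n), function(i) {
    run_simulation(config, seed = .replicate_seed(master_seed, i))
  })
  structure(list(runs = runs, config = config, n = n,
                 master_seed = master_seed),
            class = "medfly_replicates")
}

#' @export
print.medfly_run <- function(x, ...) {
  cat(sprintf("<medfly_run> %d days, termination: %s (day %d), %d females ever, %d trapped\n",
              x$days_run, x$termination, x$termination_day,
              nrow(x$females), sum(x$females$fate == "trapped")))
  invisible(x)
}

#' @export
print.medfly_replicates <- function(x, ...) {
  cat(sprintf("<medfly_replicates> %d replicates (master seed %d)\n",
              x$n, x$master_seed))
  term <- table(vapply(x$runs, `[[`, "", "termination"))
  cat("  terminations:", paste(names(term), term, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
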