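#' Presence-area and presence-radius statistics
#'
#' Two distinct clustering statistics of a cohort's lifetime presence-days
#' around the release point. The *presence area* ranks sectors by
#' presence-days in descending order and converts the smallest prefix whose
#' cumulative share reaches `q` into hectares (625 m2 per sector). The
#' *presence radius* is the smallest radius around the release sector's
#' centre containing fraction `q` of all presence-days. The two are not a
#' filled-circle pair: the ranked-area statistic exploits local clustering
#' and is generally smaller than the circle the radius implies.
#'
#' @param presence A 40 x 40 matrix (or length-1600 vector) of lifetime
#'   presence-day counts.
#' @param release_sector Sector index of the release point.
#' @param q Quantile of presence-days to enclose (default 0.90).
#' @return A tibble with `q`, `area_ha`, `radius_m`, `total_presence_days`.
#' @examples
#' m <- matrix(0, 40, 40); m[20, 20] <- 100
#' presence_statistics(m, release_sector = 780)
#' @export
presence_statistics <- function(presence, release_sector, q = 0.90) {
  stopifnot(q > 0, q < 1)
  p <- as.numeric(if (is.matrix(presence)) t(presence) else presence)
  stopifnot(length(p) == GRID_N * GRID_N)
  tot <- sum(p)
  if (tot <= 0) stop("presence grid is all zero", call. = FALSE)
  ord <- order(p, decreasing = TRUE)
  n_sec <- which(cumsum(p[ord]) >= q * tot - 1e-9)[1]
  area_ha <- n_sec * SECTOR_HA

  row <- (seq_along(p) - 1L) %/% GRID_N
  col <- (seq_along(p) - 1L) %% GRID_N
  r0 <- (release_sector - 1L) %/% GRID_N
  c0 <- (release_sector - 1L) %% GRID_N
  d <- SECTOR_M * sqrt((row - r0)^2 + (col - c0)^2)
  od <- order(d)
  radius_m <- d[od][which(cumsum(p[od]) >= q * tot - 1e-9)[1]]
  tibble::tibble(q = q, area_ha = area_ha, radius_m = radius_m,
                 total_presence_days = tot)
}

#' 3-sigma control-limit check
#'
#' Simplified process-control acceptance: a reference value is considered
#' reproduced when it falls within three simulated standard deviations of
#' the simulated mean.
#'
#' @param sim_mean,sim_sd Simulated mean and SD (sd >= 0).
#' @param reference_value Reference (experimental) value.
#' @return `TRUE` if `|reference - sim_mean| <= 3 * sim_sd`.
#' @export
three_sigma_check <- function(sim_mean, sim_sd, reference_value) {
  stopifnot(all(sim_sd >= 0))
  abs(reference_value - sim_mean) <= 3 * sim_sd
}

#' Mark-release dispersal and trapping validation experiment
#'
#' Emulates the mark-release-recapture design used to validate the model:
#' a cohort of 1,000 females released synchronously on day 1 from the
#' centre of a homogeneous 1 km2 orchard, oviposition and immigration
#' switched off, constant temperature, eight traps in pairs at 75, 150,
#' 300 and 600 m, run for 25 weeks and replicated with seeded streams.
#'
#' @param temperature Constant temperature (20, 25 or 30 in the reference
#'   design).
#' @param extrinsic_risk Adult extrinsic daily risk (0.02, or 0 for the
#'   no-natural-enemies case).
#' @param n_females Cohort size.
#' @param n_replicates Number of seeded replicates.
#' @param master_seed Master seed.
#' @param q Presence quantile for area/radius statistics.
#' @return A `medfly_dispersal` object; see [tidy.medfly_dispersal()] for
#'   the per-replicate metrics and [glance.medfly_dispersal()] for the
#'   across-replicate summary.
#' @export
validation_dispersal_experiment <- function(temperature = 25,
                                            extrinsic_risk = EXTRINSIC_RISK,
                                            n_females = 1000L,
                                            n_replicates = 5L,
                                            master_seed = 1L,
                                            q = 0.90) {
  cfg <- scenario_validation(temperature = temperature,
                             extrinsic_risk = extrinsic_risk,
                             n_females = n_females)
  reps <- run_replicates(cfg, n = n_replicates, master_seed = master_seed)
  metrics <- purrr::map_dfr(seq_along(reps$runs), function(i) {
    r <- reps$runs[[i]]
    died <- r$females$fate %in% c("dead_intrinsic", "dead_extrinsic")
    ps <- presence_statistics(r$presence, r$origin_sector, q = q)
    catches <- .catches_by_distance(r)
    tibble::tibble(
      replicate = i,
      mean_longevity = mean(r$females$age_at_death[died]),
      max_lifetime = max(r$females$age_at_death[died]),
      maturation_time = .maturation_days(temperature),
      explorers_beyond_site = sum(r$females$crossed_boundary),
      area_ha = ps$area_ha, radius_m = ps$radius_m,
      catch_75 = catches[["75"]], catch_150 = catches[["150"]],
      catch_300 = catches[["300"]], catch_600 = catches[["600"]]
    )
  })
  structure(list(metrics = metrics, temperature = temperature,
                 extrinsic_risk = extrinsic_risk, n_females = n_females,
                 q = q, runs = reps$runs, master_seed = master_seed),
            class = "medfly_dispersal")
}

.maturation_days <- function(temperature) {
  r <- maturation_rate(temperature)
  if (r <= 0) return(Inf)
  ceiling(MATURITY_AGE / r)
}

.catches_by_distance <- function(run) {
  out <- c("75" = 0, "150" = 0, "300" = 0, "600" = 0)
  ev <- run$trap_events
  if (length(ev$trap_id)) {
    dist <- run$traps$distance[match(ev$trap_id, run$traps$trap_id)]
    agg <- tapply(ev$count, as.character(dist), sum)
    out[names(agg)] <- agg
  }
  out
}

#' @export
print.medfly_dispersal <- function(x, ...) {
  cat(sprintf("<medfly_dispersal> %d C, extrinsic risk %.2f, %d females x %d replicates\n",
              x$temperature, x$extrinsic_risk, x$n_females, nrow(x$metrics)))
  print(glance(x))
  invisible(x)
}

#' Run an invasion experiment across replicates
#'
#' The propagule invasion protocol for one landscape preset and climate:
#' each replicate draws its own landscape realisation (seeded from the
#' master seed) and runs the full scenario. Marginalising over landscape
#' draws makes across-replicate detection and survival percentages a
#' property of the scenario class rather than of one particular mosaic.
#'
#' @param site Landscape preset (`"farm"`, `"urban1"`..`"urban4"`).
#' @param climate_name Climate preset (`"med"`, `"opt"`, `"const20"`,
#'   `"const25"`, `"const30"`).
#' @param n Number of replicates.
#' @param master_seed Integer master seed.
#' @param ... Passed to [scenario_config()] via [scenario_invasion()]
#'   (e.g. `duration_days`, `establishment_threshold`).
#' @return A `medfly_replicates` object.
#' @export
invasion_experiment <- function(site = "farm", climate_name = "med",
                                n = 15L, master_seed = 1L, ...) {
  runs <- lapply(seq_len(n), function(i) {
    seed_i <- .replicate_seed(master_seed, i)
    cfg <- scenario_invasion(site, climate_name, landscape_seed = seed_i, ...)
    run_simulation(cfg, seed = seed_i)
  })
  structure(list(runs = runs, config = list(site = site, climate = climate_name),
                 n = n, master_seed = master_seed),
            class = "medfly_replicates")
}

#' Detection and establishment summary across invasion replicates
#'
#' Summarises a replicate series of an invasion scenario the way the
#' propagule-fate experiments are reported: percentage of replicates with
#' medfly presence (any stage) at the horizon, adult survival percentage,
#' mean extinction day, detection percentage (any trap catch), first
#' detection day, catch size and female population at first detection,
#' stage-wise survivor counts, and the maximum adult count, with 95%
#' confidence limits (`1.96 * SD / sqrt(n)`).
#'
#' @param replicates A `medfly_replicates` object.
#' @return A one-row tibble of summary statistics; per-replicate values in
#'   attribute `"per_replicate"`.
#' @export
detection_summary <- function(replicates) {
  stopifnot(inherits(replicates, "medfly_replicates"))
  per <- purrr::map_dfr(seq_along(replicates$runs), function(i) {
    r <- replicates$runs[[i]]
    last <- nrow(r$daily)
    detected <- length(r$trap_events$day) > 0L
    first_det <- if (detected) min(r$trap_events$day) else NA_integer_
    first_n <- if (detected) {
      sum(r$trap_events$count[r$trap_events$day == first_det])
    } else NA_integer_
    females_at_det <- if (detected) r$daily$female_equiv[first_det] else NA_real_
    survived <- r$termination %in% c("horizon", "established") ||
      r$daily$female_equiv[last] > 0
    tibble::tibble(
      replicate = i,
      survived = survived,
      adult_survivors = r$daily$adults[last] *
        (r$termination != "extinct"),
      eggs_end = r$daily$eggs[last] * (r$termination != "extinct"),
      larvae_end = r$daily$larvae[last] * (r$termination != "extinct"),
      pupae_end = r$daily$pupae[last] * (r$termination != "extinct"),
      extinction_day = if (r$termination == "extinct") r$termination_day else NA_integer_,
      established = r$termination == "established",
      detected = detected,
      first_detection_day = first_det,
      n_trapped_at_detection = first_n,
      females_at_detection = females_at_det,
      max_adults = max(r$daily$adults)
    )
  })
  ci <- function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) return(NA_real_)
    1.96 * stats::sd(x) / sqrt(length(x))
  }
  mean_ <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  out <- tibble::tibble(
    n_replicates = nrow(per),
    survival_pct = 100 * mean(per$survived),
    adult_survival_pct = 100 * mean(per$adult_survivors > 0),
    established_pct = 100 * mean(per$established),
    detection_pct = 100 * mean(per$detected),
    extinction_day_mean = mean_(per$extinction_day),
    extinction_day_cl95 = ci(per$extinction_day),
    first_detection_day_mean = mean_(per$first_detection_day),
    first_detection_day_cl95 = ci(per$first_detection_day),
    n_trapped_at_detection_mean = mean_(per$n_trapped_at_detection),
    females_at_detection_mean = mean_(per$females_at_detection),
    females_at_detection_cl95 = ci(per$females_at_detection),
    max_adults_mean = mean(per$max_adults),
    max_adults_cl95 = ci(per$max_adults)
  )
  attr(out, "per_replicate") <- per
  out
}
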