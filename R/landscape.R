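#' Landscape structure specifications
#'
#' A site specification gives the percentages of sectors with no canopy
#' (buildings, roads), host trees and non-host trees. Five presets span a
#' fragmentation gradient from contiguous farmland to a sparse urban mosaic:
#'
#' | preset  | bare | host | non-host |
#' |---------|------|------|----------|
#' | farm    | 0    | 80   | 20       |
#' | urban1  | 20   | 40   | 40       |
#' | urban2  | 40   | 30   | 30       |
#' | urban3  | 60   | 20   | 20       |
#' | urban4  | 80   | 10   | 10       |
#'
#' @param bare,host,nonhost Cover percentages; must sum to 100.
#' @param name Optional label.
#' @return A `medfly_site_spec` list.
#' @export
site_spec <- function(bare, host, nonhost, name = "custom") {
  if (abs(bare + host + nonhost - 100) > 1e-8) {
    stop("cover fractions must sum to 100%", call. = FALSE)
  }
  structure(list(name = name, bare = bare, host = host, nonhost = nonhost),
            class = "medfly_site_spec")
}

#' @rdname site_spec
#' @param preset One of `"farm"`, `"urban1"`, ..., `"urban4"`.
#' @export
site_preset <- function(preset = c("farm", "urban1", "urban2", "urban3", "urban4")) {
  preset <- match.arg(preset)
  specs <- list(
    farm   = c(0, 80, 20),
    urban1 = c(20, 40, 40),
    urban2 = c(40, 30, 30),
    urban3 = c(60, 20, 20),
    urban4 = c(80, 10, 10)
  )
  p <- specs[[preset]]
  site_spec(p[1], p[2], p[3], name = preset)
}

#' Canopy trait parameters
#'
#' Mean and SD of per-sector canopy coverage (percent) and canopy diameter
#' (m) for host and non-host trees; draws are clipped to \[5, 100\]% and
#' \[1, 10\] m.
#'
#' @param host_cover,host_cover_sd,host_diam,host_diam_sd Host tree traits.
#' @param nonhost_cover,nonhost_cover_sd,nonhost_diam,nonhost_diam_sd
#'   Non-host tree traits.
#' @return A list of canopy parameters.
#' @export
canopy_params <- function(host_cover = 50, host_cover_sd = 15,
                          host_diam = 4, host_diam_sd = 1.5,
                          nonhost_cover = 60, nonhost_cover_sd = 18,
                          nonhost_diam = 5, nonhost_diam_sd = 1.8) {
  as.list(environment())
}

GRID_N <- 40L          # sectors per side
SECTOR_M <- 25         # sector side length, m
SECTOR_HA <- 0.0625    # sector area, hectares

# Row-major sector index from 0-based row/col.
.sector_index <- function(row, col) row * GRID_N + col + 1L

#' Generate a virtual landscape
#'
#' Builds a 1 km2 site of 40 x 40 square sectors, 25 x 25 m each, with a
#' cover class per sector (`bare`, `host`, `non_host`), a host identity for
#' host sectors (the four hosts contribute 1:1:1:1), and canopy traits.
#' The `farm` preset tiles the site with twenty-five contiguous 4-hectare
#' blocks (8 x 8 sectors) of a single host or non-host type with uniform
#' canopies ("regular blocks of trees of regular size"); urban presets
#' assign cover classes sector-by-sector at the specified fractions with
#' randomly varied canopy traits.
#'
#' @param site A [site_spec()] or preset name.
#' @param hosts Host trait table, see [host_table()].
#' @param canopy Canopy trait parameters, see [canopy_params()].
#' @param seed Integer seed; the same seed reproduces the landscape exactly.
#' @return A tibble of class `medfly_landscape` with one row per sector:
#'   `sector` (index), `row`, `col` (0-based), `x`, `y` (sector centre, m),
#'   `cover`, `host_id`, `suitability`, `canopy_coverage`, `canopy_diameter`,
#'   `trap_id` (NA until traps are placed).
#' @examples
#' farm <- generate_landscape("farm", seed = 1)
#' dplyr::count(farm, cover)
#' @export
generate_landscape <- function(site = "farm", hosts = host_table(),
                               canopy = canopy_params(), seed = 1L) {
  if (is.character(site)) site <- site_preset(site)
  stopifnot(inherits(site, "medfly_site_spec"))
  set.seed(seed)
  n <- GRID_N * GRID_N
  grid <- tibble::tibble(
    sector = seq_len(n),
    row = rep(0:(GRID_N - 1L), each = GRID_N),
    col = rep(0:(GRID_N - 1L), times = GRID_N)
  )
  grid$x <- (grid$col + 0.5) * SECTOR_M
  grid$y <- (grid$row + 0.5) * SECTOR_M

  if (site$name == "farm") {
    assign <- .assign_farm_blocks(grid, site)
  } else {
    assign <- .assign_urban(grid, site)
  }
  grid$cover <- assign$cover
  grid$host_id <- assign$host_id

  suit <- hosts$suitability[match(grid$host_id, hosts$host_id)]
  grid$suitability <- ifelse(grid$cover == "host", suit, 0)

  is_host <- grid$cover == "host"
  is_non <- grid$cover == "non_host"
  vary <- site$name != "farm"
  grid$canopy_coverage <- 0
  grid$canopy_diameter <- 0
  if (vary) {
    grid$canopy_coverage[is_host] <-
      .rnorm_clipped(sum(is_host), canopy$host_cover, canopy$host_cover_sd, 5, 100)
    grid$canopy_diameter[is_host] <-
      .rnorm_clipped(sum(is_host), canopy$host_diam, canopy$host_diam_sd, 1, 10)
    grid$canopy_coverage[is_non] <-
      .rnorm_clipped(sum(is_non), canopy$nonhost_cover, canopy$nonhost_cover_sd, 5, 100)
    grid$canopy_diameter[is_non] <-
      .rnorm_clipped(sum(is_non), canopy$nonhost_diam, canopy$nonhost_diam_sd, 1, 10)
  } else {
    grid$canopy_coverage[is_host] <- canopy$host_cover
    grid$canopy_diameter[is_host] <- canopy$host_diam
    grid$canopy_coverage[is_non] <- canopy$nonhost_cover
    grid$canopy_diameter[is_non] <- canopy$nonhost_diam
  }
  grid$trap_id <- NA_integer_

  structure(grid,
            class = c("medfly_landscape", class(tibble::tibble())),
            site = site, hosts = hosts, seed = seed)
}

# Farm layout: 5 x 5 tiling of 8x8-sector (4 ha) blocks; block types follow
# a diagonal round-robin (row + 2*col mod 5 over host1..host4, non_host),
# giving exactly 5 blocks of each of the four hosts (80% host cover) and 5
# non-host blocks, no two like blocks adjacent, the central block the host
# that starts fruiting soon after a day-90 arrival, and all four host types
# represented near the quarter centres where detection traps sit.
.assign_farm_blocks <- function(grid, site) {
  stopifnot(site$bare == 0, site$host == 80, site$nonhost == 20)
  block_row <- grid$row %/% 8L
  block_col <- grid$col %/% 8L
  type_cycle <- c(1L, 2L, 3L, 4L, NA_integer_)   # NA = non-host
  host_id <- type_cycle[((block_row + 2L * block_col) %% 5L) + 1L]
  cover <- ifelse(is.na(host_id), "non_host", "host")
  list(cover = cover, host_id = host_id)
}

.assign_urban <- function(grid, site) {
  n <- nrow(grid)
  n_bare <- round(n * site$bare / 100)
  n_host <- round(n * site$host / 100)
  n_non <- n - n_bare - n_host
  cover <- sample(rep(c("bare", "host", "non_host"), c(n_bare, n_host, n_non)))
  host_id <- rep(NA_integer_, n)
  k <- sum(cover == "host")
  host_id[cover == "host"] <- sample(rep_len(1:4, k))
  list(cover = cover, host_id = host_id)
}

#' Homogeneous orchard landscape for dispersal validation
#'
#' A uniform 40 x 40 host landscape (every sector the same fruiting host
#' with moderate ~4 m canopies), used by the mark-release dispersal and
#' trapping validation experiment.
#'
#' @param host_id Which host type fills the site (default 3).
#' @param hosts Host trait table.
#' @return A `medfly_landscape` tibble.
#' @export
homogeneous_landscape <- function(host_id = 3L, hosts = host_table()) {
  n <- GRID_N * GRID_N
  grid <- tibble::tibble(
    sector = seq_len(n),
    row = rep(0:(GRID_N - 1L), each = GRID_N),
    col = rep(0:(GRID_N - 1L), times = GRID_N)
  )
  grid$x <- (grid$col + 0.5) * SECTOR_M
  grid$y <- (grid$row + 0.5) * SECTOR_M
  grid$cover <- "host"
  grid$host_id <- as.integer(host_id)
  grid$suitability <- hosts$suitability[match(host_id, hosts$host_id)]
  grid$canopy_coverage <- 50
  grid$canopy_diameter <- 4
  grid$trap_id <- NA_integer_
  structure(grid,
            class = c("medfly_landscape", class(tibble::tibble())),
            site = site_spec(0, 100, 0, name = "homogeneous"),
            hosts = hosts, seed = NA_integer_)
}

#' Per-sector daily phenology state
#'
#' Evaluates [daily_host_state()] for every sector of a landscape on a
#' given day, before harvest removal. Bare sectors have zero attractiveness
#' and fruit.
#'
#' @param landscape A `medfly_landscape`.
#' @param day_of_year Day of year.
#' @return A tibble with `sector`, `attractiveness`, `fruit_fraction`.
#' @export
landscape_phenology <- function(landscape, day_of_year) {
  hosts <- attr(landscape, "hosts") %||% host_table()
  att <- numeric(nrow(landscape))
  fru <- numeric(nrow(landscape))
  for (i in seq_len(nrow(hosts))) {
    h <- hosts[i, ]
    idx <- if (is.na(h$host_id)) {
      landscape$cover == "non_host"
    } else {
      !is.na(landscape$host_id) & landscape$host_id == h$host_id &
        landscape$cover == "host"
    }
    if (!any(idx)) next
    st <- daily_host_state(h, day_of_year)
    att[idx] <- st$attractiveness
    fru[idx] <- st$fruit_fraction
  }
  tibble::tibble(sector = landscape$sector, attractiveness = att,
                 fruit_fraction = fru)
}

#' Apply harvest removal to a daily phenology state
#'
#' On and after each host's harvest day (through the post-harvest tail of
#' its fruiting window), the fruit fraction in every sector of that host is
#' multiplied by `1 - harvest_accuracy`; the residual unpicked fruit then
#' decays to zero with the bell's post-harvest tail. Idempotent on sectors
#' without fruit.
#'
#' @param state Per-sector state from [landscape_phenology()].
#' @param landscape The `medfly_landscape` the state was computed from.
#' @param day_of_year Day of year.
#' @return The state tibble with harvested `fruit_fraction`.
#' @export
apply_harvest <- function(state, landscape, day_of_year) {
  hosts <- attr(landscape, "hosts") %||% host_table()
  for (i in which(!is.na(hosts$host_id))) {
    h <- hosts[i, ]
    off <- .day_offset(((day_of_year - 1) %% 365) + 1, h$harvest_day)
    if (off >= 0 && off <= 0.3 * h$fruit_availability) {
      idx <- !is.na(landscape$host_id) & landscape$host_id == h$host_id &
        landscape$cover == "host"
      state$fruit_fraction[idx] <- state$fruit_fraction[idx] * (1 - h$harvest_accuracy)
    }
  }
  state
}

#' Place the four-trap detection grid
#'
#' One McPhail-type detection trap per site quarter, in the host-containing
#' sector nearest to a randomly jittered point close to the quarter centre
#' (pairwise spacing about 500 m). If a quarter holds no host sector the
#' trap falls back to the nearest host sector anywhere, with a warning.
#'
#' @param landscape A `medfly_landscape`.
#' @param n_traps Number of traps (4: one per quarter).
#' @param seed Integer seed for the jitter.
#' @param jitter_sd SD of the centre jitter, in sectors.
#' @return The landscape with `trap_id` set (1..4).
#' @export
place_detection_traps <- function(landscape, n_traps = 4L, seed = 1L,
                                  jitter_sd = 1.5) {
  stopifnot(n_traps == 4L)
  set.seed(seed + 101L)
  half <- GRID_N / 2
  centres <- expand.grid(qr = c(0, 1), qc = c(0, 1))
  landscape$trap_id <- NA_integer_
  host_rows <- which(landscape$cover == "host")
  if (length(host_rows) == 0L) stop("landscape has no host sectors", call. = FALSE)
  for (t in seq_len(4L)) {
    qr <- centres$qr[t]; qc <- centres$qc[t]
    target_row <- qr * half + half / 2 - 0.5 + stats::rnorm(1, 0, jitter_sd)
    target_col <- qc * half + half / 2 - 0.5 + stats::rnorm(1, 0, jitter_sd)
    in_q <- landscape$row %/% half == qr & landscape$col %/% half == qc
    cand <- which(in_q & landscape$cover == "host" & is.na(landscape$trap_id))
    if (length(cand) == 0L) {
      warning(sprintf("no host sector available in quarter %d; using nearest host sector", t))
      cand <- setdiff(host_rows, which(!is.na(landscape$trap_id)))
    }
    d2 <- (landscape$row[cand] - target_row)^2 + (landscape$col[cand] - target_col)^2
    landscape$trap_id[cand[which.min(d2)]] <- t
  }
  landscape
}

#' Place the eight-trap mark-release validation layout
#'
#' Eight traps in four pairs at 75, 150, 300 and 600 m from the release
#' sector at the site centre, pair members on opposite sides. Distances are
#' grid-snapped: 75/150/300 m lie exactly 3/6/12 sectors along an axis, and
#' the 600 m pair sits on the diagonal at 17 sectors per axis (601 m,
#' within half a sector of nominal).
#'
#' @param landscape A `medfly_landscape` (typically [homogeneous_landscape()]).
#' @return The landscape with `trap_id` 1..8 set; trap metadata (nominal
#'   distance per trap) in attribute `trap_distance`.
#' @export
place_validation_traps <- function(landscape) {
  c0 <- GRID_N %/% 2  # release sector (row, col) = (20, 20), 0-based
  offsets <- list(
    c(0, 3), c(0, -3),       # 75 m pair
    c(6, 0), c(-6, 0),       # 150 m pair
    c(0, 12), c(0, -12),     # 300 m pair
    c(17, 17), c(-17, -17)   # 600 m pair (601 m on the diagonal)
  )
  dist_nominal <- c(75, 75, 150, 150, 300, 300, 600, 600)
  landscape$trap_id <- NA_integer_
  for (t in seq_along(offsets)) {
    r <- c0 + offsets[[t]][1]; cc <- c0 + offsets[[t]][2]
    if (r < 0 || r >= GRID_N || cc < 0 || cc >= GRID_N) {
      stop("validation trap distance extends beyond the site", call. = FALSE)
    }
    landscape$trap_id[.sector_index(r, cc)] <- t
  }
  attr(landscape, "trap_distance") <- dist_nominal
  landscape
}

#' @export
print.medfly_landscape <- function(x, ...) {
  site <- attr(x, "site")
  cat(sprintf("<medfly_landscape> %s site: %d sectors (%d x %d, %.0f m each), %d traps\n",
              site$name %||% "custom", nrow(x), GRID_N, GRID_N, SECTOR_M,
              sum(!is.na(x$trap_id))))
  NextMethod()
}
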