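#' Plot a landscape mosaic
#'
#' Cover classes (and host identities) per sector, with trap positions
#' overlaid.
#'
#' @param object A `medfly_landscape`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.medfly_landscape <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$class <- ifelse(df$cover == "host", paste0("host ", df$host_id), df$cover)
  traps <- df[!is.na(df$trap_id), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$class)) +
    ggplot2::geom_tile(width = SECTOR_M, height = SECTOR_M) +
    ggplot2::geom_point(data = traps, shape = 24, size = 3, fill = "white",
                        colour = "black") +
    ggplot2::scale_fill_brewer(palette = "Set2") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x [m]", y = "y [m]", fill = NULL,
                  title = "Landscape mosaic (triangles: traps)")
}

#' Plot daily stage counts of a run
#'
#' @param object A `medfly_run`.
#' @param ... Unused.
#' @return A ggplot of daily eggs/larvae/pupae/adult females.
#' @export
autoplot.medfly_run <- function(object, ...) {
  long <- tidyr::pivot_longer(object$daily,
                              c("eggs", "larvae", "pupae", "adults"),
                              names_to = "stage", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data$count,
                                     colour = .data$stage)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "day post-invasion", y = "individuals on site",
                  colour = NULL)
}

#' Plot lifetime presence density of a dispersal experiment
#'
#' Presence-days per sector, summed across replicates, on the 1 km2 grid.
#'
#' @param object A `medfly_dispersal`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.medfly_dispersal <- function(object, ...) {
  pres <- Reduce(`+`, lapply(object$runs, `[[`, "presence"))
  df <- expand.grid(row = 0:(GRID_N - 1L), col = 0:(GRID_N - 1L))
  df$x <- (df$col + 0.5) * SECTOR_M
  df$y <- (df$row + 0.5) * SECTOR_M
  df$presence <- as.vector(t(pres))[.sector_index(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$presence)) +
    ggplot2::geom_tile(width = SECTOR_M, height = SECTOR_M) +
    ggplot2::scale_fill_viridis_c(trans = "sqrt") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x [m]", y = "y [m]", fill = "presence-days",
                  title = sprintf("Lifetime fly presence, %g C", object$temperature))
}

#' Plot catches against trap distance
#'
#' Mean lifetime catches per trap pair at each distance, with replicate
#' points.
#'
#' @param x A `medfly_dispersal` (or a list of them for several
#'   temperatures).
#' @return A ggplot.
#' @export
plot_catch_distance <- function(x) {
  xs <- if (inherits(x, "medfly_dispersal")) list(x) else x
  df <- purrr::map_dfr(xs, function(d) {
    m <- tidyr::pivot_longer(d$metrics,
                             dplyr::starts_with("catch_"),
                             names_to = "distance", values_to = "catch",
                             names_prefix = "catch_")
    m$distance <- as.numeric(m$distance)
    m$temperature <- factor(d$temperature)
    m
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance, y = .data$catch,
                                   colour = .data$temperature)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::labs(x = "trap distance from release point [m]",
                  y = "females caught per trap pair (lifetime)",
                  colour = "temp [C]")
}
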