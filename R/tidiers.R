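#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a dispersal validation experiment
#'
#' @param x A `medfly_dispersal` object.
#' @param ... Unused.
#' @return Per-replicate metrics: mean/max longevity, maturation time,
#'   number of females exploring beyond the site, presence area (ha) and
#'   radius (m), and lifetime catches per trap-pair distance.
#' @export
tidy.medfly_dispersal <- function(x, ...) x$metrics

#' Across-replicate summary of a dispersal validation experiment
#'
#' @inheritParams tidy.medfly_dispersal
#' @return One row of means and SDs across replicates.
#' @export
glance.medfly_dispersal <- function(x, ...) {
  m <- x$metrics
  num <- m[setdiff(names(m), "replicate")]
  out <- tibble::as_tibble(as.list(colMeans(num)))
  sds <- tibble::as_tibble(as.list(vapply(num, stats::sd, numeric(1))))
  names(sds) <- paste0(names(sds), "_sd")
  dplyr::bind_cols(
    tibble::tibble(temperature = x$temperature,
                   extrinsic_risk = x$extrinsic_risk,
                   n_replicates = nrow(m)),
    out, sds)
}

#' Tidy a replicate series
#'
#' @param x A `medfly_replicates` object.
#' @param ... Unused.
#' @return One row per replicate: termination, termination day, detection
#'   and end-state counts.
#' @export
tidy.medfly_replicates <- function(x, ...) {
  attr(detection_summary(x), "per_replicate")
}

#' Summary of a replicate series
#'
#' @inheritParams tidy.medfly_replicates
#' @return The one-row [detection_summary()] tibble.
#' @export
glance.medfly_replicates <- function(x, ...) detection_summary(x)

#' Tidy one replicate run
#'
#' @param x A `medfly_run`.
#' @param ... Unused.
#' @return The daily record tibble (stage counts, catches, temperatures).
#' @export
tidy.medfly_run <- function(x, ...) x$daily
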