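#!/usr/bin/env Rscript

# Movement-kernel calibration sweep.
#
# The hop-based movement kernel has a handful of free parameters (mean hops
# per day at 25 C, the gamma shape of the per-female mobility multiplier,
# the maturity hop factors and the young-phase directional persistence).
# They were tuned ONCE against the 25 C mark-release dispersal statistics
# (realized longevity, explorers beyond the site, 90% presence area and
# radius, lifetime catches of the 75-600 m trap pairs, and the
# no-extrinsic-mortality contrasts) and then frozen as the defaults of
# movement_params(). This script re-evaluates the frozen kernel and a small
# neighbourhood around it, so the choice can be audited or re-done.
#
# Usage: Rscript scripts/calibrate_movement.R [n_replicates] [master_seed]

suppressPackageStartupMessages(library(medflysim))

args <- commandArgs(trailingOnly = TRUE)
n_rep <- if (length(args) >= 1) as.integer(args[1]) else 10L
seed <- if (length(args) >= 2) as.integer(args[2]) else 42L

eval_kernel <- function(mv, temperature = 25, extrinsic = 0.02) {
  d <- validation_dispersal_experiment(temperature, extrinsic_risk = extrinsic,
                                       n_replicates = n_rep, master_seed = seed)
  g <- glance(d)
  c(longevity = g$mean_longevity, explorers = g$explorers_beyond_site,
    area_ha = g$area_ha, radius_m = g$radius_m,
    c75 = g$catch_75, c150 = g$catch_150, c300 = g$catch_300, c600 = g$catch_600)
}

frozen <- movement_params()
cat("Frozen kernel:\n")
str(frozen[c("mean_hops", "hop_dispersion", "maturity_factor",
             "persistence", "outside_attract", "return_prob")])

cat("\nReference statistics (homogeneous-orchard mark release, 25 C, 2%/day",
    "extrinsic risk):\n",
    "longevity 26.7 d | explorers 124.2 | area 45.0 ha | radius 418.8 m |",
    "pair catches 7.6 / 3.0 / 0.6 / 0.4\n\n")

cat("Frozen kernel, 25 C with extrinsic risk:\n")
print(round(eval_kernel(frozen), 1))
cat("\nFrozen kernel, 25 C without extrinsic risk",
    "(reference: longevity 41.8 d, area 56.3 ha):\n")
print(round(eval_kernel(frozen, extrinsic = 0), 1))

cat("\nLocal sensitivity (one parameter at a time):\n")
for (mh in c(0.8, 1.25) * frozen$mean_hops) {
  mv <- movement_params(mean_hops = mh)
  cat(sprintf("mean_hops = %.2f: ", mh)); print(round(eval_kernel(mv), 1))
}
for (disp in c(0.5, 2)) {
  mv <- movement_params(hop_dispersion = disp)
  cat(sprintf("hop_dispersion = %.1f: ", disp)); print(round(eval_kernel(mv), 1))
}
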