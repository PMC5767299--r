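---
title: "Simulating incipient medfly populations: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating incipient medfly populations: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medflysim)
```

## The problem

A handful of Mediterranean fruit flies (*Ceratitis capitata*) arriving in a
piece of infested fruit can found a population that lingers for months or
years at densities far below anything a surveillance trap network reliably
sees. Whether such an incipient population establishes, when it goes
extinct, and when (if ever) it is first detected are questions that cannot
be studied experimentally — releasing gravid medflies into a clean
landscape is not an option — so they are studied *in silico*.

`medflysim` is an individual-based, daily-time-step simulator of this
earliest phase of invasion. Space is a 1 km² site of 40 × 40 square
sectors, 25 m on a side — the scale of a single daily exploration errand.
Adult females are individual agents; immature stages are per-sector
cohorts; males are bookkeeping (a 1:1 sex ratio at emergence). The sole
external forcing is the average daily temperature.

## Climate

Two profile kinds are supported. Constant profiles hold one temperature all
year (the mark-release designs use 20, 25 and 30 °C). Sinusoidal profiles
produce a smooth skewed annual curve
$T(d) = \bar T + c_1\cos\theta + c_2\cos 2\theta$, with the two harmonics
solved so the curve attains the prescribed annual minimum and maximum while
averaging exactly to the prescribed mean (both harmonics integrate to zero
over a year). The packaged `climate_med()` (min 11, max 27, mean 20 °C,
a Cretan-type pattern) and `climate_opt()` (min 20, max 25, mean 22.9 °C)
share the same phase, warmest around day 210. Years are 365 days; leap
days are ignored.

Temperature enters the biology through three distinct channels:

* an **activity scalar** (`activity_scalar()`): 1 on the 20–25 °C
  plateau, linearly down to 0 at 11 °C, and modestly reduced on hot days
  (0.6 at 32 °C). It modulates realized daily fecundity.
* a **maturation/metabolic pace** (`maturation_rate()`, and its ratio to
  the 25 °C value, `movement_pace()`): anchored so that maturity onset
  (physiological age 11) takes 16, 9 and 6 calendar days at 20, 25 and
  30 °C. It drives the physiological-age clock, the daily hop counts, and
  (raised to an exponent, below) the oogenesis rate.
* a **senescence hazard multiplier** (`senescence_multiplier()`), described
  next.

Why three channels rather than one: the reference statistics force them
apart. Dispersal increases monotonically from 20 to 30 °C even though
lifespans shorten — so movement must follow the metabolic pace, not the
flat-plateau activity scalar. Realized longevities (35.1/26.7/16.9 d at
20/25/30 °C under a 2 %/day extrinsic risk) cannot be produced by the same
clock that yields 16/9/6-day maturation — so maturation and senescence are
modulated separately.

## Adult survival

Intrinsic (senescence) mortality is a discrete Gompertz hazard
$h(t) = \min(1, a e^{bt})$ at adult age $t$ days, with $a = e^{-170b}$ so
the hazard reaches exactly 1 at the 170-day truncation age, and $b$ solved
(deterministically, `gompertz_params()`) so the mean of the induced
lifespan distribution at the optimum is 79.1 days. Temperature scales the
hazard by a multiplier $k(T)$ with $k = 1$ at 22.5 °C; $k$ at the 20, 25
and 30 °C anchors is solved by 1-D root finding so that the *expected*
longevity under the 2 %/day extrinsic risk equals the realized anchors
above. Below 20 °C the multiplier is held at its 20 °C value (cool slows
metabolism; there is no basis for extrapolating cold stress steeper), and
log k is interpolated linearly between anchors. This hazard-multiplier
form — rather than rescaling the age axis — reproduces the
no-extrinsic-mortality contrast (mean lifespan 41.9 d expected at 25 °C
vs 41.8 reported) and keeps realized maximum lifespans in the reported
ranges at 25 and 30 °C. At 20 °C the model's maximum (~115 d) falls a few
days short of the reported 156.6 ± 12.5: the mean-79.1 Gompertz simply has
too thin a tail to give both the 35.1-day mean and that maximum under a
2 % daily risk; we keep the calibrated means and accept the shortfall.

Extrinsic mortality is a constant daily risk (default 2 %), weighted by
individual mobility (`min(2, 0.5 + 0.5z)`, mean ≈ 1 over the mobility
distribution): predation exposure scales with flight activity. This
weighting is what makes the no-extrinsic-mortality scenario qualitatively
different rather than just longer-lived — removing the risk
disproportionately frees the mobile minority that carries the dispersal
tail, widening the 90 % presence area from ~43 to ~52 ha.

## Immature development and survival

Each stage (egg, larva, pupa) develops by rate summation: a cohort gains
$1/D(T)$ progress per day, where the duration $D$ interpolates linearly
between the cool anchor (13 °C: 11/55/67 days) and the warm anchor
(30 °C: 3/8/9 days); below 11 °C development is arrested. Survival is
applied as a *daily* rate $s(T)^{1/D(T)}$ — at constant temperature a
completed stage realises exactly its cumulative survival bound
(0.60–0.90 / 0.19–0.80 / 0.26–0.70 across the thermal range), while slow
development accumulates proportionally more exposure. During cold arrest
(below 13 °C) torpid stages switch to flat overwintering rates (eggs 0.97,
larvae 0.988, pupae 0.994 per day), so winters decimate, but need not
annihilate, the immature stock; the winter bottleneck is the engine of the
extinction dynamics. Host suitability (0.60–0.90 by host) thins each stage
transition, and the pupa-to-adult transition additionally pays the 30 %
in-soil extrinsic loss. Harvest removes ripe fruit *with the eggs and
larvae inside it*: on a host's harvest day, in-fruit cohorts on that host
are thinned by the harvest accuracy (65–80 %) — a major regulator of the
effective reproduction rate. Emergence from one pupal batch is staggered
over 30 days with geometrically decaying weights tuned so 75 % emerge in
the first 10 days; emergers split 1:1 by sex and only females become
agents.

## Fecundity

The maximum daily fecundity envelope over physiological age is zero while
young (ages 1–10), rises linearly to the 16-egg ceiling at age 20,
plateaus through the 20–35 peak, and declines linearly with the endpoint
solved so the envelope sums to exactly 742 eggs. Realized daily fecundity
is a clipped normal draw (SD 2) around the envelope scaled by (i) a
field-realization fraction (0.9), (ii) the activity scalar, and (iii) the
oogenesis pace — the maturation-pace ratio raised to an exponent of 2.5 on
the cool side and entering linearly on the warm side. The realization
fraction and cool-side exponent are the two free demographic constants of
the model; they were calibrated once against the invasion experiments (the
constant-climate peak ordering 25 > 30 > 20 °C and the two-year
survival/detection percentages) and then frozen. Eggs are laid only into
fruit: the clutch is thinned by a saturating fruit-availability acceptance
(full at ≥ 30 % of peak fruit) and by a crowding factor
$1 - 0.5\,\max(0, i - 0.3)/0.7$ that is ≈ 1 at low-to-moderate sector
infestation $i$. A female's lifetime total can never exceed 742.

## Landscape and host phenology

Five site presets span a fragmentation gradient (bare/host/non-host
percentages 0/80/20 for farmland through 80/10/10 for sparse urban). The
farm preset tiles twenty-five contiguous 4-ha blocks (8 × 8 sectors) in a
diagonal round-robin over the four hosts plus non-host — exactly 1:1:1:1
hosts, no two like blocks adjacent, the central block the host that starts
fruiting soon after a day-90 arrival, and all four host types represented
near the quarter centres where the detection traps sit. Urban presets
assign cover sector-by-sector at the stated fractions with truncated-normal
canopy traits.

Host phenology is an asymmetric bell around each host's harvest day: a
slow half-Gaussian rise spanning the host's fruit-availability window
(65–85 days) and a faster decline over 30 % of the window after harvest.
With the packaged hosts (harvest days 90/170/250/350) the bells overlap so
fruit is available somewhere on every day of the year — the continuous
host succession of sub-tropical horticulture. Attractiveness tracks the
same bell between the host's seasonal bounds; non-host trees oscillate
mildly within 13–29 % and bear nothing.

## Movement

Daily movement is emulated, not imposed: each active female performs
$k \sim \text{Poisson}(\mu \cdot \text{pace}(T) \cdot m \cdot z)$ hops to
one of the eight adjacent sectors, weighted by local attractiveness plus a
baseline. Here $\mu = 2.6$ is the calibrated base rate, $m$ a maturity
multiplier (young 1.2, mature 0.56, old 0.6, very old 0.45 — dispersal
first, station-keeping around oviposition hosts at peak reproduction,
moderate wandering afterwards), and $z$ a per-female lifetime mobility
multiplier drawn from a gamma distribution with mean 1 and shape 1.
Young females add strong within-day directional persistence (a von
Mises-style weight with concentration 4 around a daily heading), making
their dispersal errands near-ballistic daily runs. Mature females whose
sector offers no usable fruit switch to host search: young-phase
persistence at an elevated rate, settling the moment a hop lands on
fruit. Hops across the site boundary are temporary explorations (same-day
return probability 0.8) or permanent emigration; when immigration is
enabled each emigrant is balanced by 0.25 expected immigrants initialised
at a random edge sector.

The kernel's free parameters were calibrated once against the 25 °C
mark-release statistics (realized longevity, explorers beyond the site,
90 % presence area and radius, trap-pair catches at 75–600 m, and the
no-extrinsic contrasts) and frozen; `scripts/calibrate_movement.R`
re-evaluates the frozen kernel and its local neighbourhood. Homogeneous
hop diffusion cannot reproduce these jointly — it ties the central trap
catches to the tail radius too tightly — which is why the kernel carries
individual mobility heterogeneity and young-phase persistence.

## Trapping

Each McPhail-type food-lure trap occupies one sector (the effective bait
attraction range). Bait efficacy decays multiplicatively by 0.5 %/day and
resets at the 60-day re-baiting. Female responsiveness to the lure is
piecewise linear over physiological age through the observed anchors
(40 % at emergence, 100 % peak at early maturity, 50 % at 45 days, 15 %
floor from 76 days), so it rescales automatically with the
temperature-dependent maturation pace. Capture requires activity around
the lure: every *arrival* into the trap sector during the day's errand is
an independent trial at
$p = 0.05 \times \text{bait} \times \text{responsiveness}$ (per-trial
probability never above the 5 % base risk), and a female residing in a
trap sector that currently bears fruit forages there and runs one
additional activity-scaled trial per day. Host-searching (food-deprived)
females respond to the food lure at full strength — the basis on which
protein lures work. Females sheltering in barren sectors, or arrested by
winter cold, are not exposed; this is what gives trap catches their
observed increase with temperature.

## The daily loop and experiments

Each simulated day executes a fixed order: temperature lookup; phenology
and harvest update; immature development and transitions; staggered
emergence; adult ageing with intrinsic and extrinsic mortality; movement
and boundary exchange; oviposition; trap servicing and capture trials;
recording. Replicates are seeded independently from a master seed and are
bit-reproducible.

Two experiment designs are packaged. The **mark-release validation**
(`validation_dispersal_experiment()`) releases 1,000 females at the centre
of a homogeneous orchard with oviposition and immigration off, constant
temperature, and eight traps in pairs at 75/150/300/600 m, for 25 weeks.
The **propagule invasion** (`scenario_invasion()`, `invasion_experiment()`)
drops 200 larvae (100 female-equivalents) near the site centre on day 90,
runs up to 100 weeks (700 days), and terminates early on extinction or on
establishment — a female population across all stages (immatures counted
at the 1:1 sex ratio) reaching 3,000. `invasion_experiment()` draws a
fresh landscape per replicate: urban outcomes vary strongly between
equally-specified mosaics, and marginalising over draws makes the
summaries a property of the scenario class rather than of one lucky or
unlucky map. Longevity summaries count only females with observed deaths
(trapped and emigrated females are excluded from the mean).

Two presence statistics summarise dispersal: the ranked-sector **area**
(smallest set of sectors holding 90 % of lifetime presence-days, in
hectares) and the **radius** (smallest radius around the release point
holding 90 %). They are deliberately not a filled-circle pair: the ranked
statistic exploits clustering and sampling noise and is systematically
smaller than the circle the radius implies.

## Problem sizes and what the tests show

The packaged experiments run at the reference design sizes: 1,000-female
cohorts over 175 days with 5 replicates for the validation suite, and
700-day invasions at 15 replicates per landscape (5 for the
constant-climate peak comparisons, 10 for the climate-contrast ratio).
The validation suite checks its statistics with the same 3-sigma
control-limit convention the reference experiments used; invasion
percentages are checked against exact binomial 95 % bands of the reported
15-replicate values.

Passing these checks shows that the simulator reproduces the reference
system's behaviour under its own idealised conditions — calm weather, a
year-round host succession, no pest management, no Allee effect. It does
not show that any particular real site behaves this way; the generator's
landscapes are statistical mosaics, not maps, and the climate is a smooth
annual curve without weather.

## Known limitations

* Two-year survival in host-rich landscapes (the farm and the densest
  urban mosaic) runs some 10–15 percentage points above the reported
  values: winter-2 extinction of large host-rich populations is
  under-expressed. The fragmented sites' survival is well centred.
* Fragmented-site detection is variable between landscape realisations
  and runs borderline-to-low against the moderately fragmented site's
  reported 93 % (the highest of all landscapes); the
  concentration-facilitates-detection effect is only partially
  reproduced.
* At 20 °C the realized maximum lifespan is a few days short of the
  reported value (see Adult survival).
* Hourly weather, wind-assisted dispersal, male biology beyond the sex
  ratio, diapause, and management interventions are out of scope.
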