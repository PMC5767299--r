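Package: medflysim
Title: Individual-Based Simulation of Incipient Mediterranean Fruit Fly
    Populations, Their Dispersal and Trap-Based Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A daily-time-step, individual-based stochastic simulator of
    incipient Mediterranean fruit fly (Ceratitis capitata) populations on a
    40 x 40 grid of 25 m landscape sectors. Couples climate forcing (constant
    or sinusoidal annual temperature profiles) to temperature-dependent
    immature development by rate summation, Gompertz adult senescence with a
    temperature-dependent hazard multiplier, age- and temperature-modulated
    female movement over host mosaics, age-dependent oviposition into host
    fruit, and McPhail-type food-lure trap capture with bait ageing. Ships
    generators for farm and fragmented urban landscape scenarios, a
    mark-release dispersal/trapping validation experiment, and a propagule
    invasion experiment suite with replicate summaries, establishment and
    detection statistics, and 3-sigma control-limit checks. Tidy interfaces:
    tibbles in and out, broom-style tidy()/glance() methods and ggplot2
    autoplot() methods for result objects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
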