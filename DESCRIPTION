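Package: migrahealth
Title: Dynamic Simulation of Climate-Related Migration and Population Health
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A discrete-time stock-and-flow simulator of climate-related
    migration, population health, health-care and environmental-service
    provision, and armed-conflict potential for one origin site and one
    destination site hosting immigrants and natives.  Each group carries
    stocks of population, health problems per capita (HP pc), and
    environmental problems (EP); per-period flows couple the groups through
    migration, HP/EP spillovers, and capacity-constrained allocation of
    health care (HC) and environmental services (ES).  The package builds
    the four reference storylines and their sensitivity variants, runs
    deterministic or seeded-stochastic simulations, detects steady states,
    and searches for the minimum sufficient HC capacity under access-barrier
    and quality policies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
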