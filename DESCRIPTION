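Package: dyncubeprod
Title: Growth-Coupled Reaction Deletion Strategies by Dynamic Solution-Space Division
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes reaction-deletion (knockout) strategies that couple
    growth to target-metabolite production in constraint-based metabolic
    models.  Implements the static solution-space subdivision searches
    GridProd (2-D over growth and production rate) and CubeProd (3-D over
    growth rate, production rate and total absolute flux), and their dynamic
    refinement DynCubeProd, which doubles the number of divisions per axis
    while pruning sub-spaces already proven infeasible at coarser levels and
    stopping at the first accepted strategy.  Reads SBML Level 3 (FBC) and
    BiGG JSON models, ships a small in-memory demonstration network and a
    seeded random-network generator for property testing, and includes a
    deterministic dense two-phase simplex solver sized for the small and
    medium models the subdivision search targets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
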