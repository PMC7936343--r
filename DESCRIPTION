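Package: micropatch
Title: Stochastic Host-Microbe Metapopulation Dynamics on Ephemeral Patches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Individual-based simulation of two microbial types (a fast and a
    slow grower) and their animal hosts on a landscape of ephemeral habitat
    patches.  Microbes grow within patches as a stochastic pure-birth (urn)
    process up to a carrying capacity, microbial load degrades patch quality
    and kills developing hosts, and surviving hosts disperse carrying a small
    random sample of their source patch's microbial community to found new
    patches.  The package provides the within-patch dynamics, the dispersal
    phase (uptake bottleneck, dispersal pool, host-independent migration), a
    synchronous cycle engine, an asynchronous generalisation with jittered
    development times and patch renewal, fixation-probability estimation,
    parameter sweeps, an exact dynamic-programming oracle for the pure-birth
    process, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
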