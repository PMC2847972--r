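Package: synkaryo
Title: Chromosomal Rearrangement Inference from Multi-Species Genetic Maps
Version: 1.0.0
Authors@R: person("synkaryo", "maintainers", email = "synkaryo@example.org",
    role = c("aut", "cre"))
Description: Reference-mediated comparative analysis of chromosomal evolution
    from genetic (linkage) maps of multiple related species. Projects each
    species' map onto a common reference via single-copy orthologous markers,
    partitions chromosomes into translocation segments with breakpoint
    regions, detects inverted marker blocks, times every rearrangement on a
    dated phylogeny by two-state parsimony, reconstructs ancestral
    karyotypes, estimates per-lineage rearrangement rates (events per million
    years) with min-max ranges for events of undetermined timing, and screens
    independent translocations for breakpoint reuse near centromeres. Ships
    a packaged set of Solanaceae observations (tomato, potato, eggplant,
    pepper, Nicotiana) and a seeded simulator of marker-map evolution
    (inversions, translocations, per-species marker dropout) whose true
    history serves as an oracle for every inference step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
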