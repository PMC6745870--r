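Package: phylosens
Title: Sensitivity of Community Phylodiversity Metrics to Taxon Sampling
    and Tree Choice
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Community phylogenetics toolkit centred on the standardized
    effect sizes (SES) of Faith's phylogenetic diversity, mean pairwise
    distance (MPD) and mean nearest taxon distance (MNTD) under a
    tip-label randomization null, with the picante sign convention
    (-NRI, -NTI).  Provides taxon subsampling strategies (uniform random,
    family-proportional, clade-restricted), paired comparisons of pattern
    classifications and SES distributions between methods, birth-death
    simulators for regional species pools and community assembly under
    neutral, filtering and repulsion scenarios, and runners for five
    sensitivity experiments probing how taxon count, sampling strategy,
    clade restriction, tree perturbation, and phylogram-versus-chronogram
    branch lengths change detected phylogenetic patterns.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
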