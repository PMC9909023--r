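Package: passar
Title: Passive-Sampling Species-Area Relationships for Microbial Communities
Version: 0.1.0
Authors@R: person("passar", "developers", role = c("aut", "cre"),
    email = "passar@example.org")
Description: Tools for testing the passive sampling hypothesis of the
    species-area relationship (SAR) on microbial count tables. Builds
    area-nested island models by randomly superimposing equal-area samples,
    fits power-law SARs in log-log space, computes Coleman's random-placement
    richness expectation stratified by abundance class, compares expectation
    with observation by paired t-tests, partitions pairwise beta diversity
    into replacement and richness-difference components, and computes
    weighted and unweighted UniFrac distances on a rooted phylogeny. A
    synthetic-community module (species-abundance-distribution pools and a
    dart-throwing placement simulator) provides fully reproducible inputs.
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
    vegan,
    withr
Config/testthat/edition: 3
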