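Package: kv4class
Title: Simulation, Feature Extraction and ACMG Classification for Kv4.1
    Channel Variants
Version: 0.1.0
Authors@R:
    person("kv4class", "maintainers", email = "kv4class@example.org",
           role = c("aut", "cre"))
Description: A pipeline for the functional assessment and clinical
    classification of variants in voltage-gated Kv4.1 (KCND1) potassium
    channels. Provides a phenomenological simulator of two-electrode
    voltage-clamp A-type current traces under the four canonical
    stimulation protocols (current-voltage family, prolonged decay step,
    double-pulse recovery, steady-state inactivation), fitting routines
    for double-exponential macroscopic inactivation, single-exponential
    recovery from inactivation and Boltzmann voltage dependences, one-way
    ANOVA with Dunnett many-to-one post hoc testing, a 29-item functional
    assessment registry scoring ACMG criterion PS3, and a points-based
    ACMG evidence combiner using gnomAD hemizygote counts and in-silico
    predictor consensus.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
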