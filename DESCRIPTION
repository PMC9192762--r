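Package: benthiso
Title: Isotope-Based Trophic and Nitrogen-Source Inference for Benthic Molluscs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for stable-isotope trophic ecology of benthic invertebrates
    in oxygen minimum zone sediments. Estimates trophic positions from
    compound-specific amino-acid nitrogen isotopes (glutamic acid and
    phenylalanine delta-15N) with analytical-error propagation and trophic
    classification; attributes inorganic nitrogen sources (dinitrogen, nitrate,
    ammonium) to chemoautotrophic symbionts by fractionation-window exclusion;
    checks a host-symbiont ammonium-recycling mass balance; estimates apparent
    RuBisCO carbon-isotope discrimination from dissolved inorganic carbon and
    tissue delta-13C; and computes blank-corrected, biomass-normalised net
    fluxes from closed-chamber incubations. A seeded synthetic-data generator
    reproduces the statistical structure of each input so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
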