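Package: explantr
Title: Quantification of Nuclear Signalling Gradients and Morphometrics in
    Zebrafish Embryos and Blastoderm Explants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying nuclear signal gradients and tissue shape
    from microscopy spot-detection exports. Projects detected nuclei onto a
    2D plane, re-centers explants on their wounding site, and computes
    nearest-reference distances in cell tiers; scores nuclear pSMAD2/3 by
    DAPI-normalized, background-subtracted intensity with bright-nucleus
    selection and domain classification; summarises nuclear beta-catenin
    counts and angular dispersion; measures explant morphometrics
    (circularity, extension length, cavity position, binned expression
    domains, domain areas, EVL intensity) and clone dispersal statistics.
    Includes a seeded synthetic-data generator emulating the geometric and
    intensity structure these analyses assume, so the whole pipeline can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
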