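Package: pubsem
Title: Multi-Method Latent Factor Models of Pubertal Development and
    Cortical Thickness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling pubertal development in early-adolescent
    girls from multi-method data: ordinal self-report items (Pubertal
    Development Scale and Tanner line drawings), repeated salivary hormone
    samples (DHEA, testosterone, estradiol) and single hair hormone
    concentrations.  Provides a synthetic-cohort generator with the full
    latent structure (per-hormone saliva factors, self-report factors,
    second-order adrenarche/gonadarche or overall puberty factors, same-day
    saliva residual covariance, age correlations, planted region-wise
    cortical-thickness effects); hormone cleaning (log transform,
    rank-preserving winsorization), composite scoring and MRI quality-control
    filtering; a structural-equation engine with maximum likelihood,
    full-information maximum likelihood for missing data, pairwise likelihood
    for ordinal indicators, Huber-White sandwich standard errors and the
    CFI, MFI, ECVI and SRMR fit indices; a factory for the one- and
    two-factor model variants; and region-wise latent-factor associations
    with cortical thickness over the 68 Desikan-Killiany regions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    mvtnorm,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
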