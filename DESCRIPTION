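Package: lpathway
Title: Limiting-Pathway Models of Epistasis and Phantom Heritability in Twin Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates nuclear families (parents, an offspring, its monozygotic
    and dizygotic co-twins) under basic and extended limiting-pathway (LP)
    models, in which the observed phenotype is the maximum (or minimum) of k
    latent additive pathway phenotypes. Provides twin-correlation and
    Falconer ACE variance-component estimators, a regression-based estimator
    of narrow-sense heritability, a shared-environment estimator at the final
    phenotype level, and phantom heritability. Includes a Monte-Carlo
    calibration routine that inverts pathway heritability and common-environment
    fraction to match observed MZ/DZ twin correlations, sweep drivers for
    sensitivity analyses, and a minimal pathway-threshold disease model.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
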