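Package: radbreaks
Title: Quantification of Radiation-Induced Plasmid DNA Damage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying ionizing-radiation-induced DNA damage in
    circular plasmid assays. Converts agarose-gel topology fractions
    (supercoiled, relaxed circular, linear) into mean single- and double-strand
    break numbers with the Cowan Poisson model, fits dose-response G-values
    (events per Mbp per Gy), quantifies base lesions and non-DSB clustered
    lesions from Fpg/Nth enzyme differences, computes damage-based relative
    biological effectiveness and hydroxyl-radical scavenging capacities, and
    measures apparent DNA contour lengths from AFM topography images via
    skeletonization and Freeman chain codes. A Monte Carlo generator simulates
    break-bearing plasmid populations, noisy gel lanes and rendered AFM images
    with retained ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
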