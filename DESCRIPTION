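Package: rgcrhythms
Title: Daily Rhythms in Retinal Ganglion Cell Light Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for day-night changes in retinal output measured
    with high-density multielectrode arrays. Classifies retinal ganglion cells
    as ON, ON-OFF or OFF by template matching on normalized cumulative spike
    distributions to full-field flashes, splits polarity classes into
    functional sub-clusters with PCA and silhouette-selected k-means, computes
    peak firing-rate statistics across Zeitgeber times, contrasts and
    genotypes, quantifies luminance-dependent polarity maintenance, fits
    fixed-period cosinor models to clock-gene expression time series, and
    extracts a-/b-wave amplitudes from flash electroretinograms. A synthetic
    data generator with known ground truth supports recovery and calibration
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
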