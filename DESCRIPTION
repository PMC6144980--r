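Package: chromaspace
Title: Generalized n-Dimensional Colour Vision Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Colour vision modelling for animals with any number of
    photoreceptor types. Builds the (i-1)-dimensional chromaticity space
    spanned by i equidistant receptor vectors and implements the colour
    hexagon, the Endler-Mielke colour space, and the linear and
    log-linear receptor-noise-limited models as special cases of one
    generic formulation, together with user-defined models, a
    noise-space transform that makes Euclidean distance equal
    receptor-noise chromatic distance, spectral data handling
    (reading, resampling, clamping, synthetic reflectance and
    sensitivity generators, packaged CIE D65), simulation harnesses
    (logistic midpoint sweeps, achromatic sweeps against chromatic
    backgrounds, photoreceptor-set screening, between-model rank
    concordance), tidy and glance methods, ggplot2 visualisations,
    and a command-line interface.
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
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
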