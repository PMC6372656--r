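Package: climAnalogs
Title: Climate-Analog Mapping with Sigma Dissimilarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for contemporary climate-analog mapping of cities under
    future climate scenarios. For each urban area the package locates the
    grid cell of a contemporary climate surface whose climate is most
    similar to the city's projected future climate under the sigma
    dissimilarity statistic: a Mahalanobis distance scaled by local
    interannual climatic variability (ICV) and converted to a multivariate
    z-score through chi-distribution percentiles. Includes gridded climate
    handling (seasonal aggregation, domain cropping, ensemble means),
    weather-station selection and inverse-distance-weighted combination for
    ICV covariance estimation, similarity surfaces, best-analog search with
    geodesic distance and initial bearing, novelty classification, cohort
    summaries, machine-readable layer export, and a synthetic-data
    generator so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    geosphere,
    jsonlite,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
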