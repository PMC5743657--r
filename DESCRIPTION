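Package: itvsampler
Title: Sampling-Effort Optimization for Intraspecific Trait Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to plan leaf-trait sampling campaigns when trait variation
    within tree crowns matters. Partitions trait variance across a nested
    canopy/plot design (quadrat, individual within quadrat, height class,
    external/internal crown position) by permutational ANOVA with
    Freedman-Lane permutation of reduced-model residuals; builds resampling
    precision curves of standard error against sample size and locates their
    flex point by segmented (broken-line) regression; simulates multistage
    stratified field-sampling strategies over a grid of individuals-by-leaves
    sampling sizes; and selects minimum and optimal sampling sizes by joint
    accuracy (mean within the whole-data confidence interval) and precision
    (standard error below the flex-point value) criteria. Includes a
    synthetic-data generator reproducing the hierarchical variance structure
    of an intensively sampled holm-oak (Quercus ilex) population, so the
    whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
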