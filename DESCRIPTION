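Package: cytokinedoe
Title: Stagewise Design-of-Experiments Optimization of Cytokine Schedules
    for In Vitro T-Cell Differentiation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for a stagewise design-of-experiments campaign that
    optimizes cytokine concentrations over a 42-day in vitro T-cell
    differentiation assay. Generates definitive screening designs from
    conference matrices and orthogonal central composite designs; analyzes
    screening runs by z-scoring cell counts against a control cocktail and
    selecting influential cytokines by minimum-BIC stepwise regression with
    effect heredity; fits full-quadratic response-surface models to
    square-root-transformed cell counts per population per 7-day interval;
    maximizes Derringer-Suich overall desirability by basin-hopping; and
    collapses per-interval optima into a three-stage protocol by exhaustive
    search over weekly stage boundaries. Includes a synthetic-data generator
    with time-varying ground-truth dose-response surfaces, and small
    bioassay utilities (ED50 by linear interpolation, cumulative fold
    expansion across passages, coating surface density, delta-Ct relative
    expression, and a normality-gated group comparison procedure).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
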