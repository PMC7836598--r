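Package: hypoxiaSig
Title: Hypoxia Gene-Signature Scoring and Prognostic Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives a tumor hypoxia gene signature from tumor-versus-normal
    expression studies intersected with a hallmark hypoxia gene set, computes
    per-sample median-dichotomized (+1/-1) hypoxia and
    epithelial-to-mesenchymal-transition scores, and runs the downstream
    prognostic analyses: Kaplan-Meier / log-rank stratification, univariate and
    forward likelihood-ratio multivariate Cox proportional-hazards models,
    Pearson and partial correlation, gene-wise score correlation screening,
    and clinical contingency tests. Ships a synthetic-cohort generator with
    planted ground truth (latent hypoxia factor driving expression, EMT and
    event hazard) so every stage of the pipeline can be exercised and
    calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
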