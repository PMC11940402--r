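Package: gliomapd
Title: Proliferation-Diffusion Invasiveness Profiling of Supramaximally
    Resected Glioblastoma
Version: 0.1.0
Authors@R:
    person("gliomapd", "maintainers", email = "gliomapd@example.org",
           role = c("aut", "cre"))
Description: Scores glioblastoma invasiveness from volumetric MRI measurements
    via the proliferation/diffusion (rho/D) ratio of the reaction-diffusion
    growth model, classifies extent of resection under the 2022 RANO-resect
    scheme and MGMT promoter methylation status, and runs the accompanying
    survival analysis (Kaplan-Meier estimation, proportional-hazards
    regression with univariable screening and invasiveness-stratified MGMT
    effects). Includes a radially symmetric Fisher-KPP simulator that
    validates the imaging-based rho/D estimator against virtual tumors with
    known parameters, and a synthetic-cohort generator that emulates the
    descriptive structure and planted survival effects of a supramaximal
    resection series so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
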