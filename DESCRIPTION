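Package: ihsim
Title: System-Dynamics Simulation of Disease Course in Idiopathic Hypersomnia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Target-seeking stock-and-flow simulation of the subjective
    disease course in idiopathic hypersomnia. Interview-derived clinical
    parameters are dynamized into yearly target schedules on a common
    [-100, 100] scale, integrated as negative-feedback levels with
    adjustment-time delays, and aggregated into twelve clinical state
    variables whose sum drives an overall-experience level. The simulated
    experience waveform is compared to the patient-reported course by
    matching derivative signs year by year, and scenario-level contribution
    tables (full duration, last five years, medicated patients) are
    summarised with Mann-Whitney comparisons. A calibrated synthetic cohort
    generator reproduces the marginal structure of the study population so
    the whole pipeline is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
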