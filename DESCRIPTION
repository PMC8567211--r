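Package: hehprofile
Title: Trisomy-Based Risk Profiling for High Hyperdiploid Childhood ALL
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for risk stratification of high hyperdiploid (51-65
    chromosomes) childhood B-cell precursor acute lymphoblastic leukaemia.
    Parses ISCN karyotype strings into whole-chromosome gain profiles,
    applies trisomy-based risk classifiers (the UKALL high hyperdiploid
    good/poor profile, COG double and triple trisomies, modal-number
    categories), provides survival machinery (Kaplan-Meier, log-rank, Cox
    models, Harrell's C-index), re-runs the profile-discovery pipeline
    (univariate screening, chromosome-gain clustering, best-subset and
    forward-stepwise selection by C-index, Mallows' Cp and BIC, decision-rule
    derivation), scans minimal-residual-disease thresholds for the optimal
    discriminative cutoff, and simulates synthetic cohorts with correlated
    chromosome gains and proportional-hazards outcomes so that every stage
    is testable without patient-level trial data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    mvtnorm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
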