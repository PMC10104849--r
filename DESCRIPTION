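Package: specdev
Title: Spectral Deviation Mapping of Neurophysiological Cortical Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Spectral Deviation Index (SDI), a per-patient,
    vertex-resolved measure of multi-frequency deviation of neurophysiological
    power spectra from a normative control cohort, together with the
    statistical machinery used to relate such maps to behavioural outcomes:
    vertex-wise general linear models with threshold-free cluster enhancement
    (TFCE) and permutation family-wise error control, seeded orthogonalized
    amplitude-envelope connectivity, leave-one-band-out AIC contribution
    analysis, bootstrap causal mediation, intraclass correlation for rating
    reliability, and simplified dysarthria-relevant acoustic features.
    Includes synthetic-cohort generators with ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
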