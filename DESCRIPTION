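Package: metabopls
Title: Binned 1H-NMR Metabolomics with Cross-Validated OPLS-DA Ensembles
Version: 1.0.0
Authors@R:
    person("Alex", "Reed", email = "alex.reed@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for two-group 1H-NMR metabolomics:
    synthetic cohort simulation (plasma-like CPMG and brain-extract spectra
    with known metabolite effects), chemical-shift referencing, 0.02-ppm
    sum binning, fixed-region and RSD-based noise exclusion, total-area and
    TSP normalization, from-scratch PCA and OPLS-DA with VIP scores,
    repeated stratified 10-fold cross-validation ensembles with
    permuted-label null distributions, and VIP-ranked direction-of-change
    reporting with Levene-gated t-tests and Cohen's d.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
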