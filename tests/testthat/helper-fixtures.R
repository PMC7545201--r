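# Shared fixtures, built once per test run and cached in this environment.
# Simulation parameters are the package defaults (the stated world); only
# iteration counts are reduced to keep the default suite fast.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures))
    assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

# A processed plasma cohort: referenced, binned, masked, normalized.
plasma_fixture <- function() cached("plasma", {
  design <- default_cohort_design("plasma", seed = 42)
  cohort <- simulate_cohort(design)
  spectra <- lapply(cohort$spectra, reference_spectrum)
  bm <- bin_cohort(spectra, cohort$metadata)
  policy <- default_exclusion_policy("plasma")
  bm <- apply_exclusions(bm, policy)
  bm <- detect_noise_bins(bm, policy)
  bm <- normalize_bins(bm, "total_area")
  list(design = design, cohort = cohort, bm = bm, policy = policy,
       groups = cohort$metadata$group)
})

cortex_fixture <- function() cached("cortex", {
  design <- default_cohort_design("cortex", seed = 43)
  cohort <- simulate_cohort(design)
  spectra <- lapply(cohort$spectra, reference_spectrum)
  bm <- bin_cohort(spectra, cohort$metadata)
  policy <- default_exclusion_policy("brain")
  bm <- apply_exclusions(bm, policy)
  bm <- detect_noise_bins(bm, policy)
  bm <- normalize_bins(bm, "total_area")
  bm <- normalize_bins(bm, "tsp")
  list(design = design, cohort = cohort, bm = bm, policy = policy,
       groups = cohort$metadata$group)
})

# Two well-separated Gaussian clouds along planted columns.
planted_matrix <- function(n_per = 15, p = 40, planted = 1, delta = 6,
                           seed = 7) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per * p), 2 * n_per, p)
  y <- rep(c("ctrl", "trt"), each = n_per)
  X[y == "trt", planted] <- X[y == "trt", planted] + delta
  colnames(X) <- paste0("v", seq_len(p))
  list(X = X, y = y, planted = planted)
}
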