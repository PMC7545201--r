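# Referencing, binning, exclusion masks, noise detection, normalization.

make_singlet <- function(center, ppm = seq(-0.5, 10, length.out = 10501),
                         hw = 0.004, height = 5, matrix = "brain",
                         id = "s1") {
  nmr_spectrum(ppm, height * hw^2 / ((ppm - center)^2 + hw^2), id, matrix)
}

test_that("referencing shifts the apex onto the target", {
  s <- make_singlet(0.013)
  r <- reference_spectrum(s, target = 0, search_window = c(-0.2, 0.2))
  expect_equal(r$shift_applied, -0.013, tolerance = 1e-3)
  apex <- r$ppm[which.max(r$intensity)]
  expect_lt(abs(apex), diff(s$ppm[1:2]) / 2 + 1e-12)
  # idempotence: re-referencing an already-referenced spectrum is a no-op
  r2 <- reference_spectrum(r, target = 0, search_window = c(-0.2, 0.2))
  expect_equal(r2$ppm, r$ppm)
  expect_identical(r2$intensity, r$intensity)
})

test_that("plasma referencing lands the lactate apex at 1.33", {
  d <- default_cohort_design("plasma", seed = 21)
  for (i in 1:3) {
    s <- reference_spectrum(simulate_spectrum(d, "A", i))
    win <- s$ppm > 1.2 & s$ppm < 1.45
    apex <- s$ppm[win][which.max(s$intensity[win])]
    expect_lt(abs(apex - 1.33), diff(s$ppm[1:2]) + 1e-12)
  }
})

test_that("referencing rejects windows with no detectable peak", {
  set.seed(1)
  ppm <- seq(-0.5, 10, length.out = 2000)
  flat <- nmr_spectrum(ppm, rnorm(2000, 0, 0.01), "flat", "brain")
  expect_error(reference_spectrum(flat, 0, c(-0.2, 0.2)),
               "no reference peak")
  s <- make_singlet(5)
  expect_error(reference_spectrum(s, 0, c(20, 21)), "does not overlap")
})

test_that("sum binning matches its definition and conserves intensity", {
  # 40 evenly spaced points on [0, 0.04) at constant intensity 1 -> two
  # bins of 20
  s <- nmr_spectrum((0:39) * 0.001, rep(1, 40), "const", "brain")
  b <- bin_spectrum(s)
  expect_identical(unname(b$values), c(20, 20))
  expect_identical(b$labels, c("b0.00_0.02", "b0.02_0.04"))
  # conservation on a realistic simulated spectrum
  d <- default_cohort_design("plasma", seed = 3)
  sp <- simulate_spectrum(d, "B", 1)
  bb <- bin_spectrum(sp)
  expect_equal(sum(bb$values), sum(sp$intensity), tolerance = 1e-12)
  expect_true(all(abs(bb$edges[, "hi"] - bb$edges[, "lo"] - 0.02) < 1e-9))
  expect_error(bin_spectrum(sp, width = 0), "width")
})

test_that("a peak straddling a bin edge keeps its total", {
  ppm <- seq(0, 1, length.out = 20001)
  mk <- function(center) {
    sigma <- 0.001 / sqrt(2 * log(2))
    nmr_spectrum(ppm, exp(-(ppm - center)^2 / (2 * sigma^2)), "g", "brain")
  }
  centred <- bin_spectrum(mk(0.51))   # mid-bin [0.50, 0.52)
  straddle <- bin_spectrum(mk(0.52))  # on the 0.52 edge
  tot_c <- centred$values[["b0.50_0.52"]]
  tot_s <- straddle$values[["b0.50_0.52"]] + straddle$values[["b0.52_0.54"]]
  expect_equal(tot_s, tot_c, tolerance = 1e-8)
  # brute-force oracle: direct summation over the same grid
  oracle <- sum(mk(0.52)$intensity[ppm >= 0.50 & ppm < 0.54])
  expect_equal(tot_s, oracle, tolerance = 1e-12)
})

test_that("default exclusions retain exactly the documented bin counts", {
  fx <- cortex_fixture()
  bm_brain <- apply_exclusions(
    bin_cohort(lapply(fx$cohort$spectra, reference_spectrum),
               fx$cohort$metadata),
    default_exclusion_policy("brain"))
  # (9.38 - 0.7)/0.02 - (6.0 - 5.0)/0.02 = 434 - 50 = 384
  expect_identical(sum(!bm_brain$excluded), 384L)
  expect_false(any(bm_brain$reason %in% "EDTA"))

  px <- plasma_fixture()
  expect_identical(sum(!px$bm$excluded), 366L) # 384 minus 18 EDTA bins
  expect_identical(sum(px$bm$reason == "EDTA", na.rm = TRUE), 18L)
})

test_that("exclusion flags are additive metadata with one reason per bin", {
  fx <- plasma_fixture()
  bm0 <- bin_cohort(lapply(fx$cohort$spectra, reference_spectrum),
                    fx$cohort$metadata)
  bm1 <- apply_exclusions(bm0, fx$policy)
  expect_identical(bm1$values, bm0$values) # audit: values untouched
  expect_true(all(!is.na(bm1$reason[bm1$excluded])))
  expect_true(all(is.na(bm1$reason[!bm1$excluded])))
  # a policy with zero regions flags nothing new
  empty <- exclusion_policy(data.frame(lo = numeric(0), hi = numeric(0),
                                       label = character(0)))
  expect_identical(apply_exclusions(bm0, empty)$excluded, bm0$excluded)
})

test_that("RSD noise detection separates noise from peak-bearing bins", {
  fx <- plasma_fixture()
  # pure-noise vs peak-bearing labels from a noiseless twin of the design
  quiet <- cohort_design("plasma", noise_sd = 0, shift_jitter_sd = 0,
                         baseline_amplitude = 0, abundance_sdlog = 0,
                         seed = 1)
  ref <- bin_spectrum(simulate_spectrum(quiet, "A", 1))
  lev <- ref$values[match(fx$bm$labels, ref$labels)]
  retained <- !fx$bm$excluded
  # pure noise: noiseless signal well below the noise level per bin
  # (noise_sd 0.02 over ~26 points gives a bin-sum sd of ~0.1)
  pure_noise <- retained & lev < 0.05
  expect_gt(sum(pure_noise), 50)
  expect_gte(mean(fx$bm$noise[pure_noise]), 0.9)

  # noiseless-peak cohort: biological RSD ~0.15 never crosses the threshold
  d0 <- cohort_design("plasma", noise_sd = 0, shift_jitter_sd = 0,
                      baseline_amplitude = 0, seed = 4)
  c0 <- simulate_cohort(d0)
  bm0 <- apply_exclusions(bin_cohort(c0$spectra, c0$metadata), fx$policy)
  bm0 <- detect_noise_bins(bm0, fx$policy)
  lev0 <- ref$values[match(bm0$labels, ref$labels)]
  expect_identical(sum(bm0$noise[!bm0$excluded & lev0 > 0.5]), 0L)
})

test_that("noise detection edge rules hold", {
  vals <- matrix(rep(c(1, 2, 3, 4), each = 4), nrow = 4) # constant columns
  bm <- metabopls:::new_binned_matrix(
    vals, cbind(lo = (0:3) * 0.02 + 1, hi = (1:4) * 0.02 + 1),
    metabopls:::bin_label((0:3) * 0.02 + 1, (1:4) * 0.02 + 1),
    "plasma", rep("g", 4))
  rownames(bm$values) <- bm$sample_ids <- paste0("s", 1:4)
  pol <- default_exclusion_policy("plasma")
  out <- detect_noise_bins(bm, pol)
  expect_false(any(out$noise)) # sd = 0 -> RSD 0, never flagged
  # a zero-mean bin is flagged outright and logged
  bm$values[, 2] <- c(-1, 1, -1, 1)
  out2 <- detect_noise_bins(bm, pol)
  expect_true(out2$noise[2])
  expect_true(is.infinite(out2$noise_log$rsd[2]))
  # fewer than 3 samples is a precondition violation
  bm2 <- bm; bm2$values <- bm2$values[1:2, ]
  expect_error(detect_noise_bins(bm2, pol), "at least 3 samples")
})

test_that("total-area normalization sums retained bins to 100", {
  fx <- plasma_fixture()
  keep <- !fx$bm$excluded & !fx$bm$noise
  sums <- rowSums(fx$bm$values[, keep, drop = FALSE])
  expect_equal(sums, setNames(rep(100, nrow(fx$bm$values)),
                              fx$bm$sample_ids), tolerance = 1e-8)
  # idempotent
  again <- normalize_bins(fx$bm, "total_area")
  expect_equal(again$values, fx$bm$values, tolerance = 1e-12)
})

test_that("total-area normalization is invariant to global row scaling", {
  fx <- plasma_fixture()
  bm0 <- bin_cohort(lapply(fx$cohort$spectra, reference_spectrum),
                    fx$cohort$metadata)
  bm0 <- detect_noise_bins(apply_exclusions(bm0, fx$policy), fx$policy)
  bm7 <- bm0
  bm7$values[3, ] <- 7 * bm7$values[3, ]
  n0 <- normalize_bins(bm0, "total_area")
  n7 <- normalize_bins(bm7, "total_area")
  expect_equal(n7$values[3, ], n0$values[3, ], tolerance = 1e-12)
})

test_that("TSP normalization pins the delta-0 bin to 1 (brain only)", {
  fx <- cortex_fixture()
  tsp_col <- which(fx$bm$edges[, "lo"] <= 0 & fx$bm$edges[, "hi"] > 0)
  expect_equal(unname(fx$bm$values[, tsp_col]),
               rep(1, nrow(fx$bm$values)), tolerance = 1e-12)
  px <- plasma_fixture()
  expect_error(normalize_bins(px$bm, "tsp"), "brain extracts only")
})
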