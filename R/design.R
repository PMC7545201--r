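# Cohort designs: the simulator's recipe object and its shipped defaults.

#' Define a two-group simulated NMR cohort
#'
#' A `cohort_design` fixes everything the simulator needs: group sizes, the
#' metabolite library, signed log2 fold changes applied multiplicatively to
#' group B, and the stochastic model (i.i.d. Gaussian spectral noise,
#' per-sample log-normal abundance variation, small chemical-shift jitter,
#' a smooth low-order baseline).
#'
#' @param matrix `"plasma"` or `"brain"`.
#' @param n_group_a,n_group_b group sizes (>= 2). Group A is the control-like
#'   group, group B the treated-like group.
#' @param effects named numeric vector of log2 fold changes (group B vs A);
#'   names must be metabolites of the library.
#' @param noise_sd sd of additive Gaussian noise per spectral point.
#' @param shift_jitter_sd sd (ppm) of the per-metabolite, per-sample chemical
#'   shift jitter.
#' @param baseline_amplitude maximum |amplitude| of the smooth quadratic
#'   baseline drift added to each spectrum. The input contract is
#'   already-corrected spectra, so the default models only a small residual
#'   drift (a few percent of the weaker metabolite peaks).
#' @param abundance_sdlog sdlog of the per-sample, per-metabolite log-normal
#'   abundance multiplier (biological variation).
#' @param ppm_grid numeric c(min, max, n_points); n_points >= 1000.
#' @param seed integer master seed for the cohort.
#' @param library optional list of [metabolite_template]s; defaults to
#'   [default_metabolite_library()] for `matrix`.
#' @param group_names length-2 named character vector `c(A = ..., B = ...)`
#'   used for metadata labels.
#' @return an object of class `cohort_design`.
#' @seealso [simulate_cohort()], [default_cohort_design()]
#' @export
cohort_design <- function(matrix,
                          n_group_a = 15L,
                          n_group_b = 14L,
                          effects = numeric(0),
                          noise_sd = 0.02,
                          shift_jitter_sd = 0.002,
                          baseline_amplitude = 0.05,
                          abundance_sdlog = 0.15,
                          ppm_grid = c(-0.5, 10.0, 14001L),
                          seed = 1L,
                          library = NULL,
                          group_names = c(A = "saline", B = "LPS")) {
  matrix <- match_matrix_type(matrix)
  n_group_a <- assert_count(n_group_a, "n_group_a", lower = 2L)
  n_group_b <- assert_count(n_group_b, "n_group_b", lower = 2L)
  assert_number(noise_sd, "noise_sd", lower = 0)
  assert_number(shift_jitter_sd, "shift_jitter_sd", lower = 0)
  assert_number(baseline_amplitude, "baseline_amplitude", lower = 0)
  assert_number(abundance_sdlog, "abundance_sdlog", lower = 0)
  seed <- assert_count(seed, "seed")
  if (length(ppm_grid) != 3L || !all(is.finite(ppm_grid)))
    stop_f("ppm_grid must be c(min, max, n_points)")
  if (ppm_grid[1] >= ppm_grid[2]) stop_f("ppm_grid min must be < max")
  if (ppm_grid[3] < 1000) stop_f("ppm_grid must have at least 1000 points")
  if (is.null(library)) library <- default_metabolite_library(matrix)
  if (is.null(names(library)))
    names(library) <- vapply(library, function(t) t$name, character(1))
  ok <- vapply(library, function(t) t$matrix %in% c(matrix, "both"),
               logical(1))
  if (!all(ok))
    stop_f("library templates not valid for matrix %s: %s", matrix,
           paste(names(library)[!ok], collapse = ", "))
  effects <- unlist(effects)
  if (length(effects)) {
    if (is.null(names(effects)) || any(!nzchar(names(effects))))
      stop_f("effects must be a named vector of log2 fold changes")
    if (!all(is.finite(effects))) stop_f("effects must be finite")
    bad <- setdiff(names(effects), names(library))
    if (length(bad))
      stop_f("effects name metabolites absent from the %s library: %s",
             matrix, paste(bad, collapse = ", "))
  }
  if (length(group_names) != 2L)
    stop_f("group_names must have two entries (A, B)")
  structure(list(matrix = matrix, n_group_a = n_group_a,
                 n_group_b = n_group_b, effects = effects,
                 noise_sd = noise_sd, shift_jitter_sd = shift_jitter_sd,
                 baseline_amplitude = baseline_amplitude,
                 abundance_sdlog = abundance_sdlog,
                 ppm_grid = c(ppm_grid[1], ppm_grid[2],
                              as.integer(ppm_grid[3])),
                 seed = seed, library = library,
                 group_names = c(A = unname(group_names[1]),
                                 B = unname(group_names[2]))),
            class = "cohort_design")
}

#' Shipped cohort designs
#'
#' Ready-made designs mirroring the shapes of an LPS-vs-saline study:
#' a strong-effect plasma cohort, a moderate-effect cortical brain cohort,
#' and a weak-effect hippocampal brain cohort, each 15 control vs 14 treated
#' animals. Effect directions follow the discriminatory metabolites of such
#' studies (plasma: lipoproteins and glucose down, isoleucine/leucine and
#' creatine up; brain: glutamine and NAA up, with additional cortical
#' decreases in alanine, glutamate, serine and aromatic amino acids).
#' Magnitudes are simulator choices, not measured values.
#'
#' @param profile `"plasma"`, `"cortex"` or `"hippocampus"`.
#' @param seed master seed passed to [cohort_design()].
#' @param ... further arguments overriding [cohort_design()] defaults.
#' @return a `cohort_design`.
#' @export
default_cohort_design <- function(profile = c("plasma", "cortex",
                                              "hippocampus"),
                                  seed = 1L, ...) {
  profile <- match.arg(profile)
  eff <- switch(profile,
    plasma = c(lipoprotein_hdl_ch3 = -0.8, lipoprotein_vldl_ch3 = -0.6,
               lipoprotein_ch2 = -0.8, isoleucine = 1.0, leucine = 1.0,
               glucose_alpha = -1.0, glucose_beta = -1.0, creatine = 0.8),
    cortex = c(glutamine = 0.8, naa = 0.8, alanine = -0.7, glutamate = -0.6,
               serine = -0.8, histidine = -0.6, phenylalanine = -0.6,
               glycerol = 0.7),
    hippocampus = c(glutamine = 0.4, naa = 0.35))
  matrix <- if (profile == "plasma") "plasma" else "brain"
  cohort_design(matrix = matrix, effects = eff, seed = seed, ...)
}

#' Ground truth table for a design
#'
#' Lists every non-zero planted effect with its expected direction and the
#' 0.02-ppm bins overlapping the metabolite's peak supports (center +/- HWHM).
#'
#' @param design a `cohort_design`.
#' @param width bin width in ppm.
#' @return data.frame with columns `metabolite`, `direction`
#'   (`"up"`/`"down"`), `bins` (comma-joined bin labels).
#' @export
ground_truth <- function(design, width = 0.02) {
  stopifnot(inherits(design, "cohort_design"))
  eff <- design$effects[design$effects != 0]
  if (!length(eff))
    return(data.frame(metabolite = character(0), direction = character(0),
                      bins = character(0), stringsAsFactors = FALSE))
  rows <- lapply(names(eff), function(nm) {
    pk <- design$library[[nm]]$peaks
    ks <- unlist(lapply(seq_len(nrow(pk)), function(i) {
      lo <- pk$center[i] - pk$half_width[i]
      hi <- pk$center[i] + pk$half_width[i]
      seq(floor(lo / width), floor(hi / width))
    }))
    ks <- sort(unique(ks))
    data.frame(metabolite = nm,
               direction = if (eff[[nm]] > 0) "up" else "down",
               bins = paste(bin_label(ks * width, (ks + 1) * width),
                            collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
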