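# Metabolite peak templates used by the cohort simulator.
#
# Chemical shifts and multiplet positions are library constants taken from
# standard 1H reference compilations (HMDB-style values at physiological pH).
# They are deliberately simple fixed multiplets: the downstream analysis only
# sees 0.02-ppm bin integrals, so J-coupling fine structure is not modelled.
# Half widths are HWHM in ppm; broad lipoprotein envelopes stand in for the
# residual macromolecule signal that survives a CPMG filter.

#' Construct a metabolite peak template
#'
#' A template is a named set of peaks (`center` ppm, `rel_intensity`,
#' `half_width` HWHM in ppm, `shape` lorentzian or gaussian) plus a base
#' abundance, valid for one or both sample matrices.
#'
#' @param name metabolite name (unique within a library).
#' @param matrix one of `"plasma"`, `"brain"`, `"both"`.
#' @param peaks data.frame with columns `center`, `rel_intensity`,
#'   `half_width`, `shape`.
#' @param base_abundance positive scalar; overall signal level.
#' @return an object of class `metabolite_template`.
#' @export
metabolite_template <- function(name, matrix, peaks, base_abundance) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!matrix %in% c("plasma", "brain", "both"))
    stop_f("template %s: matrix must be plasma, brain or both", name)
  peaks <- as.data.frame(peaks)
  need <- c("center", "rel_intensity", "half_width", "shape")
  if (!all(need %in% names(peaks)))
    stop_f("template %s: peaks need columns %s", name,
           paste(need, collapse = ", "))
  if (nrow(peaks) < 1L)
    stop_f("template %s: at least one peak required", name)
  if (any(peaks$center < -0.5 | peaks$center > 10.0))
    stop_f("template %s: peak centers must lie in [-0.5, 10] ppm", name)
  if (any(peaks$rel_intensity < 0) || sum(peaks$rel_intensity) <= 0)
    stop_f("template %s: rel_intensity must be >= 0 with positive sum", name)
  if (any(peaks$half_width <= 0))
    stop_f("template %s: half_width must be > 0", name)
  if (!all(peaks$shape %in% c("lorentzian", "gaussian")))
    stop_f("template %s: shape must be lorentzian or gaussian", name)
  assert_number(base_abundance, "base_abundance")
  if (base_abundance <= 0) stop_f("template %s: base_abundance must be > 0", name)
  structure(list(name = name, matrix = matrix, peaks = peaks,
                 base_abundance = base_abundance),
            class = "metabolite_template")
}

# terse constructor for the tables below
tpl <- function(name, matrix, abundance, centers, rels, hw,
                shape = "lorentzian") {
  metabolite_template(name, matrix,
                      data.frame(center = centers, rel_intensity = rels,
                                 half_width = hw, shape = shape),
                      abundance)
}

#' Built-in metabolite library
#'
#' Returns the default peak templates for a sample matrix. The plasma panel
#' covers the CPMG-visible small metabolites plus broad mobile-lipoprotein
#' envelopes (HDL/VLDL CH3 near 0.85-0.89 ppm, (CH2)n near 1.27 ppm) and the
#' lactate doublet used as the internal reference at delta 1.33. The brain
#' panel covers the aqueous-extract amino acids and NAA and includes the TSP
#' reference singlet at delta 0. Glucose multiplets are confined to the
#' retained 3.2-3.9 ppm window (the anomeric protons fall inside the
#' water/noise exclusion and are not modelled).
#'
#' @param matrix `"plasma"` or `"brain"`.
#' @return list of [metabolite_template] objects.
#' @export
#' @examples
#' names(default_metabolite_library("plasma"))
default_metabolite_library <- function(matrix) {
  matrix <- match_matrix_type(matrix)
  shared <- list(
    # lactate CH3 doublet centred on 1.33 (J ~ 7 Hz -> +/- 0.005 ppm at 700
    # MHz) plus the CH quartet collapsed to one line at 4.11. Abundance makes
    # it the tallest signal near 1.33 — the precondition for using it as the
    # plasma chemical-shift reference.
    tpl("lactate", "both", 9.0, c(1.323, 1.337, 4.11), c(1, 1, 0.35), 0.004),
    tpl("creatine", "both", 2.0, c(3.027, 3.93), c(1, 0.6), 0.004),
    tpl("alanine", "both", 0.9, c(1.475, 1.485), c(1, 1), 0.004),
    tpl("acetate", "both", 0.8, 1.92, 1, 0.004),
    tpl("glycine", "both", 1.0, 3.56, 1, 0.004)
  )
  plasma <- list(
    tpl("lipoprotein_hdl_ch3", "plasma", 7.0, 0.84, 1, 0.035),
    tpl("lipoprotein_vldl_ch3", "plasma", 6.0, 0.89, 1, 0.035),
    tpl("lipoprotein_ch2", "plasma", 7.0, 1.27, 1, 0.045),
    tpl("isoleucine", "plasma", 1.2, c(0.936, 0.944, 1.004, 1.012),
        c(1, 1, 0.8, 0.8), 0.004),
    tpl("leucine", "plasma", 1.5, c(0.953, 0.961, 0.969),
        c(0.9, 1, 0.9), 0.004),
    tpl("valine", "plasma", 1.0, c(0.985, 1.035), c(1, 1), 0.004),
    tpl("glucose_alpha", "plasma", 5.0, c(3.40, 3.53, 3.70, 3.82),
        c(0.6, 0.7, 0.8, 0.5), 0.005),
    tpl("glucose_beta", "plasma", 6.0, c(3.25, 3.45, 3.49, 3.88),
        c(0.8, 0.6, 0.7, 0.5), 0.005),
    # unaffected background: residual macromolecule hump surviving the CPMG
    # filter plus ubiquitous small metabolites. Without this, the few
    # effect-bearing lipoprotein envelopes carry almost the whole retained
    # area and total-area normalization's closure effect distorts every
    # direction of change.
    tpl("macromolecules", "plasma", 2.0, c(2.0, 2.9, 3.9), c(1, 0.7, 0.5),
        0.25, shape = "gaussian")
  )
  brain <- list(
    tpl("tsp", "brain", 3.0, 0.0, 1, 0.003),
    tpl("naa", "brain", 2.5, c(2.008, 2.49), c(1, 0.15), 0.004),
    tpl("glutamate", "brain", 1.8, c(2.06, 2.34, 3.75), c(0.6, 0.8, 0.4),
        0.005),
    tpl("glutamine", "brain", 1.8, c(2.13, 2.44, 3.77), c(0.6, 0.8, 0.4),
        0.005),
    tpl("glycerol", "brain", 1.2, c(3.56, 3.66, 3.78), c(0.8, 0.6, 0.4),
        0.005),
    tpl("serine", "brain", 1.0, c(3.835, 3.96), c(0.7, 1), 0.004),
    tpl("histidine", "brain", 0.6, c(7.07, 7.80), c(0.8, 1), 0.005),
    tpl("phenylalanine", "brain", 0.6, c(7.32, 7.37, 7.42), c(1, 0.9, 0.8),
        0.005),
    # unaffected background typical of aqueous brain extracts
    tpl("myo_inositol", "brain", 1.5, c(3.27, 3.53, 3.62, 4.06),
        c(0.6, 1, 0.9, 0.5), 0.005),
    tpl("taurine", "brain", 1.2, c(3.25, 3.42), c(1, 1), 0.005),
    tpl("choline", "brain", 0.8, 3.19, 1, 0.004),
    tpl("gaba", "brain", 0.9, c(1.89, 2.28, 3.01), c(1, 0.9, 0.9), 0.005)
  )
  lib <- c(if (matrix == "plasma") plasma else brain, shared)
  names(lib) <- vapply(lib, function(t) t$name, character(1))
  lib
}
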