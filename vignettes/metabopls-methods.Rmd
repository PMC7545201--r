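---
title: "Methods: simulated NMR cohorts, binning, and OPLS-DA ensemble validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated NMR cohorts, binning, and OPLS-DA ensemble validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`metabopls` implements a complete two-group ¹H-NMR metabolomics workflow of
the kind used to ask whether a systemic inflammatory challenge (e.g. a single
LPS injection in mice, versus saline) leaves a detectable metabolic signature
in plasma and in brain tissue: binned spectral features, an OPLS-DA
classifier validated by repeated cross-validation against a permuted-label
null, and a VIP-ranked direction-of-change table. Because studies of this
kind often leave their raw spectra unpublished, the package ships a
synthetic-cohort generator with known ground truth, so every downstream
claim can be tested against what was actually planted.

## 1. The simulated world

`simulate_cohort()` draws two groups (defaults 15 control vs 14 treated,
the usual size of such animal cohorts) of frequency-domain spectra on a
`(-0.5, 10)` ppm grid of 14,001 points (≈0.00075 ppm resolution, ≥26 points
per 0.02-ppm bin). Each spectrum is a sum of fixed metabolite multiplet
templates:

* **Plasma** (CPMG-style): sharp small-metabolite multiplets (isoleucine,
  leucine, valine, alanine, creatine, α/β-glucose confined to the retained
  3.2–3.9 ppm window, lactate) over broad mobile-lipoprotein envelopes
  (HDL/VLDL –CH₃ near 0.84/0.89 ppm, (–CH₂–)ₙ near 1.27 ppm) and a smooth
  unaffected macromolecule hump. CPMG relaxation filtering is emulated
  simply by the large half-widths of the lipoprotein templates — binning
  only ever sees the resulting line shapes.
* **Brain extract**: amino acids (alanine, glutamate, glutamine, serine,
  histidine, phenylalanine, GABA), NAA, glycerol, creatine, lactate,
  myo-inositol, taurine, choline, plus a TSP reference singlet at exactly
  δ0.

Peak positions and widths are **library constants** from standard
chemical-shift compilations (HMDB-style values), not measured quantities;
the analysis only needs plausible, mostly separated templates. Templates
use Lorentzian lines (HWHM 0.004–0.045 ppm); the macromolecule hump is
Gaussian so that far-field bins remain genuinely signal-free.

The stochastic model, per sample:

* a per-metabolite log-normal abundance multiplier, `sdlog = 0.15`
  (biological variation; gives across-sample bin RSDs of ~15%, comfortably
  under the 0.5 noise threshold);
* group-B abundances additionally multiplied by `2^(log2 fold change)` from
  the design's effect map;
* per-metabolite chemical-shift jitter, Normal(0, 0.002 ppm);
* a smooth quadratic baseline bounded by `baseline_amplitude = 0.05` — the
  pipeline's input contract is *already phased and baseline-corrected*
  spectra, so only a small residual drift is modelled;
* i.i.d. Gaussian point noise, `noise_sd = 0.02` (signal-to-noise of a few
  hundred for the major peaks, typical of a 700-MHz acquisition).

The noise level, biological coefficient of variation and effect sizes are
**simulator choices, not reported values** — the study this design mirrors
does not publish them. The shipped designs are: `plasma` (strong effects,
|log2 FC| 0.6–1.0: lipoproteins and glucose down, isoleucine/leucine and
creatine up), `cortex` (moderate: glutamine/NAA/glycerol up; alanine,
glutamate, serine, histidine, phenylalanine down), `hippocampus` (weak:
glutamine +0.4, NAA +0.35 only). Directions follow the discriminatory
metabolites such studies report; magnitudes were fixed once and are not
revisited.

Determinism: each spectrum's RNG substream is derived from
`(seed, group, sample_index)`, so identical designs are byte-identical and
cohorts can be generated in any order. Ground truth (metabolite, direction,
affected bins) is a pure function of the design, independent of the seed.

Three defects were found while validating the generator's realism and fixed
before the defaults were frozen: the plasma reference-search window had to
be narrowed to (1.31, 1.35) ppm so the lactate doublet, not the lipid
(CH₂)ₙ apex at 1.27 ppm, anchors the referencing; lactate was made the
dominant signal of that neighbourhood (the physical precondition for using
it as the reference); and unaffected background templates were added so
that effect-bearing metabolites do not carry nearly all of the retained
area (see §3 on closure). None of these changes touches a test tolerance or
an acceptance threshold.

## 2. Spectral processing

The pipeline order is fixed and recorded in provenance: **reference → bin →
fixed exclusions → RSD noise detection → normalization**.

* **Referencing** (`reference_spectrum`): the axis is shifted so the apex
  of the tallest peak in the search window lands on the target — TSP to δ0
  for brain, lactate to δ1.33 for plasma. Intensities are untouched. A
  window whose maximum does not clear the spectrum's noise floor
  (median + 5·MAD) is rejected rather than silently mis-referenced.
* **Binning** (`bin_spectrum`): half-open `[k·0.02, (k+1)·0.02)` ppm bins
  anchored at 0; the bin value is the plain *sum* of intensities falling
  inside, so total intensity is conserved exactly and boundary points have
  a deterministic home.
* **Fixed exclusions** (`apply_exclusions`): bins intersecting `< 0.7` ppm,
  `≥ 9.38` ppm and the 5.0–6.0 ppm water/noise region are flagged; plasma
  additionally masks four EDTA/Ca-EDTA/Mg-EDTA contamination windows
  (2.52–2.58, 2.68–2.74, 3.08–3.24, 3.58–3.65 ppm — the source protocol
  names EDTA without coordinates, so these literature resonances are
  defaults, not assertions). Flags are metadata: values are preserved for
  audit, which is also what makes TSP normalization possible after the δ0
  bin is masked. On the standard grid this retains exactly
  `(9.38−0.7)/0.02 − 50 = 384` bins before EDTA/noise masking. We
  considered widening the water mask to 4.5–6.0 ppm to cover residual
  water at δ4.7–4.9, but kept the listed 5.0–6.0 region as the default (the
  retained-bin arithmetic above is part of the package's contract); the
  bounds are configurable.
* **Noise detection** (`detect_noise_bins`): for each retained bin the
  across-sample `RSD = sd/|mean|` and the signal score `mean + sd` are
  computed; a bin is noise when `RSD > 0.5` **and** its score is below the
  0.75 quantile of all retained bins' scores (zero-mean bins are flagged
  outright). The conjunctive rule flags bins that are both unstable and
  weak. The floor quantile default of 0.75 reflects that metabolite peaks
  are sparse on a 0.02-ppm grid — typically well over half the retained
  bins are signal-free, so a low floor would protect most of them; with
  0.75 ≥90% of truly empty bins are caught while biological variation
  (~15% RSD) keeps genuine peaks unflaggable. Both knobs are exposed.
* **Normalization** (`normalize_bins`): `total_area` divides each row by
  its sum over retained, non-noise bins and rescales to 100 (idempotent,
  invariant to per-sample gain); `tsp` (brain only) divides each row by its
  δ0-bin value. For brain both are applied, total-area first — the order
  follows the source description's listing and is recorded in provenance.
  Note that TSP division effectively undoes total-area closure, restoring a
  per-sample internal-standard scale.

**Closure caveat.** Total-area normalization makes bin values
compositional: if the dominant signals decrease, every other bin's share
rises, and apparent directions of modest changes can flip. This is a real
property of the method, not a simulator artifact; it is why the plasma
library carries an unaffected background and why direction tables should be
read as *relative to total signal* for plasma.

## 3. Multivariate models

Scaling is learned from training rows only (`learn_scaling`): pareto
(divisor √sd) for PCA — the spectral-bin convention — and unit variance for
OPLS-DA, matching common chemometrics-package defaults; the source study
names pareto only for its PCA, so the OPLS-DA choice is ours and is
configurable and recorded. Zero-variance columns get divisor 1 and are
counted.

**PCA** (`fit_pca`) is the SVD of the scaled matrix; scores `UD`, loadings
`V`, explained variance the squared singular-value fractions.

**OPLS-DA** (`fit_opls_da`) follows the standard orthogonal-projections
scheme for a two-class response coded +1 (treated) / −1 (control), centred:

1. predictive weight `w = Xᵀy/‖Xᵀy‖`;
2. for each of `n_ortho` components: `t = Xw`, `p = Xᵀt/tᵀt`,
   `w_o ∝ p − (wᵀp)w` normalised, `t_o = Xw_o`, `p_o = Xᵀt_o/t_oᵀt_o`,
   deflate `X ← X − t_o p_oᵀ`;
3. final single predictive component `t = Xw`, `c = yᵀt/tᵀt` on the
   deflated matrix.

Because `t_oᵀy = 0` by construction, deflation never changes `w`; with
`n_ortho = 0` the model *is* a one-component PLS1 (verified against an
independent NIPALS oracle to 1e-10). `R²X` sums the explained scaled-X
variance over all components; `R²Y = c²tᵀt/‖y‖²`. `n_ortho` defaults to 1
(standard two-class practice; the original analysis does not state its
component count, so it is never auto-selected here).

Prediction deflates new rows by the stored orthogonal components, scores
`t = Xw`, and classifies by the sign of `t·c`; an exact tie goes to the
control class. **VIP** is defined on the predictive component only —
discriminatory relevance, not orthogonal variance — and with `‖w‖ = 1`
reduces to `VIP_j = √K·|w_j|`, so `mean(VIP²) = 1` exactly.

## 4. Ensemble validation

One **iteration** = one fresh random stratified 10-fold partition; each
fold's model is fit on the other nine folds and predicts the held-out fold,
so every sample is predicted exactly once per iteration. Per iteration we
record pooled accuracy, sensitivity and specificity (positive class =
treated), `Q² = 1 − PRESS/SS_y` over the pooled held-out predictions, and
the fold-averaged R²X/R²Y. With the default 100 iterations this yields the
conventional "ensemble of 1000 models", summarised as mean ± SEM with
`SEM = sd/√100` — the per-iteration accuracy is the unit of analysis (the
alternative, 1000 per-fold accuracies, would imply a √1000 divisor and is
deliberately not used). Stratification is the default because with ~14 per
class, unstratified folds are occasionally single-class.

The **permutation null** (`permutation_null`) repeats exactly this
procedure, drawing one fresh uniform label permutation per iteration, and
locates chance performance (≈50% accuracy, negative Q²).
`compare_to_null()` reports the mean differences and the empirical
`p = (1 + #{null ≥ observed mean})/(1 + iterations)` — floor 1/101 at 100
iterations; we prefer this over a t-test between ensembles because the
permuted ensemble *is* the null distribution.

Leakage control: scaling is always learned per training fold; when a
`noise_policy` is supplied in `cv_config`, RSD-noise bins are also
re-detected inside each training fold and dropped for that fold only.
`run_pipeline()` computes global noise flags for the audit artifacts but
hands the ensemble the in-fold policy, so relocating one sample between
folds changes only the affected folds' fitted parameters. Whether the
original in-house analysis detected noise inside or outside its CV loop is
not stated; both are explicit configuration here.

## 5. Reporting

`discriminant_report()` lists bins with `VIP > 1` (strict), sorted
descending, annotated against a chemical-shift table (every intersecting
interval; multi-hit bins joined with "/", e.g. broad HDL/VLDL overlaps;
unmatched bins "unassigned"), with the direction of the treated-vs-control
mean and a Levene-gated t-test: Levene's test (centre = mean, α = 0.05)
selects the pooled or Welch variant, Cohen's d uses the pooled SD, and an
optional square-root transform handles right-skewed measures. Stars follow
the */**/*** convention at 0.05/0.01/0.001. p-values are **unadjusted**
(matching field practice for these tables, and stated in the report
footer); a Benjamini–Hochberg column is emitted as a clearly-labelled
extension. Tests run on normalized bin values — not back-calculated
concentrations — which is an interpretation the report inherits. The
shipped shift table is derived from the simulator library (±max(2·HWHM,
0.01 ppm) per peak); at literature shift values the histidine and
phenylalanine aromatic intervals do not overlap on this grid, so joint
"Histidine/Phenylalanine"-style labels arise only in denser tables —
the mechanism is fully supported and tested.

## 6. What a green test establishes — and what it does not

The generator emulates line shapes, reference peaks, biological spread,
baseline drift and noise, but **not**: J-coupling fine structure, peak
warping/misalignment beyond a rigid shift, field-strength effects,
time-domain artifacts, or the crowded many-hundred-metabolite background
of real biofluids. Green recovery tests therefore establish that the
pipeline is *correct* (it finds what was planted, at the planted
direction, and nothing under permuted labels) — not that it would achieve
any particular accuracy on real spectra. Conversely, the permutation-null
results (~50% accuracy, negative Q²) are data-independent properties of
the validation machinery and are directly comparable to published null
values.

Numerical conventions worth knowing: bin grids are anchored at 0 with
half-open intervals; equal-width checks use a 1e-9 tolerance; row sums
after total-area normalization are exact to 1e-8 relative; OPLS-DA rejects
`n_ortho` at or beyond the rank bound and degenerate orthogonal
components; `Q²` may be arbitrarily negative; classification ties (score
exactly 0) go to the control class and are deterministic; all RNG flows
through named, independently-seeded streams (simulate / cv / permute).
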