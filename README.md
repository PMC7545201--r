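# metabopls

Two-group ¹H-NMR metabolomics at desk scale: simulate plasma-like (CPMG)
and brain-extract spectra with known metabolite effects, process them into
a binned feature matrix (referencing, 0.02-ppm sum binning, fixed-region
and RSD-based exclusion, total-area/TSP normalization), discriminate the
groups with OPLS-DA validated by repeated cross-validation against a
permuted-label null, and report VIP-ranked discriminatory bins with their
direction of change.

The intended user is anyone analysing (or teaching, or stress-testing) the
classic inflammation-metabolomics design — e.g. LPS-treated vs saline
mice, ~15 animals per group — where the headline claim is of the form
*"an ensemble of 1000 OPLS-DA models predicted treatment group with
97 ± 1.1% accuracy, versus ~50% for permuted labels"*. Every stage of that
claim is implemented here as tested, reusable code with a synthetic ground
truth to validate against.

## The statistics at the core

* **OPLS-DA** (Trygg–Wold): for class response y ∈ {+1, −1} on
  column-scaled X, predictive weight **w** = Xᵀy/‖Xᵀy‖; `n_ortho`
  orthogonal components (w_o ∝ p − (wᵀp)w, t_o = Xw_o, deflate by
  t_o p_oᵀ) are removed before the single predictive component t = Xw,
  c = yᵀt/tᵀt. Prediction is sign(t_new·c); ties go to control.
* **VIP** on the predictive component: VIP_j = √K·|w_j|, so
  mean(VIP²) = 1; bins with VIP > 1 are the discriminatory set.
* **Ensemble validation**: 100 iterations × stratified 10-fold CV (an
  ensemble of 1000 models); per iteration every sample is predicted
  exactly once, giving pooled accuracy/sensitivity/specificity and
  Q² = 1 − PRESS/SS_y; summaries are mean ± SEM with SEM = sd/√100.
  The permutation null repeats the identical procedure with labels
  freshly shuffled each iteration; the empirical p-value is
  (1 + #{null ≥ observed})/(1 + iterations).
* **Direction of change**: per-bin independent t-tests, pooled or Welch
  as selected by Levene's test (centre = mean, α = 0.05), Cohen's d
  (pooled SD), stars at 0.05/0.01/0.001, unadjusted (BH column provided
  as a labelled extra).

See `vignettes/metabopls-methods.Rmd` for the full model, parameter
rationale, and limitations.

## Worked example

```r
library(metabopls)

cfg <- run_config(profile = "plasma", out_dir = "plasma_run",
                  iterations = 100,
                  seed_simulate = 1, seed_cv = 2, seed_permute = 3)
res <- run_pipeline(cfg)
print(res$observed)
print(res$null)
print(res$comparison)
```

which prints (numbers from this exact run):

```
<ensemble_result (true labels): 100 iterations x 10-fold CV>
  accuracy      100.000 +/- 0.000
  sensitivity   100.000 +/- 0.000
  specificity   100.000 +/- 0.000
  q2              0.885 +/- 0.001
  r2x             0.812 +/- 0.000
  r2y             0.932 +/- 0.000
<ensemble_result (permuted labels): 100 iterations x 10-fold CV>
  accuracy       51.241 +/- 1.176
  sensitivity    50.714 +/- 1.497
  specificity    51.733 +/- 1.206
  q2             -0.331 +/- 0.031
  r2x             0.787 +/- 0.001
  r2y             0.334 +/- 0.008
<null_comparison: accuracy 100.0% vs null 51.2%, empirical p = 0.009901>
```

Reading: the simulated LPS-vs-saline plasma cohort (15 vs 14, planted
|log2 FC| 0.6–1.0 on lipoproteins ↓, glucose ↓, isoleucine/leucine ↑,
creatine ↑) is perfectly separable by the true-label ensemble (Q² 0.885),
while the permuted-label ensemble sits at chance (51.2%) with negative Q²
— so the separation is signal, not overfitting; p = 0.0099 is the floor
attainable with 100 null iterations. `res$report` then lists the VIP > 1
bins; its head for this run:

```
         bin      vip                              annotation direction            p stars
1 b3.02_3.04 1.254340                 macromolecules/creatine         ↑ 7.946832e-11   ***
2 b0.96_0.98 1.251103                          leucine/valine         ↑ 1.042694e-10   ***
3 b1.00_1.02 1.246987                              isoleucine         ↑ 1.460337e-10   ***
4 b3.40_3.42 1.244126            glucose_alpha/macromolecules         ↓ 3.387511e-10   ***
```

— creatine and branched-chain amino acids up, glucose down, exactly the
planted signature. All artifacts (binned matrix, bin mask with reasons,
per-iteration metrics, report CSV/Markdown, provenance with digests) are
written to `out_dir`.

A command-line front end mirrors the same stages:

```sh
Rscript inst/scripts/metabopls simulate --profile cortex --seed 3 --out cohort/
Rscript inst/scripts/metabopls run-all  --profile cortex --seed 3 --out run/
```

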