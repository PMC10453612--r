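# rescuekit

Tools for quantifying how blood serum or receptor ligands rescue cancer
cells from growth inhibition by targeted drugs. EGFR-blocking drugs can
arrest tumour-cell growth in clean medium yet lose potency when serum
components or EGF re-activate the blocked signalling axis; demonstrating
and measuring that rescue spans four assay types, and this package
implements the quantitative analysis for all of them:

* **Dose-response** — growth normalisation against background-subtracted
  controls; median-effect fitting of $f_a/f_u = (D/D_m)^m$ (so $D_m$ is the
  IC50 and $m$ the dose-effect shape); the closed-form
  $IC_{50} = D/(100/y-1)^{1/m}$; and the Loewe combination index
  $CI = d_1/D_{x,1} + d_2/D_{x,2}$ with conventional
  synergy/additivity/antagonism bands.
* **Single-cell kinase activity** — ERK-KTR reporter quantification from
  two-channel fluorescence fields: illumination correction, Otsu nuclei
  segmentation, 10-px cytoplasm-ring extension with nearest-nucleus
  assignment, per-cell cytoplasm/nucleus median-intensity ratios, and
  declared artifact screens.
* **Cell-cycle fractions** — G0/G1, S, G2/M estimation from DNA-content
  event lists by constrained maximum-likelihood mixture fitting
  (Dean-Jett-Fox-style broadened S phase, G2/M pinned near twice the G1
  mean), plus replicate-level comparisons with t-tests.
* **Differential expression and core gene groups** — a self-contained
  negative-binomial Wald caller (median-of-ratios size factors, moderated
  dispersion, moderated-t reference) with BH-FDR control; drug *core gene
  groups* (drug DEGs that become non-differential under a rescuing
  modulator) and their restored fractions; and a permutation test for
  gene-set overlap validated against the exact hypergeometric null.
* **Pathway activation levels (PAL)** — geometric-mean (case-to-normal
  ratio) normalisation and the signed, role-weighted score
  $PAL = K \sum_g ARR_g \log_{10} CNR_g / \sum_g |ARR_g|$ over
  user-supplied GMT gene sets, with group comparison and BH adjustment.

A first-class synthetic-data module (`sim_dose_response()`,
`sim_ktr_field()`, `sim_dna_histogram()`, `sim_counts()`) generates every
input type with known ground truth, so the whole pipeline is validated by
round-trip recovery without any external data. Everything takes and
returns ordinary data frames/tibbles and composes with the pipe; fitted
objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

Fit a noisy simulated titration and read off the IC50:

```r
library(rescuekit)

tab <- sim_dose_response(m = 2, Dm = 300, doses = 50 * 2^(0:7),
                         noise_sd = 0.02, seed = 1)
fit <- fit_median_effect(tab)
fit
#> Median-effect fit
#>   m (shape): 1.9532
#>   Dm (IC50): 289.2
#>   r: 0.9994
#>   points: 8 (0 dropped)
```

The planted shape (2) and median-effect dose (300, in drug units such as
nM) are recovered within the noise; `r` is the correlation of the
linearised fit, and `glance(fit)` returns the same numbers as a one-row
tibble. `ic50(100, 20, 1)` gives `25`: a drug leaving 20% growth at dose
100 with slope 1 halves growth at dose 25.

The end-to-end demonstration generates a full synthetic experiment (dose
tables, reporter fields, DNA histograms, counts with planted rescued
genes) and runs all five stages:

```r
demo <- run_demo(seed = 1)
demo
#> Synthetic rescue-experiment demo (seed 1 )
#>   dose: m 1.95 (true 2.0), IC50 287.2 (true 300), CI 2.61 (moderate antagonism)
#>   ktr: control C/N 2.51 (true 2.5), drug relative activity 0.40
#>   cycle: G1 shift +20.5 points (p = 3.79e-05)
#>   degs: 149 drug DEGs; restored 76.5% (serum), 100.0% (EGF)
#>   pal: top changed pathway 'planted_drug_suppressed'
```

Reading the report: the drug + modulator combination scores CI 2.61
(antagonistic — the modulator works against the drug, i.e. rescues the
cells); drug treatment drops reporter C/N activity to 0.40 of control;
the drug arm shows a significant ~20-point G0/G1 arrest; 76.5% of the
drug's expression signature reverts under serum and all of it under EGF
(planted: 75% and 100%); and the pathway built from the planted
drug-suppressed genes ranks first by activation change. Rerunning with the
same seed reproduces the report bit-identically; `run_demo(seed = 1,
out_dir = "results")` also writes it as JSON.

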