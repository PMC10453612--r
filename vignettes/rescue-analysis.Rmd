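---
title: "Quantifying serum and ligand rescue of drug-inhibited cancer cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying serum and ligand rescue of drug-inhibited cancer cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rescuekit)
```

## The problem

Targeted drugs that block a growth-factor receptor (for instance EGFR
inhibitors in squamous carcinoma models) can arrest tumour cell growth in
clean culture medium and still fail in patients. One proposed reason is the
patient's own blood: serum components and receptor ligands such as EGF can
partially re-activate the blocked signalling axis and "rescue" the cells.
Measuring that rescue quantitatively takes several assays analysed
together:

* **dose-response**: how much drug is needed to halve growth, with and
  without the rescuing supplement, and whether the combination is
  antagonistic;
* **single-cell kinase activity**: whether the downstream kinase (ERK, read
  out by a translocation reporter) is re-activated;
* **cell-cycle distributions**: whether the drug-induced G1 arrest is
  released;
* **transcriptomics**: which drug-induced expression changes revert when the
  supplement is co-applied (the drug's *core gene group*), and which
  pathways those genes implicate.

rescuekit implements each stage as ordinary R functions over data frames and
matrices, plus a synthetic-data module that generates every input type with
known ground truth. The synthetic route is not a convenience: it is how the
package demonstrates, in its tests, that each estimator actually recovers
what was planted.

## Dose-response: the median-effect model

Growth at dose $D$ is normalised to percent of the untreated control after
subtracting the background cell number present at treatment start
(`normalize_growth()`). The dose-effect relationship is modelled by the
median-effect law

$$\frac{f_a}{f_u} = \left(\frac{D}{D_m}\right)^m,$$

where $f_a$ is the fraction affected ($1 - \text{growth}/100$), $f_u = 1 -
f_a$, $D_m$ the median-effect dose (the IC50), and $m$ the shape
coefficient. `fit_median_effect()` fits the linearised form
$\log_{10}(f_a/f_u)$ versus $\log_{10} D$ by least squares, which is exact
on model data and transparent about fit quality through the correlation
$r$. Points at or beyond 0% or 100% growth carry no information on the
log-odds scale; they are excluded and counted rather than clamped, since any
clamping constant would silently bias the slope.

A single observed (dose, growth) pair yields an IC50 through the closed
form `ic50(D, y, m)` $= D/(100/y - 1)^{1/m}$, useful when a full titration
is not available but the shape is known.

Antagonism between the drug and a rescuing supplement is scored by the
Loewe combination index,

$$CI = \frac{d_1}{D_{x,1}} + \frac{d_2}{D_{x,2}},$$

where $D_{x,i}$ is the dose of agent $i$ alone that produces the chosen
effect level under its own median-effect fit. CI near 1 is additivity,
below 1 synergy, above 1 antagonism; the default classification bands
(0.9, 1.1, 3.3) follow the conventional scale and are configurable. A
fixed-level supplement such as serum has no dose axis of its own in the
combination well, so the package treats the supplement's own titration as
agent 2 and evaluates CI at the observed combined effect level. This was a
genuinely open design point: the alternative — folding the supplement into
a modified drug curve — yields no separable $D_{x,2}$ and makes the score
incomparable across supplements. The chosen convention keeps both terms
well defined and reproduces the qualitative antagonism bands; the effect
level is an explicit argument so users can probe its sensitivity.

## Single-cell KTR quantification

A kinase translocation reporter leaves the nucleus when phosphorylated, so
per-cell kinase activity is the ratio of median reporter fluorescence in
the cytoplasm to that in the nucleus (C/N). The pipeline mirrors common
high-content practice:

1. `correct_illumination()` divides by a heavy Gaussian smooth of the image
   (sigma defaulting to 1/8 of the short image side) and rescales to
   preserve the global median. A flat field passes through unchanged; a
   zero-reaching estimate falls back to the uncorrected image with a
   warning rather than dividing by zero.
2. `segment_nuclei()` applies a global two-class Otsu threshold to the
   nuclear stain, labels connected components with 8-connectivity, and
   drops components outside a [50, 5000] px area gate. The gate bounds are
   stated defaults at the synthetic scale, not inferred biology, and are
   configurable.
3. `extend_cytoplasm()` defines each cell's cytoplasm as the background
   pixels within 10 px (Euclidean) of its nucleus. Pixels within reach of
   two nuclei go to the nearer one; implementing the ring as a per-nucleus
   distance-map argmin makes the disk dilation and the nearest-nucleus
   tie-break one and the same operation, so rings can never overlap.
4. `measure_ktr()` takes per-cell medians and their ratio; cells with a
   zero nuclear median get an undefined ratio and a QC flag.
5. `remove_artifacts()` drops cells with more than 1% saturated pixels
   (top of the declared bit depth), out-of-bounds nuclear area, or
   out-of-bounds ratio. The criteria are declared defaults — artifact
   screens in published pipelines are typically external scripts whose
   rules are not printed — and every removal is counted.

Replicate and condition summaries (`summarize_condition()`) use the median
of per-cell ratios per replicate, then the mean of replicate medians per
condition, optionally normalised to a no-drug reference.

Medians, not means, are used throughout because per-cell intensity
distributions are right-skewed and contaminated by residual segmentation
errors; the C/N ratio of medians is also exactly invariant to any positive
rescaling of the reporter channel, which the tests assert.

## Cell-cycle fractions from DNA content

DNA-content histograms are fit with a three-component mixture: a Gaussian
G0/G1 peak at mean $\mu$, a Gaussian G2/M peak constrained to
$[1.8, 2.2]\,\mu$ (the 2x genome equivalent with instrument slack), and an
S-phase component modelled as a uniform plateau between the peak means
convolved with a Gaussian — a Dean-Jett-Fox-style broadened component with
the convenient closed-form density

$$f_S(x) = \frac{\Phi\!\left(\frac{x-\mu}{\sigma_s}\right) -
  \Phi\!\left(\frac{x-2\mu}{\sigma_s}\right)}{\mu}.$$

No specific histogram-deconvolution model is canonical across instrument
software, so the package declares this one and validates it by recovery on
generated data. Events are median-normalised before fitting, making the
reported fractions exactly invariant to intensity-axis rescaling. Sub-G1
debris below half the initial G1 estimate is gated out and counted.
Initialisation comes from the histogram mode, with a half-mode candidate in
case G2/M dominates; optimisation is bounded L-BFGS with a deterministic
jitter schedule for restarts (no hidden randomness, so a fit is a pure
function of its input). Reported percentages are posterior membership
fractions, which coincide with mixture weights at the optimum and reduce to
exact event counts when peaks are well separated — this is what makes the
degenerate two-atom case come out exact.

`compare_fractions()` reports per-phase shifts in percentage points across
replicate sets with a two-sample t-test at the conventional p < 0.05, and
marks significance unavailable rather than inventing it when either arm has
a single replicate.

## Differential expression, core gene groups and overlap

The DE caller (`call_degs()`) is a deliberately self-contained two-group
negative-binomial Wald test: median-of-ratios size factors, per-gene
method-of-moments dispersion moderated toward the experiment-typical value
(weights residual-df : prior-df, default prior 10, floored at $10^{-4}$),
group means $\hat\mu_g = \sum_j K_{gj} / \sum_j s_j$, and

$$\mathrm{Var}(\log \hat\mu_g) = \frac{1}{\hat\mu_g \sum_j s_j} +
  \alpha\,\frac{\sum_j s_j^2}{(\sum_j s_j)^2}.$$

Because the dispersion is estimated from only a few replicates, the Wald
statistic is referred to a t distribution with residual-plus-prior degrees
of freedom rather than a normal: in triplicate designs the normal reference
proved visibly anticonservative in null simulations (occasional clusters of
spurious discoveries at low counts), and the moderated-t reference removes
them while leaving power at high counts essentially unchanged. With a
user-supplied known dispersion the normal reference is used. Genes with
total count below 10 in the contrasted samples are excluded and counted.
A gene is a DEG when BH-adjusted p < 0.05 and |log2FC| > 1 (fold change
\> 2) — both thresholds are arguments. This caller is *not* a re-creation
of any specific published estimator; the downstream machinery is
caller-agnostic and accepts any table with `gene`, `is_deg`, `direction`
columns, so results from DESeq2 or edgeR can be substituted directly (the
test suite cross-checks the caller's fold changes and calls against DESeq2
on simulated data and finds near-identical results).

The *core gene group* of a drug relative to a modulator
(`core_gene_set()`) is the set of drug-alone DEGs that become
non-differential when the modulator is co-applied, and the *restored
fraction* is their share of all drug DEGs. By construction the core set and
the combined-condition DEG set are disjoint, which is asserted as an
invariant.

Overlap significance (`permutation_overlap_test()`) follows the
random-intersection recipe: each iteration draws sets of the observed sizes
uniformly without replacement from their universes and records the
intersection size; p is the fraction of iterations at or above the observed
overlap, with no +1 correction — a literal reading of the procedure — and
an exact zero annotated as "< 1/n_iter". On a shared universe this null is
hypergeometric, and the tests verify convergence to the closed-form tail.
The default universe is the set of genes passing the expression filter in
the contrast, since that is the population from which DEGs could have been
drawn; using all annotated genes instead would overstate significance.

## Pathway activation levels

Expression is first normalised to case-to-normal ratios (CNR): each gene's
value divided by its geometric mean across all samples in the dataset
(`geometric_mean_normalize()`; genes that are zero everywhere are excluded,
genes with some zeros get a pseudocount added uniformly within the gene so
per-gene scale invariance is preserved). The pathway activation level of a
pathway with activator/repressor role weights $ARR_g \in [-1, 1]$ is

$$PAL = K\,\frac{\sum_g ARR_g \log_{10} CNR_g}{\sum_g |ARR_g|}, \qquad
K = 100,$$

a weighted mean of signed log-ratios. The constant, the log base and the
minimum pathway size (10 genes present) are all configurable; the formula
is adopted from the established pathway-activation scoring family, and
since published PAL values depend on proprietary pathway definitions, the
package ships no database — users supply gene sets as GMT, with an optional
`gene|weight` dialect for roles (plain GMT means all-activator). Group
comparisons use per-sample PALs with a two-sample t-test and BH adjustment
across pathways; the test is declared, not inferred from any external
convention.

## What the synthetic generator does and does not emulate

The generator mirrors the statistical structure of a serum/EGF rescue
study: six conditions (control, serum, EGF, drug, drug+serum, drug+EGF) in
triplicate; negative-binomial counts with a global dispersion of 0.05 and
baseline means log-uniform on [20, 2000]; 100 + 100 planted drug-responsive
genes at |log2FC| = 2; and rescued fractions defaulting to 0.75 under serum
and 1.0 under EGF — the pattern reported for an antibody-type EGFR drug,
where EGF fully reverts the expression signature and serum reverts about
three quarters of it. Reporter fields plant a C/N ratio of 2.5 for active
kinase versus 1.0 under drug; DNA histograms plant 60/25/15 phase fractions
with a 5% CV, shifting to 80/10/10 under drug (a ~20-point G1 arrest).
Dose tables use m = 2, Dm = 300 with 2% multiplicative noise.

Deliberate simplifications, and hence limits on what passing tests show
about real data:

* Rescue is modelled as effective-dose attenuation,
  $D_{\mathrm{eff}} = D(1 - \rho L)$ — monotone and sufficient to produce
  CI > 1, but not a mechanistic claim; in particular the bell-shaped
  dual effect of EGF (growth stimulation at low dose, inhibition at high)
  is not simulated.
* Serum-only and EGF-only arms are generated at baseline expression, so
  they act as negative controls; real single-agent arms have their own
  signatures.
* A single global NB dispersion, not a mean-dispersion trend; the caller's
  moderation would matter more on real data.
* Cells are non-overlapping disks on a jittered grid with at most a linear
  illumination gradient and detector-level saturated blobs; touching
  nuclei, debris and focus drift are out of scope (as is watershed
  splitting in the segmenter).
* Donor-to-donor variability in rescue strength is a scalar, not a
  distribution.

## Numerical choices and degenerate inputs

* Median-effect fitting requires at least 3 usable points strictly inside
  (0, 100)% growth; an all-50% table has undefined slope and errors as
  unfittable. Duplicate doses are averaged before fitting; logs are base
  10 throughout.
* CI at an effect level outside both single-agent ranges warns
  (extrapolation) instead of erroring.
* The cell-cycle fit bounds component CVs away from zero only by machine
  floor, so atomic histograms converge to exact masses; non-convergence
  after the deterministic restart schedule raises an error carrying
  diagnostics.
* Permutation p-values use the plain count, not (count+1)/(n+1); a zero is
  reported with its resolution note.
* All generators accept a `seed` and restore the caller's RNG state, so
  fixed seeds reproduce artifacts bit-identically without side effects on
  the session; derived stage seeds in `run_demo()` are fixed offsets of the
  master seed.

## Problem sizes

The test suite validates recovery at the scales the estimators are meant
for: 8-dose titrations over 50 noise seeds; ten 384x384 fields of 50 cells;
10,000-event histograms over 20 seeds; 2000-gene count matrices in
triplicate for null FDR control, power and rescue-fraction recovery; and
10,000-iteration permutation tests against exact hypergeometric tails on
small universes. `run_demo()` uses reduced sizes (15-cell fields,
4000-event histograms, 1500 genes) chosen to keep the end-to-end
demonstration fast while leaving every recovery unambiguous.
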