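---
title: "Models and methods behind mmrscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mmrscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmrscreen)
```

`mmrscreen` implements a complete desk-scale development loop for automated
mismatch-repair (MMR) immunohistochemistry scoring: a synthetic cohort
generator, a synthetic brightfield image simulator with a classical cell
caller, quality control and case scoring, diagnostic evaluation, and
survival/power analysis. This vignette records the models, the parameters
that matter, and the design decisions, so that every default is traceable.

## 1. The scoring model

For each tissue-microarray core and each protein (MLH1, PMS2, MSH2, MSH6 —
a separate stained section per protein), the core-level signal is the
percentage of **epithelial** cells that are DAB-positive. Stromal cells,
lymphocytes and background objects are excluded from numerator and
denominator: intraepithelial lymphocytes retain MMR expression and are
enriched in MMRd tumours, so leaving them in would systematically inflate
the apparent expression of exactly the cases one wants to catch.

Case-level, per protein, the score is the unweighted mean across passing
cores (tumour-centre and invasive-margin cores pooled; per-core minima and
maxima are also reported). The case statistic is

$$\texttt{mmr\_min} = \min_{p \in \text{informative proteins}} \;
\overline{\%\text{positive epithelial}}_p,$$

the value from the protein with the fewest positive epithelial cells. A low
`mmr_min` indicates loss of at least one protein. Classification is strict:
a case is MMRd iff `mmr_min` < threshold, and the lost proteins are those
whose case-level mean falls below the same threshold (one threshold keeps
per-protein calls consistent with the case call). `mmr_min` is taken over
*informative* proteins only; a case is dropped only when uninformative for
all four.

**QC cascade** (in order): (i) a section with < 100 epithelial cells is
excluded — per core × protein, since each protein is its own section;
(ii) a core whose sections for *all four* proteins have < 20 positive cells
summed over epithelium and stroma is excluded entirely (the "negative in
both compartments" reading of a staining/tissue failure); (iii) cases with
no passing section are excluded. Every rule reports excluded + retained =
input. A deliberate consequence: a *single-protein* staining failure
survives QC and corrupts that protein's mean downward — this is the dominant
mechanism by which automated calls disagree with reviewers, and the rater
simulator is built around it.

## 2. The cohort generator

`generate_cohort()` simulates case → core → section count tables.

**Composition.** MMRd status (prevalence 0.115) and the loss pattern
(default mix: MLH1+PMS2 0.75, MSH2+MSH6 0.10, isolated PMS2 0.06, MSH6
0.06, MLH1 0.02, MSH2 0.01 — a plausible clinical mix, fully configurable)
are assigned by seed-offset golden-ratio (Kronecker) sequences rather than
iid Bernoulli draws. This is a variance-reduction choice: the realised
prevalence and pattern counts match the configured marginals to O(1/n) for
every n, so cohort-level summary statistics (notably the heterodimer
correlations, which lean on a joint-loss cluster of only ~2% of cases) are
stable across seeds instead of swinging with binomial count noise. Each case
additionally owns an RNG substream derived from the master seed by a Lehmer
step, so enlarging `n_cases` never reshuffles earlier cases.

**Expression.** Per case, a latent percent-positive fraction per protein and
compartment comes from a Gaussian copula: heterodimer partners share a pair
latent with correlation `dimer_coupling` (defaults 0.2 for MLH1–PMS2, 0.8
for MSH2–MSH6), and the copula uniform is pushed through a marginal that
depends on loss status:

* retained: mixture of a homogeneous-high component (weight 0.92,
  Beta(110, 3.5), mean ≈ 0.97) and a moderate component (Beta(16, 4),
  mean ≈ 0.80);
* lost: mixture of complete absence (weight 0.8, Beta(0.5, 20)) and partial
  loss (Beta(2, 5), mean ≈ 0.29), the component drawn independently per
  protein — residual missense protein and clonal heterogeneity make true
  partial loss a real phenomenon, and it is what keeps the MLH1–PMS2
  correlation away from its two-point-cluster ceiling.

These mixtures were calibrated once, jointly, against four cohort-level
targets — MLH1–PMS2 Pearson r ≈ 0.88, MSH2–MSH6 r ≈ 0.69, two thirds of
cases ≥ 90% positive for all four proteins, and roughly one case in ten
with < 10% expression of ≥ 1 protein — and then frozen as the defaults.
The composition fixed by prevalence and pattern mix caps the achievable
MLH1–PMS2 correlation near 0.94 (the binary φ of the joint-loss cluster);
the partial-loss spread and sporadic staining failures bring it down to the
0.88 regime, while the MSH2–MSH6 value is carried mostly by the retained
side through its stronger coupling.

Stromal expression is retained regardless of MMR status (Beta(9, 2.5)
marginal), with a shared-factor coupling of 0.75 across proteins targeting
the observed 0.68–0.76 stromal correlation band, and a 0.5 coupling to the
epithelial case factor.

**Counts.** Section totals are negative-binomial (mean 1500, size 10);
composition splits into lymphocytes (case fraction ~Beta around 0.10,
doubled in MMRd), strong/weak background objects (2%/5%), and an
epithelial/stromal split from a per-case Beta(11, 9) fraction. Positive
counts are Beta-binomial around the latent fraction (concentration 150).
Failure modes: per-section staining failure (0.004) and whole-core failure
(0.002) leave < 20 positive cells; epithelium-poor sections (0.02) carry
10–99 epithelial cells. Cores per case follow the configured 4-core (0.76)
/ 8-core (0.24) mix, split evenly between tumour-centre and invasive-margin
regions; 3-core central-only designs are supported for validation-style
cohorts.

**Raters and MSI.** `simulate_raters()` gives two independent reviewers a
misclassification probability of 0.25 on cases containing at least one
failed section and 0.0025 elsewhere — chosen so that, at the default failure
rates, about 90% of rater-versus-truth discordances arise on stain-failed
cases — plus a consensus that resolves discrepancies to truth with
configurable fidelity (default 1). `simulate_msi()` flips MMR truth into
MSI/MSS labels with configurable discordance rates, defaulting to P(MSS |
MMRd) = 0.05 and P(MSI | MMRp) = 0.01.

## 3. The image simulator and classical caller

`render_core()` synthesises brightfield H-DAB images by forward
Beer–Lambert transmission: per-pixel optical densities of haematoxylin and
DAB accumulate from a background wash, elliptical nuclei and artifacts, and
each RGB channel is $I = 255 \cdot 10^{-OD_h h_c - OD_d d_c}$ with the
standard stain vectors $h = (0.65, 0.70, 0.29)$, $d = (0.27, 0.57, 0.78)$.
Morphology encodes class: epithelial nuclei are medium ellipses placed in
glandular clusters, stromal nuclei are thin and elongated (eccentricity
> 0.85), lymphocytes are small dense circles (area below half the
epithelial median). Dart-throwing placement with a grid hash and a minimum
separation of 0.8 × the summed semi-major axes keeps nuclei resolvable;
specs whose summed nucleus area exceeds 55% of the disc are rejected as
unrenderable. Positive nuclei draw DAB OD ~ N(0.65, 0.05); negatives carry
0.02.

`call_cells()` inverts this with classical operations only: colour
deconvolution by the stain-matrix inverse (`OD = -log10(I/255)`), exclusion
of fold bands (contiguous regions with DAB OD > 0.95 and area ≥ 600 px²,
counted as strong background), Gaussian smoothing (σ = 1.2 px) of total OD,
thresholding at 0.3, connected components, and distance-transform watershed
to split touching nuclei. Objects are classified by mean haematoxylin OD
(< 0.2 → background, strong vs weak at mean DAB 0.45), area and
eccentricity (lymphocyte: area ≤ 45 px² and ecc ≤ 0.8; stromal: ecc ≥ 0.88;
else tumour), and DAB positivity at mean nuclear OD ≥ 0.15 — midway between
the rendered negative (~0) and positive (≥ 0.4) modes. All thresholds are
calibrated against the renderer's defaults, not against any scanner or
commercial pipeline, and are exposed in `cell_caller_params()`.

Rendering then deconvolving recovers input densities to within the 8-bit
quantisation bound (0.02 OD), which the test suite asserts; the end-to-end
check renders one core per case and protein, calls cells, scores the
resulting count table and requires `mmr_min` within ±5 points of the
rendered truth for ≥ 95% of cases.

## 4. Diagnostic evaluation

AUROC is the tie-corrected rank (Mann–Whitney) statistic, with the score
negated internally so that low `mmr_min` ranks as "more diseased"; the
bootstrap CI resamples cases (percentile, 1000 draws, seeded). Threshold
calibration scans the observed score values: fixed-sensitivity modes return
the *smallest* qualifying threshold (maximal specificity), Youden mode
maximises sensitivity + specificity with ties broken toward the smaller
threshold. The performance report emits the confusion counts alongside
derived metrics so that the identities F1 = harmonic mean(PPV, sens),
Fowlkes–Mallows = geometric mean(PPV, sens), rule-out = specificity × (1 −
prevalence) and FN fraction = (1 − sens) × prevalence hold exactly on the
emitted counts. `extrapolate_cohort()` adds unreviewed screen-negative
cases to the true-negative cell and recomputes all fractions — the standard
move when a review set is enriched for screen positives.

Agreement uses Cohen's κ (chance from marginal products; undefined and
flagged when expected agreement is 1) and Gwet's AC1 (chance
$\sum_k \pi_k(1-\pi_k)/(K-1)$ with $\pi_k$ the mean marginal), the latter
robust to the skewed prevalence that deflates κ. Pattern-level agreement
uses identity weighting — no partial credit for overlapping protein sets.

## 5. Survival analysis and the interaction power design

The recurrence-free interval runs from randomization to relapse, censoring
at death without relapse or last contact; records with missing or
non-positive times are rejected, never imputed. Kaplan–Meier, log-rank and
Cox machinery delegate to the `survival` package (Efron ties; Wald CIs;
scaled-Schoenfeld trend test per term via `cox.zph`), with constant
covariables dropped with a flag and a warning below 10 events per term.

`trial_design()` fixes the power simulation: 2,000 patients, exponential
event times with administrative censoring at a 72-month horizon, the
baseline hazard solved (by `uniroot`, tolerance 1e-12) so the expected
number of recurrences is 500; MMRd prevalence 0.1; 1:1 allocation of 3- vs
6-month chemotherapy independent of MMR status. The interaction effect is
parameterised as the *ratio* between the MMR-group-specific duration hazard
ratios (the alternative arithmetic-difference reading of "difference in
hazard ratios" has no natural Cox parameterisation). Defaults include an
MMRd main-effect HR of 2.08 — the elevated recurrence hazard of MMRd
tumours under oxaliplatin-based therapy — and a duration main effect of 1,
consistent with duration non-inferiority; both are configurable. Power is
the fraction of ≥ 200 (default 500) replicates whose interaction Wald p
falls below α = 0.05 two-sided, with a binomial CI; failed fits are
counted, excluded only when < 1% of replicates, and an error otherwise.

## 6. Problem sizes and numerical choices

The shipped tests and the acceptance script use: cohorts of 2,000 cases for
calibration checks (≈ 40,000 sections, a few seconds), 500-replicate power
runs, 500 simulated trials of n = 2,000 for Cox bias/coverage, and 20-case
image cohorts (80 rendered cores at 320 px) for the end-to-end check —
sizes chosen so the whole loop stays comfortably interactive on one CPU.
Other numerical conventions: percentages carried at full precision (0–100
scale) and rounded only for display; strict `<` at every classification
boundary; pixel coordinates are 1-based (x, y) in R's matrix convention;
RGB is clamped to [0, 255] and OD computed from `max(I, 1)` to avoid
log-of-zero; mixture quantiles are tabulated on an 8,193-point grid and
inverted by interpolation (error < 1e-4).

## 7. What the synthetic data do and do not establish

The generator reproduces the *statistical shape* of a trial cohort —
hierarchy, marginals, heterodimer coupling, failure modes, lymphocyte
enrichment — but not antibody chemistry, staining-batch effects, scanner
optics, or inter-observer ambiguity on genuinely borderline morphology. The
rendered cores are cleaner than scanned tissue: nuclei are ellipses, stains
mix linearly, and no out-of-focus or edge artifacts exist beyond the fold
and blob models. Consequently the pipeline separates MMRd from MMRp more
cleanly than any real-slide system should be expected to (worked examples
can reach AUROC ≈ 1.0), and passing tests demonstrate correctness of the
*machinery* — QC arithmetic, score definitions, threshold logic, metric
identities, statistical calibration — not clinical-grade performance. The
trained-classifier stand-in is deliberately classical; nothing here learns
from data, and its thresholds are tied to the renderer's defaults.
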