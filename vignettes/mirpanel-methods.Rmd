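---
title: "Methods: from raw Ct values to a validated miRNA panel"
author: "mirpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw Ct values to a validated miRNA panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirpanel)
library(dplyr)
```

`mirpanel` implements a complete circulating-miRNA biomarker discovery
workflow for case-control serum studies profiled by RT-qPCR: absolute
quantification against per-assay standard curves, endogenous reference
selection and normalization, differential screening across discovery and
validation cohorts, multi-marker logistic panel optimization by sequential
forward floating search (SFFS) inside repeated two-fold cross-validation, and
evaluation of the frozen panel on a held-out cohort. Because studies of this
kind rarely deposit raw data, the package ships a synthetic-cohort generator
that emulates the data structure the workflow assumes; every stage is tested
against it.

## The measurement model

qPCR reports a threshold cycle `Ct`; for each assay a 6-log dilution series
of synthetic template (1e7 down to 1e2 copies) defines a linear standard
curve

$$Ct = a \log_{10}(\text{copies}) + b, \qquad a < 0 ,$$

whose slope encodes the amplification efficiency $E = 10^{-1/a} - 1$
($E = 1$ is perfect doubling, $a \approx -3.32$). Quantification inverts the
assay's own curve, which is also what operationally corrects for per-assay
efficiency differences; no second correction is applied.

The generator and the quantifier share one volume bookkeeping, fixed to the
protocol the workflow targets: 0.2 ml serum enters RNA isolation, the RNA is
eluted in 25 µl, and 2 µl enter each RT reaction, so

$$\text{reacted copies} = \text{copies/ml} \times 0.2\,\text{ml} \times
\phi_i \times \tfrac{2}{25},$$

where $\phi_i$ is sample $i$'s RNA-isolation efficiency. Three spike-in
controls of known input (high/medium/low; defaults 2e5/2e4/2e3 copies) pass
through isolation with the sample; the per-sample recovery is the geometric
mean of their measured/expected ratios, and dividing by it undoes $\phi_i$
exactly in the noise-free limit. The 14-cycle pre-amplification shared by
samples and standards shifts both identically, so it is folded into the
curve intercept rather than modelled separately — the correction cancels by
construction.

Numerical conventions, chosen where the protocol is silent and fixed
throughout:

* technical duplicates are averaged on the **Ct scale** (the instrument's
  near-Gaussian scale), not the copy scale; discordant duplicates
  (spread > 2 cycles) are reported but still averaged;
* a cell undetected in all duplicates is **floored** at the bottom standard
  level (scaled to copies/ml like any measurement) and flagged, keeping the
  matrix complete for clustering and regression;
* values outside the fitted dilution range are flagged
  `extrapolated_low/high` but still computed from the line;
* samples whose spike-ins all fail are excluded outright.

## What the generator emulates

`sim_config()` defaults reproduce the study design the workflow targets: 324
assayed miRNAs; a discovery cohort of 183 cancer / 106 non-cancer samples
from one source; two validation cohorts (177/197 and 180/199) spread over
five further sources; tumour stages 0–IV plus unknown for cases. True
log2 abundance is

$$\ell_{im} = b_m + \beta_{s(i),m} + \mathbb{1}[\text{case}]\,\Delta_m\,
\kappa_{stage} + u_i + \varepsilon_{im},$$

with per-miRNA baselines $b_m \sim N(18, 1.5^2)$ (log2 copies/ml — a
log-normal abundance assumption, since serum abundance distributions are not
published), per-source batch shifts (SD 0.3), planted effects $\Delta_m$ for
30 differential miRNAs (defaults: 8 strong at $\pm1.2$, 22 moderate at
$\pm0.6$, half up- half down-regulated), a per-sample RNA-content shift
$u_i$ (SD 0.25), and subject noise (SD 0.8; 0.15 for the three planted
reference miRNAs). Two generator choices deserve comment:

* the planted references get a *smaller* subject SD — a usable endogenous
  reference is by definition a miRNA whose abundance varies little between
  subjects, and with equal SDs no stability method could (or should) find
  them;
* the per-sample shift $u_i$ applies to endogenous miRNAs but **not** to
  spike-ins, which are added at fixed copy number during isolation. Spike-in
  recovery therefore cannot remove it; endogenous reference normalization
  can. This is exactly the division of labour between the two normalizations
  in the real workflow.

Stage labels are annotations by default (`stage_effect` = 1 everywhere); a
stage-graded effect multiplier supports stratified-performance checks. What
the generator does *not* emulate: primer cross-reactivity between multiplex
RT pools, carrier-RNA effects, heavy-tailed or correlated miRNA co-expression
structure, hemolysis artefacts. Passing tests therefore demonstrate the
*pipeline's* correctness and power under a clean factorial model, not
performance on real sera.

All randomness derives from one master seed through fixed Lehmer substreams
per stage (cohort, assay, CV iteration), so changing assay noise never
perturbs the cohort draw and every run is bitwise reproducible.

## Reference stability and normalization

Stability is computed on log2 copies/ml over all discovery samples (cases
and controls pooled), restricting candidates to miRNAs detected (non-floored)
in at least 90% of samples. Two measures are implemented from their
definitions:

* **geNORM** $M_j$: mean over partners $k$ of the SD across samples of
  $\log_2(x_j/x_k)$, with iterative exclusion of the highest-$M$ candidate
  (ties broken by excluding the lexicographically last id) down to a final
  pair sharing rank 1; pairwise variations $V_{n,n+1}$ are reported.
* **NormFinder-style** $\rho_g$: after centring each sample across
  candidates, $\rho_g = \mathrm{mean}_i(|d_{gi}| + \sqrt{w_{gi}/n_i})$ from
  the group means and within-group variances. This is a simplified estimator
  of the original model-based decomposition (no small-sample bias
  refinements); it preserves the stability ranking, which is all the
  workflow uses.

The final reference set (default $k = 3$) is the consensus: smallest sum of
the two ranks, ties lexicographic. Normalization divides every value in a
sample by the geometric mean of the sample's reference values; it is exactly
invariant to per-sample multiplicative distortion.

## Differential screening

Per miRNA on log2 normalized values: fold change (cancer minus control),
two-sided pooled-variance Student's t-test (Welch available as an option),
Benjamini–Hochberg q-values across all assayed miRNAs, and the Mann–Whitney
AUC (ties count ½). Discovery selection keeps markers with raw p < 0.01,
|log2FC| > 0.5 (both strict), and *directional* AUC > 0.5 — the AUC oriented
by the fold-change sign, so the filter removes markers whose rank separation
contradicts their fold change. Selection on raw p-values with q-values
reported alongside (`use_q` switches) reflects an ambiguity in the workflow
being reproduced; both thresholds are exposed. Validation confirmation uses
the relaxed cut-off p < 0.05, |log2FC| > 0.5, and sign agreement with
discovery. Hierarchical clustering of the candidates (Euclidean distance,
average linkage, per-miRNA zero-mean log2 values) and the cross-cohort
Pearson correlation of fold changes complete the screen.

## Panel search and cross-validation

The panel model is logistic regression on log2 normalized expression, fit by
Newton's method with a small ridge penalty ($\lambda = 10^{-6}$ on
standardized features, intercept unpenalized). The ridge matters: strong
panels produce separable training folds, where the unpenalized MLE diverges;
$\lambda = 10^{-6}$ bounds the coefficients while changing well-conditioned
fits by less than the convergence tolerance (verified against `glm`).

SFFS searches marker subsets with the training AUC of the refit model as its
criterion (no inner CV — the honest test surface is the held-out fold):
forward steps add the best candidate; floating steps remove a member whenever
the reduced subset beats the best-known subset of its size. Three
implementation choices strengthen the classic loop, all recorded here
because the search design was genuinely open:

* every evaluated subset updates the best-of-size table, and a plain greedy
  pass is merged at the end, so SFFS best-of-size **dominates greedy forward
  at every size by construction** (a hard invariant in the test suite);
* the search overshoots the target size by 3 and backtracks — floating
  removals from the overshoot region routinely improve the reported sizes;
* after the main loop, the same conditional inclusion/exclusion rules are
  swept over every recorded best subset until a fixpoint, letting late
  improvements propagate across sizes.

On random pools of ≤10 features the search attains the exhaustive size-3
optimum in ~94% of instances and always dominates greedy; a
suppressor-variable construction (jointly informative pair, individually
null — the linear-model analogue of an XOR trap) confirms that floating
escapes greedy's local optimum.

Cross-validation repeats, 200 times by default: partition the combined
discovery + validation-1 samples into two equal groups stratified by source
and class (per-cell and per-source counts differ by at most one; odd-cell
extras alternate so the groups stay equal); run SFFS on group A; refit each
best-of-size panel on A and score it on B; swap roles. Two records per size
per iteration. The optimal size is the smallest $s$ whose test-AUC increase
to $s+1$ is not significant (two-sided t-test, $\alpha = 0.001$, records
treated as independent — their dependence through shared data is knowingly
ignored, matching the procedure being reproduced; a significant *decrease*
also stops the climb). Among the distinct panels of that size seen in CV,
each is refit on discovery and scored on both training cohorts; the panel
with the best mean of the two AUCs (ties lexicographic) is refit on
discovery + validation 1 as the final model. The aggregation by mean is a
recorded choice — the procedure being reproduced states a bivariate
criterion without an aggregation rule.

## Held-out evaluation

Validation 2 is never touched before this stage; `run_pipeline()` enforces
that with a cohort-isolation guard (attempting to feed held-out samples to
the panel stage is an error, not a warning). The frozen model yields a risk
score $\sigma(\beta_0 + \sum_m \beta_m \log_2 x_m)$ per sample. Reported:
ROC and trapezoid AUC (identical to the Mann–Whitney statistic — a hard
invariant), a DeLong 95% CI (bootstrap fallback when the DeLong variance
degenerates; both methods tagged in the output), the maximum-accuracy cutoff
(thresholds at midpoints of adjacent distinct scores; rule score ≥ cutoff ⇒
cancer; accuracy ties resolve toward higher specificity, then the higher
cutoff), Wilson 95% CIs for accuracy/sensitivity/specificity, per-source AUC
(each source's cases vs its own controls), and per-stage AUC (each stage's
cases vs **all** cohort controls, matching the pre-malignant-vs-healthy
framing) with early (0–II) / late (III–IV) composites. DeLong and Wilson are
choices, not inheritances — the reproduced procedure does not state its CI
methods.

## Problem sizes used in the tests

The shipped tests run the full pipeline at reduced scale, chosen to exercise
every code path with comfortable statistical margins: cohorts of 30–150
cases/controls per phase, 30–100 miRNAs, 3–50 CV iterations, 20 master seeds
for the planted-panel recovery study (8 strong markers at |log2FC| = 1.0
among 30 differential, 150/150 per cohort analog, sizes 2–10). The
acceptance script (`scripts/acceptance.R`) runs the full default
configuration: 324 miRNAs, the three-cohort multi-centre design (289 + 374 +
379 samples), 200 CV iterations, sizes 2–12.

## Known limitations

* The NormFinder estimator is the simplified form described above.
* The t-test in the plateau rule inherits the record-dependence
  approximation; its α should be read as a ranking device, not a calibrated
  error rate.
* The generator's independent-marker model makes panel AUC accrue like
  $\sqrt{s}$; real miRNA co-expression would slow that accrual, so planted
  plateau positions are optimistic relative to real panels.
* Undetected-Ct handling (flooring) and the stability candidate filter are
  conventions chosen here; alternatives (dropping cells, BestKeeper-style
  stability) are out of scope.

## A minimal run

```{r example, eval = FALSE}
cfg <- pipeline_config(
  simulate = sim_config(
    n_mirnas = 60, n_differential = 12, n_reference = 3,
    cohorts = small_cohort_design(
      40, 40, c("discovery", "validation1", "validation2")),
    seed = 11),
  n_iter = 20, sizes = 2:6, seed = 11)
res <- run_pipeline(cfg, "mirpanel-demo")
res$references
res$optimal$size
res$evaluation
plot_cv_auc(res$cv)
autoplot(res$evaluation)
```
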