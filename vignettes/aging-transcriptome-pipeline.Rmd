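---
title: "Methods: screening, syntropy, rescue and deconvolution in aging transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, syntropy, rescue and deconvolution in aging transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agingscreen)
```

## Overview

`agingscreen` implements an integrated analysis of transcriptome aging in
multi-tissue bulk expression cohorts, of the kind built on GTEx-style
tissue panels and GEO case/control or intervention series. The pipeline
has six analysis stages — age-correlation screening, tissue-signature
clustering, group intersection and cross-cohort validation, syntropic
deregulation in disease, rescue under anti-aging interventions, and bulk
cell-type deconvolution — plus a hypergeometric over-representation step
and a synthetic-data module that plants known effects so that every stage
can be scored against ground truth.

## The aging-gene screen

For each gene $g$ in a tissue, expression (log2 scale) is correlated with
donor age by the sample Pearson coefficient $r_g$, and significance is
assessed with the exact $t$ transform

$$t = r\sqrt{\frac{n-2}{1-r^2}} \sim t_{n-2},$$

two-sided. Calls are direction-specific and asymmetric:

* **up** aging genes: $r > 0$ and $p < \alpha_\mathrm{up}$ (default 0.05);
* **down** aging genes: $r < 0$ and $p < \alpha_\mathrm{down}$ (default
  0.01).

The stricter down threshold reflects the screening convention for brain
cohorts, in which declining genes vastly outnumber rising ones and a
stringent criterion keeps the down list specific. Because the p-value is
two-sided and the sign is constrained, the null call rate of each
direction is half its nominal $\alpha$: 0.5% down and 2.5% up. The test
suite asserts this calibration on 10,000 null genes.

Thresholds are on raw p-values by design — this mirrors the screening
convention the pipeline reproduces; a Benjamini–Hochberg switch
(`adjust = "BH"`) is available but off by default. Donor ages are
restricted to a window, default 40–69 years, exposed as `age_window`.
With `log_age = TRUE` the age covariate is log-transformed before
correlation, the convention used when validating against log-scaled
microarray cohorts. Genes constant within a tissue, or with fewer than
10 unmasked samples, are skipped with a logged reason — never silently
assigned $r = 0$.

**Why the t transform and not permutation?** The t-based p is exact under
bivariate normality and costs one vectorised pass over 10–20k genes; a
20,000-draw permutation per gene would be four orders of magnitude
slower. The permutation test is retained in the test suite as an
independent oracle. One caveat worth recording: for very small samples
(n ≈ 8) the permutation null of $r$ conditioned on the observed values
retains $O(1/n)$ moment corrections driven by sample skewness and
kurtosis, so permutation and t p-values can differ by up to ~0.05 even
with unlimited permutation draws; the two nulls coincide to Monte-Carlo
precision by n ≈ 30, which is where the suite's agreement check runs.

## Tissue signatures, grouping and intersection

A tissue's *aging signature* is its vector of per-gene $r$-values.
Signatures are aligned on the genes common to all tissues (at least 100
required), correlated pairwise, and clustered by average-linkage
hierarchical clustering on the distance $1 - r$. Average linkage on a
correlation-derived distance is the default behaviour of the standard
clustered-heatmap tools used in this field, and is stated explicitly here
so the grouping is deterministic. The tree is cut at a user-chosen $k$
(default 4 groups), or a fixed grouping file can be supplied so that
downstream stages do not depend on clustering reproducibility.

*Group aging genes* of a direction are the intersection of the per-tissue
called sets across a group's member tissues; Venn region counts are
reported for every subset of members. Cross-cohort validation retains a
gene when it is called in at least `k_min` discovery tissues (convention:
3 for up genes, 6 for down genes — both plain parameters here) and shows
a same-direction significant correlation in at least one validation
cohort screened with `log_age = TRUE`.

## Syntropy and rescue

Disease cohorts are age-matched case/control designs, so a contrast
between arms is net of aging. The contrast is Welch's unequal-variance
t on log2 values, computed genewise from group means and variances, with
log2 fold change defined as case minus control mean. This is a
deliberately transparent stand-in for count-model DE machinery
(edgeR/DESeq dispersion models are out of scope); consequently absolute
gene lists from real count data will differ from those tools, and the
package's accuracy claims rest on recovery of planted effects in matched
simulations, which the acceptance suite measures.

* **Syntropic deregulation**: an aging gene moved *further in its aging
  direction* in the disease contrast — same-signed log2FC with
  $p < \alpha$ (default 0.05). The reported proportion is
  `n_syntropic / n_aging_detected`, where the denominator contains only
  aging genes detectable in the disease dataset.
* **Rescue**: an aging gene moved *opposite to its aging direction* under
  an intervention contrast (high vs low physical activity), with
  $|log2FC| > \log_2(\texttt{fold\_min})$ and $p < \alpha$. `fold_min`
  defaults to 1.0 (any significant reversal) for bulk contrasts and 1.1
  by convention for cell-resolved contrasts. Aging genes absent from the
  intervention dataset are excluded from the denominator.

Physical-activity arms use actigraphy cut-offs of $1 \times 10^5$ and
$2.1 \times 10^5$ counts/day: high is strictly above $2.1 \times 10^5$,
moderate is the half-open interval $(1, 2.1] \times 10^5$ (a boundary
value is moderate), low is everything else. Control-mean normalization
(`normalize_to_control_mean`) re-expresses each stratum relative to its
own control arm — divide on the raw scale, subtract on the log2 scale —
so multi-area cohorts are comparable.

## Cell-type deconvolution

Cell fractions are estimated by non-negative least squares against a
signature matrix built from labeled single-cell profiles: for each type,
the `markers_per_type` (default 50) genes with the largest positive
difference between the type's mean log2 expression and the maximum mean
among other types are selected, and signature entries are per-type means.
Per bulk sample the solver minimises $\|Sf - b\|_2$ subject to
$f \ge 0$ on the linear scale, then renormalises $f$ to the simplex,
which also makes the estimate invariant to positive rescaling of the
bulk profile. NNLS is a transparent, testable choice for the digital
cytometry task: it recovers noise-free mixtures exactly and, in the
package's recovery experiments, 6-type mixtures with 10% multiplicative
noise to a mean L1 error near 0.01. No claim is made of numerical
equivalence to ν-SVR-based digital cytometry tools, whose internals
(including batch-correction modes) are not public; fidelity is to the
task, not the tool. Fraction comparisons between groups (age split at 60
years by default, or activity arms) use Welch's t per cell type.

## Over-representation

Gene-set enrichment of screened/syntropic/rescued sets is an upper-tail
hypergeometric test per set, $p = P[X \ge k]$ for
$X \sim \mathrm{Hypergeom}(N, K, n)$, with BH adjustment across sets.
The universe defaults to the genes detectable in the expression data
that produced the query — conditioning on detectability rather than the
genome — and collections are supplied as GMT files; no annotation
snapshots are bundled, avoiding database-version dependence.

## The synthetic-data module

The generator is the package's study design, not a tuning knob. Defaults:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 2000 | genes per cohort |
| `n_samples_per_tissue` | 150 | donors per tissue |
| `tissues` | 12 in 4 groups of 3 | brain-like tissue panel |
| `age_range` | 40–69 yr | uniform donor ages |
| `frac_down`, `frac_up` | 0.10, 0.05 | planted effect fractions |
| `slope_down`, `slope_up` | ∓0.05 log2/yr | linear-in-age effects |
| `noise_sd` | 1.0 log2 | residual spread |
| baseline | N(5, 2²) log2 | per-gene expression level |

Age effects are linear on the log2 scale because the screen is a Pearson
correlation — a linear-in-age signal is the matched generative model.
With these values a planted gene's population correlation is
$r = a/\sqrt{a^2+\sigma^2}$ with $a = \mathrm{slope}\cdot\mathrm{sd(age)}
\approx 0.42$, i.e. $|r| \approx 0.39$ — a moderate, realistic effect
that the screen detects with sensitivity above 0.9 at $p < 0.01$.
Tissues in the same group share a direction map drawn independently per
group; group membership is therefore encoded in the signatures, and
cutting the signature tree at the planted number of groups recovers the
partition exactly at moderate noise.

Disease cohorts add a case-arm shift (default 1.0 log2 units, 50 samples
per arm) to a stated fraction (default 40%) of a group's aging genes,
signed like their aging direction; intervention cohorts add a positive
offset to a stated fraction of down genes in the high-activity arm only.
Both draw one age vector and share it across arms — the cleanest
realisation of an age-matched design. Intervention activity values are
drawn uniformly within each arm's actigraphy interval so arm sizes are
exact. Mixtures are fraction-weighted sums of signature profiles with
multiplicative log-normal noise of stated CV and mean exactly one, so
zero CV reproduces the exact matrix product.

What the generator does **not** emulate: GTEx-like marginal expression
distributions, library-size and batch artifacts, count overdispersion,
correlated gene modules, or nonlinear age trajectories. Passing recovery
tests therefore demonstrate correctness of the estimators under the
matched generative model, not robustness to real-data pathologies.

## Numerical and degenerate-input choices

* p-values are clamped to $(\texttt{xmin}, 1]$ so perfect correlations
  never yield $p = 0$.
* Raw-scale matrices are moved to $\log_2(x+1)$; the fixed pseudocount
  makes the transform total.
* Missing values are explicit `NA` masks; `NaN`/`Inf` are rejected at
  construction. A gene needs ≥ 10 unmasked samples per tissue.
* Genes with zero variance in both arms of a contrast are flagged with
  an undefined p, not dropped silently.
* Simulations run in an isolated RNG stream seeded per call; pipeline
  stages derive distinct sub-seeds from the master seed, and identical
  configurations reproduce byte-identical outputs and manifest.

## Problem sizes

The test and acceptance workloads use the standard conditions above
(2000 genes × 150 donors for single-tissue experiments; 10,000 genes for
null calibration; 10 replicate disease/intervention cohorts of 50 per
arm for the syntropy/rescue recovery experiments; 50 six-type mixtures
for deconvolution), which the maintainers consider large enough for the
binomial error of each recovered proportion to sit well inside its
stated tolerance.

## Limitations

* The two-group contrast is Welch's t on log2 values; count-level
  dispersion modelling is explicitly out of scope.
* Identifier matching is exact string match after upper-casing; no alias
  resolution.
* The deconvolution stage estimates fractions only; cell-type-specific
  expression imputation is not implemented.
* Enrichment requires a user-supplied GMT collection and has no bundled
  annotation databases.
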