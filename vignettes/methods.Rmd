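---
title: "Methods: age-association scans, consensus co-expression modules, and methylation mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age-association scans, consensus co-expression modules, and methylation mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`agingtx` implements the computational chain of an aging-transcriptomics
analysis on purified blood cells: covariate-adjusted linear scans of age
against expression and DNA-methylation matrices, weighted co-expression
network module discovery hardened by a subsampling consensus procedure,
decomposition of age effects on expression into methylation-mediated and
direct paths, per-sample contamination scoring, and gene-set
overrepresentation. This vignette explains each model, its assumptions,
the tunable parameters, and the design decisions taken where the
procedure was genuinely open.

## The association model

For each feature $y_g$ (a gene's log2 expression or a CpG's M-value), the
scan fits ordinary least squares

$$y_g = \beta_{0g} + \beta_g\,\mathrm{age} + \gamma_g^\top \mathbf{z} + \varepsilon_g,$$

where $\mathbf{z}$ collects the nuisance covariates — sex, race, study
site, chip, and the per-sample contamination scores — one-hot encoded
against the lexicographically first level so the encoding is
deterministic. The reported partial correlation is the Pearson
correlation of the residuals of $y_g$ and of age after projecting both
on the covariates; it collapses to the plain correlation when the
covariate set is empty. Zero-variance features produce `NA` rows and are
excluded from multiple-testing adjustment.

Multiple testing uses Storey q-values. The null proportion
$\hat\pi_0 = \#\{p > \lambda\}/(m(1-\lambda))$ is estimated at a fixed
$\lambda = 0.5$ (a spline smoother over a $\lambda$ grid is available via
`smoother = TRUE`); the fixed-$\lambda$ default is deliberately simple
because the smoother is unstable at the scan sizes used in validation
(hundreds to a few thousand features). The estimate is clamped to
$[1/m, 1]$; with $\hat\pi_0 = 1$ the q-values equal Benjamini–Hochberg
adjusted p-values exactly, which the test suite asserts.

Pulse pressure is derived as the averaged second and third systolic
readings minus the averaged second and third diastolic readings, in
mmHg; the first reading is discarded by definition. `phenotype_scan()`
reverses the regression direction — expression predicting pulse
pressure, adjusted for age — so that pulse-pressure associations are not
mere age proxies.

Cis CpG–gene pairing uses a 1 Mb window, boundary inclusive, around the
gene's transcription start (annotation `start` on the + strand, `end` on
the −). The anchor choice is a documented convention: a distance rule
"within 1 Mb" does not by itself say whether the anchor is the probe,
the TSS, or the gene body, and the TSS is the common regulatory-distance
convention.

## Network construction and module detection

Co-expression is measured by the biweight midcorrelation with the
standard tuning constant of 9 MADs: values beyond 9 MADs from the median
get zero weight, which makes the correlation robust to the occasional
outlier sample without discarding it globally. A column whose MAD is
zero falls back to the Pearson correlation with a warning.

The unsigned adjacency is $a_{ij} = |\mathrm{cor}_{ij}|^\beta$. The soft
power $\beta$ is chosen from a 1–20 grid as the smallest power whose
degree distribution is approximately scale-free: connectivities are
binned on the linear scale, and $\log_{10} p(k)$ is regressed on
$\log_{10} k$; a power qualifies when $R^2 \ge 0.8$ with negative slope
*and* mean connectivity at least 1. The connectivity floor matters:
unstructured data can reach high apparent scale-free fits at powers
where the network is essentially empty (mean $k \sim 10^{-4}$), and the
floor routes such inputs to the warning path instead. When no power
qualifies — which is the expected outcome for cohorts dominated by a few
large, equally coherent modules, whose degree distribution rises with
$k$ rather than decaying — the conventional unsigned-network default of
$\beta = 6$ is used with a warning. We chose this fallback over the
best-fitting power because on block-structured data the best raw
$R^2$ often sits at $\beta = 1$, which barely separates modules from
background.

Interconnectedness is the unsigned topological overlap
$\mathrm{TOM}_{ij} = (\ell_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})$
with $\ell_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}$; the implementation is
verified against a brute-force triple-loop oracle to $10^{-10}$.

Modules come from average-linkage hierarchical clustering of
$1 - \mathrm{TOM}$ with a deterministic two-part cut:

1. **Static quantile cut with recursive sub-splitting.** The tree is cut
   at the 0.99 quantile of its merge heights; every branch large enough
   to host two modules is re-cut against its own height distribution,
   and a sub-split is accepted only when it yields at least two clusters
   of `min_size` (default 10, matching the study's lowered minimum).
   This approximates a dynamic cut while remaining exactly reproducible.
2. **Cohesion cleanup.** A member whose mean TOM similarity to the rest
   of its module is below half the module's median member similarity is
   moved to unassigned, iterating to stability. Without this pass,
   10–20 weakly correlated background genes per module are absorbed on
   planted-block benchmarks (recovery ARI ≈ 0.85); with it, recovery is
   ARI ≥ 0.96 and clean two-block designs are recovered exactly.

Modules are renumbered by decreasing size, colored from the conventional
palette (turquoise, blue, brown, ...), and label 0 is reserved for
unassigned genes. The module eigengene is the first right-singular
vector of the standardized within-module expression matrix, sign-aligned
with the module's average standardized expression; variance explained is
the first squared singular value over the total.

## Consensus stability

Module assignments from hierarchical clustering are famously unstable
under resampling, so the package implements the subsampling consensus
procedure: draw 80% of samples without replacement, rerun the *entire*
network pipeline (including soft-power re-selection; a frozen-power mode
is available through the `power` argument), and repeat 200 times. Each
partition becomes a co-membership network — an edge joins two genes
assigned to the same module — and the Jaccard index (shared edges over
union; two empty networks count as identical) measures agreement. The
consensus network keeps edges present in at least
$\lceil 0.70 \times 200 \rceil$ replicates, boundary inclusive, and
consensus modules are its connected components with no minimum size
(isolated genes stay unassigned). Components were chosen over
re-clustering because the consensus edge set is already the object the
threshold defines; the extraction rule is documented here since it is
otherwise open.

On the reference synthetic cohort (five 80-gene modules at within-module
correlation 0.7, 300 samples) individual replicate networks agree with
the full-data network at Jaccard ≈ 0.99 — planted structure this strong
is far cleaner than real cohort data, where that agreement is known to
be dramatically lower — while two consensus networks built from
independent subsample sets agree at Jaccard ≈ 1.0, preserving the
qualitative ordering (consensus stability exceeds single-replicate
stability) that motivates the procedure.

## Mediation decomposition

For a CpG–gene pair the package fits the two linear regressions

$$M = \alpha_0 + a\,\mathrm{age} + \alpha^\top \mathbf{z} + e_1, \qquad
  E = \beta_0 + b\,M + c'\,\mathrm{age} + \beta^\top \mathbf{z} + e_2,$$

giving indirect effect $ab$, direct effect $c'$, and total $c' + ab$.
For a single continuous mediator with Gaussian errors these point
estimates coincide with the maximum-likelihood structural-equation
decomposition, so no SEM machinery is required; the package verifies the
algebraic consequences on every fit — the decomposition identity
`total = direct + indirect` to $10^{-10}$, and collapsibility: the total
equals the age coefficient of the reduced model without the mediator.

Inference for the indirect effect uses nonparametric case-resampling
bootstrap: the SE is the bootstrap standard deviation and the two-sided
p-value is the percentile-of-zero rule
$p = \min(1,\, 2\min(\Pr(ab^* \le 0), \Pr(ab^* \ge 0)))$. Resamples with
a constant mediator or outcome are skipped and counted. Coefficients are
reported on the input scales (age in years) — the identity checks used
in validation are scale-free, so no standardization is imposed.

`mediation_scan()` expects its CpG–gene pairs pre-filtered (in the
pipeline: CpGs associated with age and with cis expression at
FDR ≤ 0.001) and flags per gene the pair with the smallest indirect
p-value, breaking ties by first occurrence.

One caution inherited from the scientific setting: a significant
indirect path is consistent with mediation but cannot rule out reverse
causation (expression affecting methylation) or unmeasured confounding
of the mediator–outcome relation.

## Contamination scoring

Cell-type signatures are genes at least four-fold (2 log2 units,
boundary inclusive) more expressed in the target type than the *maximum*
over all other types — the strictest reading of "other cell
populations" — and above a configurable expression floor in the target
type. The floor parameter deserves a note: the motivating description of
the extra filter reads as if it required *low* expression in the
targeted cells, which we take to be a transcription slip (it would
contradict the four-fold rule); it is implemented as a floor on
target-cell expression and documented rather than silently guessed away.

Each sample's score is the classic unweighted running-sum statistic over
its expression ranking: walk from most- to least-expressed, step up
$1/|S|$ at signature genes and down $1/(N - |S|)$ otherwise, and take
the signed maximum deviation. The unweighted form was chosen because the
per-sample ranking has no phenotype to weight by, and rank-only scores
are invariant under any strictly monotone transform of one sample's
values — an invariance the tests assert. Ties in expression are broken
lexicographically by gene id so reruns are bit-identical.

## The synthetic cohort generator

`generate_cohort()` plants every signal the analyses are meant to
detect, with the ground truth recorded machine-readably:

* **Ages** uniform on 55–94 years.
* **Modules** via one latent factor per module: gene $=$ baseline
  $+ \sigma(\sqrt{\rho} f + \sqrt{1-\rho}\,\epsilon)$, so the pairwise
  within-module correlation targets $\rho$ (`within_module_cor`). The
  factor itself carries a module-level age loading
  ($f = \gamma\,\mathrm{age}_{std} + \sqrt{1-\gamma^2}\,u$, default
  $|\gamma| = 0.3$ with alternating signs), so module eigengenes
  associate with age in both directions while the within-module
  correlation stays at target.
* **Direct age effects** on a fraction (default 25%, mirroring the
  share of age-associated genes in the motivating cohort) of background
  genes, with per-decade shifts capped at `max_effect_per_decade`
  (default 10%) of the gene's baseline; the per-gene effect-size
  distribution below the cap is uniform, a config choice since only the
  cap is externally constrained.
* **Mediation triples**: $M = a\,\mathrm{age} + e_1$ on the M-value
  scale and $E \mathrel{+}= b\,M + c'\,\mathrm{age}$, so the marginal
  age slope is exactly $ab + c'$. Methylation is generated on the
  M-value scale and stored as beta-values through the exact
  inverse-logit, making `beta_to_m()` lossless. Each mediating CpG sits
  50 kb from its gene on the synthetic genome — one chromosome with
  genes and CpGs on uniform grids — so the 1 Mb cis rule is exercised
  and testable.
* **Contamination**: per-sample fractions uniform on
  `contamination_range` (default 0–0.2) shift that type's signature
  genes by `contamination_amplitude` (default 5 log2 units per unit
  fraction, the shift a few-fold-enriched admixture of that magnitude
  would produce).
* **Nuisance covariates** sex/race/site/chip/position as independent
  categoricals with fixed marginals and small additive shifts
  (`covariate_effects = FALSE` disables them for exact-recovery tests);
  three blood-pressure readings per participant feed the pulse-pressure
  derivation.

What the generator does *not* emulate: raw bead-level intensities and
their background correction, Infinium I/II chemistry differences,
batch artifacts beyond categorical shifts, linkage between covariates
(confounded designs require explicit configuration), and the heavy-tailed
hub-and-periphery correlation structure of real transcriptomes — module
loadings are exchangeable within a module. Passing tests therefore
demonstrate correctness of the estimators under the generating model,
not robustness to every pathology of array data.

Validation problem sizes were chosen so the full suite runs comfortably
on a single core: the reference cohort is 500 genes × 300 samples with
five 80-gene modules; the consensus benchmark uses two independent runs
of 200 subsamples each; calibration suites use 200–1,000 simulated
fits. These are stated as the package's validation conditions — the
estimators themselves have no scale assumptions beyond ordinary OLS
requirements.

## Numerical and degenerate-input conventions

* Beta-values are clamped to $[\varepsilon, 1-\varepsilon]$
  ($\varepsilon = 10^{-6}$) before the logit, keeping degenerate
  simulated betas finite.
* Quantile normalization resolves ties by averaging the target
  quantiles over tied ranks; a single-sample matrix is returned
  unchanged with a warning.
* The expression variance filter runs *after* the detection and
  annotation filters, so its 10th percentile reflects the analyzable
  probe set; the other filters are order-insensitive.
* Detection thresholds are strict inequalities on the p-value and
  boundary-inclusive on the fraction: a CpG detected in exactly 90% of
  samples is retained.
* `fit_linear_association` on a noiseless response reports SE 0 and
  p-value 0; rank-deficient designs error with the collinear columns
  named rather than silently dropping them.
* All randomness flows from explicit integer seeds; replicate sub-seeds
  are drawn once from the master seed and logged in results, so any
  replicate can be reproduced in isolation.

## Known limitations

* The tree cut is a documented approximation of dynamic branch cutting;
  on data with nested or very unequal modules its agreement with other
  implementations is structural (planted-truth recovery), not
  label-for-label.
* $\hat\pi_0$ at fixed $\lambda$ is biased upward under strong
  widespread signal (conservative q-values).
* The mediation model is single-mediator and linear; multiple mediators,
  exposure–mediator interaction, and sensitivity analysis for unmeasured
  confounding are out of scope.
* The enrichment module's FDR is Benjamini–Hochberg across the supplied
  collection; it does not propagate the GO graph or reproduce any
  web-service-internal FDR.
* Model selection (e.g. stepwise covariate selection) is deliberately
  not implemented: the covariate set is fixed by the caller.
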