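---
title: "Normalization of urinary metabolomics data: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalization of urinary metabolomics data: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urinorm)
```

## The dilution problem

A spot-urine sample is an uncontrolled dilution of the kidney's output:
every metabolite concentration in sample $i$ is the physiological signal
$c_{ij}$ multiplied by one shared factor $d_i$ reflecting water volume,

$$x_{ij} = c_{ij} \, d_i .$$

$d_i$ varies by person, hydration and time of day, and is not observed.
Every normalization scheme in this package is an estimator $s_i$ of
$d_i$ (up to an irrelevant global constant), applied as $x_{ij}/s_i$:

* **ABS** — $s_i = 1$. Keeps the original concentrations; meaningful for
  timed collections, heavily confounded for spot urine.
* **IS** — $s_i = x_{i,\mathrm{ref}}$ for one reference metabolite.
  Creatinine is the customary choice (near-constant production, freely
  filtered, not reabsorbed); glucose, urea and pseudouridine are
  alternative references with different physiological assumptions. The
  reference column is removed from the output: after division it is
  identically 1 and carries no information, which is also why its
  correlations are left blank in the heat-map displays.
* **CS** — $s_i = \sum_j x_{ij}$. Simple, but urinary abundances are
  Pareto-like: urea (and to a lesser degree creatinine) dominates the sum,
  so CS in practice behaves like normalization to the dominant compounds.
* **PQN** — reference profile $r_j$ = cohort median of the constant-sum
  scaled metabolite; quotients $q_{ij} = x_{ij}/r_j$; $s_i$ = median over
  $j$ of $q_{ij}$. The median over the panel makes the estimator robust to
  biology that moves only a minority of metabolites.
* **DESEQ2** — identical to PQN except that $r_j$ is the geometric mean of
  the absolute concentrations across samples (the median-of-ratios size
  factors used for RNA-seq libraries), and no constant-sum pre-scaling is
  applied.

Scale factors are always reported on the scale of the input table so that
`values = table / scale_factors` holds exactly for every scheme; for PQN
with constant-sum pre-scaling the reported $s_i$ is therefore the row sum
times the median quotient.

## The downstream protocol

**Correlation structure.** Metabolite–metabolite association is measured
by Spearman correlation adjusted for sex, computed as the Pearson
correlation of rank residuals: both variables are rank-transformed
(average ranks on ties), residualized on an intercept plus covariates by
least squares, and correlated. With no covariates this is exactly the
classical Spearman $\rho$. The matrix of one reference scheme
(conventionally IS-CREA) is ordered by agglomerative clustering on the
distance $1-\rho$, and all other schemes are re-displayed in that fixed
order, with creatinine appended as the last row where present.

**Regression protocol.** Per metabolite and scheme: truncate extreme
values to $Q_3 + 8\,\mathrm{IQR}$ (capping, not removal, so ranks are
preserved), take natural logs, and standardize. Outcomes (BMI in kg/m²,
mean arterial pressure MAP $= (\mathrm{SBP} + 2\,\mathrm{DBP})/3$ in mmHg)
are standardized as well, so the reported coefficient is SD of outcome per
SD of log-metabolite — comparable across metabolites, outcomes and
schemes. Models are fit with and without sex adjustment by ordinary least
squares.

**Multiple testing.** The panel is strongly correlated, so a raw
Bonferroni correction over all metabolites is conservative. The effective
number of independent tests $m_\mathrm{eff}$ is the smallest number of
principal components of the log-standardized concentration correlation
matrix whose cumulative eigenvalue share exceeds 99%; the family-wise
threshold is $\alpha/m_\mathrm{eff}$, printed at two significant digits
(0.05/39 prints as 0.0013). An association is called *robust* when its
p-value falls below this threshold.

**Concordance.** Scheme agreement is quantified four ways: pairwise mean
R² between the two normalized versions of each shared metabolite
(28 comparisons for 8 data versions); Pearson correlation of the
lower-triangle entries of two correlation matrices; the fraction of
reference-robust association cells whose beta sign matches the reference
scheme; and, on synthetic data, the correlation of $\log s_i$ with the
true $\log d_i$.

## What the synthetic cohort emulates

The generator produces the structure these analyses assume, with stored
ground truth:

* **Abundances.** 44 metabolites with log-normal concentrations; default
  log-means span ~4.7 orders of magnitude with urea (~230 mmol/L) and
  creatinine (~11 mmol/L) dominant, so the constant-sum denominator is
  realistically dominated by a few compounds.
* **Correlation.** Eight thematic clusters (amino acids, hippurates,
  diet/carbohydrate, microbial metabolites, ...) with a single shared
  factor per cluster giving equicorrelation `within_cluster_corr`
  (default 0.5) between members on the log scale.
* **Variance components.** Biological log-SD 0.5 per metabolite
  (pseudouridine 0.25 as the most tightly regulated reference candidate,
  glucose 0.55), uncorrelated measurement noise log-SD 0.1, and dilution
  log-SD 0.7 — roughly a half order of magnitude of spot-urine dilution
  spread, chosen as a realistic free parameter since it cannot be derived
  from published summaries.
* **Sex.** Log-scale shifts (creatinine +0.35 as a muscle-mass proxy,
  3-methylhistidine +0.2, citrate −0.3) plus additive sex effects on the
  outcomes, so sex is a genuine confounder for the adjustment machinery.
* **Outcomes.** BMI and blood pressure are affine transforms of
  $Z\beta + \text{sex} + \varepsilon$, where $Z$ is the standardized
  biological signal. Planted effects touch 11 of 44 metabolites
  (|β| 0.1–0.25), fewer than half the panel, which is the regime in which
  the quotient estimators' median step is expected to stay unbiased. SBP
  and DBP are reconstructed from the latent MAP and a positive pulse
  pressure, so the MAP identity holds exactly. Because clusters correlate
  metabolites, the marginal SD-unit association of each metabolite differs
  from its planted coefficient; the truth object stores both
  (`true_effects` and `marginal_effects`, the latter computed analytically
  as the noise-attenuated $R\beta$ scaled by the outcome SD given sex).
* **Pathology toggle.** `glucose_tail = TRUE` adds a heavy right-tail
  mixture to log-glucose (15% of samples shifted by N(1.5, 0.5)),
  emulating saturation of tubular glucose reabsorption; it exists to show
  how a noisy reference degrades IS-GLUC while leaving PQN untouched.

One global seed drives everything through deterministically derived
per-component sub-streams, so a cohort is bit-reproducible and partially
reconfigurable without scrambling unrelated draws.

What the generator does **not** emulate: quantification error correlated
with spectral overlap, detection limits and censoring (all values are
strictly positive by construction), kidney-function covariates, batch or
storage effects, and non-log-normal shapes beyond the glucose mixture.
Passing tests on this cohort therefore demonstrate that the estimators
behave as designed under the stated model — not that any scheme is
unbiased on real urine, where the assumptions (few-metabolite biology,
shared pure dilution) can fail in structured ways.

## Numerical choices

* Quartiles for the truncation cap use linear interpolation (R's default
  type 7), making the worked example `[1, 2, 3, 4, 100]` cap at
  $4 + 8 \times 2 = 20$. The median of an even count is the mean of the
  two central values everywhere.
* Strict positivity is enforced at load; there is no zero imputation.
  Degenerate inputs fail loudly: empty tables, nonpositive cells,
  duplicate metabolite or sample names, zero-variance metabolites in the
  PCA, rank-deficient regression designs (reported with the offending
  column), and fewer than four observations for quartiles or
  correlations.
* A single self-referenced sample under PQN without pre-scaling returns
  $s_1 = 1$ (its quotients against itself are all 1).
* PQN and the geometric-mean variant accept an optional fixed
  `reference_profile`, the standard way to normalize new samples against
  a training cohort. This is also the semantics under which single-sample
  dilution invariance is exact: with the reference held fixed, scaling one
  sample's row by $c$ scales its quotient scale factor by exactly $c$ and
  leaves every normalized value unchanged. When the reference is
  recomputed from the perturbed table, a geometric-mean reference absorbs
  $c^{1/n}$ and the invariance is only approximate; CS, IS and PQN with
  constant-sum pre-scaling are exactly invariant either way.
* Hierarchical clustering defaults to average linkage on $1-\rho$ with
  `hclust`'s deterministic agglomeration order; the 8-cluster cut is a
  display convention, not an inferential claim, and linkage, distance and
  cut count are all configurable.
* Correlation matrices are clamped to $[-1, 1]$ after residualization to
  absorb floating-point overshoot; undefined entries (zero residual
  variance) propagate as missing and block clustering until dropped.

## Open design decisions

Several points are underdetermined by common practice; the package picks a
default and exposes the alternative:

* **PQN reference scale.** "Median relative concentrations" can mean
  medians of constant-sum scaled values or of raw concentrations. The
  default pre-scales (`pqn_pre_cs = TRUE`), matching the original PQN
  recipe; the raw variant is one flag away. The two differ only in the
  reference weighting, and their quotient scale factors agree up to a
  per-sample constant-sum factor.
* **Reference subsets.** Creatinine and the other IS candidates stay
  inside the CS/PQN/DESEQ2 reference subset by default (the full panel is
  used); `metabolite_subset` restricts it.
* **PCA input.** $m_\mathrm{eff}$ is computed on the log-standardized
  absolute concentrations by default — the version available before any
  normalization choice — and any table can be passed instead.
* **Outcome transforms.** Outcomes are standardized but not log
  transformed; BMI and MAP are near-symmetric at population scale.
* **Mean R² scale.** Cross-scheme metabolite correlations are computed on
  the log scale (flag available), stabilizing the heavy-tailed
  concentration distributions and matching the regression transform.
* **Concordance denominator.** Sign concordance is restricted to cells
  robust under the reference scheme, since direction consistency is only
  meaningful for associations that pass the threshold there.

## Problem sizes

The shipped tests and the acceptance script run entirely on generated
data: cohorts of 30–600 samples for structural checks, n = 500 for the
protocol-level summaries (dilution recovery, concordance, robust counts),
n = 1000 × 200 replicates for planted-effect recovery, n = 5000 for the
cluster-correlation convergence check, and 200 random 10×8 (invariance)
and 5×5 (loop-oracle) matrices for the normalization algebra. These sizes
were chosen to put Monte-Carlo error well below the asserted margins while
keeping a full run fast on a laptop.

## Known limitations

Compositional interdependence is inherent to CS/PQN/DESEQ2: normalized
concentrations must trade off against each other, so correlated
confounding across many metabolites produces normalization artifacts that
no amount of data removes. IS schemes inherit the biology of their
reference (muscle mass for creatinine, glycemia and kidney function for
glucose). The package quantifies the consequences of these choices; it
does not adjudicate which scheme is "correct" for a given physiology, and
its simulations should be read as controlled thought experiments, not as a
substitute for validation against collection-matched measurements such as
24-hour excretion or osmolality.
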