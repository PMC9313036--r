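# urinorm

Normalization strategies for quantitative urinary metabolomics in
epidemiological analyses.

## The problem

Spot-urine metabolite concentrations are confounded by urine water volume:
every metabolite in a sample is multiplied by the same unknown dilution
factor *d<sub>i</sub>*, which varies greatly between people and days. Before
a urinary metabolite panel can be regressed against clinical outcomes, each
sample must be rescaled by an estimated scale factor *s<sub>i</sub>*. Several
conventions coexist and they do not agree; this package implements the
common ones side by side, together with the downstream epidemiological
protocol needed to compare them, for researchers analysing quantitative
(e.g. NMR-based) urinary metabolomics panels.

Implemented data versions (all return *x<sub>ij</sub>* / *s<sub>i</sub>*
plus the scale factors themselves):

| Scheme | Scale factor *s<sub>i</sub>* |
|---|---|
| ABS | 1 (absolute concentrations, the baseline) |
| IS-CREA / IS-GLUC / IS-UREA / IS-PSEURID | concentration of one internal reference metabolite (creatinine, glucose, urea, pseudouridine); the reference column is dropped from the output |
| CS | constant sum: Σ<sub>j</sub> *x<sub>ij</sub>* |
| PQN | probabilistic quotient: median over metabolites of *x<sub>ij</sub>* / *r<sub>j</sub>*, with *r<sub>j</sub>* the cohort median of the constant-sum scaled metabolite |
| DESEQ2 | as PQN with a geometric-mean reference profile (the median-of-ratios size factors familiar from RNA-seq) |

On top of these sit the analysis stages: sex-adjusted Spearman
metabolite–metabolite correlation matrices ordered by two-dimensional
hierarchical clustering of a reference scheme; extreme-value truncation at
Q3 + 8×IQR, log transformation and SD-unit linear regression of each
metabolite against each outcome (BMI, mean arterial pressure); a PCA-based
effective number of independent tests *m*<sub>eff</sub> feeding the
Bonferroni threshold α/*m*<sub>eff</sub>; and cross-scheme concordance
summaries (pairwise mean R², correlation-structure similarity, association
sign concordance, dilution-factor recovery). A synthetic cohort generator
with known dilution factors and planted SD-unit effects validates the whole
chain end to end.

## Worked example

```r
library(urinorm)

cohort <- generate_cohort(generator_config(n_samples = 500, seed = 1))
cohort$table
#> metabolite_table: 500 samples x 44 metabolites
#> range: 0.0006379 - 2772

tables <- lapply(standard_schemes(), function(sp) apply_scheme(cohort$table, sp))
tables$PQN
#> normalized_table [PQN]: 500 samples x 44 metabolites
#> scale factors:   27.33 - 2762.72

## how well do the quotient scale factors recover the true dilution?
round(dilution_recovery(tables$PQN, cohort$truth), 3)
#> [1] 0.976

m_eff <- effective_tests(cohort$table)
th <- bonferroni_threshold(0.05, m_eff)
th
#> scan_threshold: p < 0.0012 (alpha 0.05 over 40 effective tests)

recs <- association_scan(tables, as.matrix(cohort$covariates[, c("BMI", "MAP")]),
                         sex = cohort$covariates$sex, adjust = TRUE,
                         threshold = th)
subset(recs, metabolite == "lactate" & outcome == "BMI")[
  , c("scheme", "beta", "se", "p_value", "robust")]
#>         scheme      beta         se      p_value robust
#> 14         ABS 0.2092065 0.04341273 1.919545e-06   TRUE
#> 101    IS-CREA 0.2297412 0.04499432 4.695467e-07   TRUE
#> 187    IS-GLUC 0.2937092 0.04241806 1.361114e-11   TRUE
#> 273    IS-UREA 0.2481750 0.04298913 1.373061e-08   TRUE
#> 359 IS-PSEURID 0.2418589 0.04307476 3.276356e-08   TRUE
#> 446         CS 0.2518590 0.04294753 8.231678e-09   TRUE
#> 534        PQN 0.2826860 0.04255857 8.122617e-11   TRUE
#> 622     DESEQ2 0.2809180 0.04258260 1.076202e-10   TRUE

round(sign_concordance(recs, "IS-CREA"), 3)
#>        ABS    IS-CREA    IS-GLUC    IS-UREA IS-PSEURID         CS        PQN     DESEQ2
#>        0.9        1.0        1.0        1.0        1.0        1.0        1.0        1.0
```

The lactate–BMI association (a planted positive effect) is recovered with
the same direction under every data version, with betas between 0.21 and
0.29 SD of BMI per SD of log-lactate — the strength varies by scheme, the
interpretation does not. The PQN scale factors correlate 0.976 with the
true log dilution factors of the simulated cohort.

`run_pipeline(run_config(out_dir = "out", generator = list(n_samples = 500)))`
drives all stages at once and writes every table plus a JSON manifest;
configurations can also be read from YAML via `read_run_config()`.

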