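# persistsig

Chronic myeloid leukaemia (CML) stem cells survive tyrosine kinase inhibitor
(TKI) therapy, and the part of their expression programme that TKIs leave
untouched is a hunting ground for curative co-targets. `persistsig` is an R
package plus analysis workflow for discovering that **TKI-independent gene
expression signature**: genes differentially expressed between CML and
healthy stem cells in two independent datasets, whose expression is
demonstrably *unchanged* after TKI treatment by an equivalence test.

It is aimed at computational biologists who want a tested, reproducible
implementation of the full procedure — and a synthetic benchmark with known
per-gene truth to validate it against — without downloading or reprocessing
the original array cohorts.

## The method in brief

- **Moderated differential expression.** Per-gene two-group or paired linear
  fits; gene variances shrunk toward an empirical-Bayes scaled inverse
  chi-square prior estimated by method-of-moments (trigamma inversion):
  `s2_post = (d0*s0² + df*s2)/(d0 + df)`, moderated t on `d0 + df` degrees
  of freedom, Benjamini–Hochberg q-values (DE ⇔ `q < 0.1`), 95% CIs.
- **Equivalence margin from technical replicates.** Pool both signed log2
  differences of every replicate pair; the 2.5/97.5 percentiles, rounded to
  the nearest 0.1 (halves away from zero), define the "no change" margin —
  raw percentiles near ±0.486/0.487 become **±0.5**.
- **Non-change call.** A gene is non-changing iff its 95% CI crosses zero
  *and* is contained within the margin (CI-containment equivalence test).
- **Signature.** Intersect the two DE sets (upper-tail hypergeometric
  overlap p), correlate fold-changes across datasets (Pearson), then label
  each consistent DE gene: non-changing → **TKI-independent**; opposite
  treatment direction → **rescued**; otherwise → **enhanced**.
- **qPCR validation.** ΔCt against the mean of reference genes, paired
  ΔΔCt per patient, non-changing iff the median ΔΔCt lies strictly inside
  (−0.5, 0.5).

A synthetic-data module generates both cohort datasets (shared, attenuated
disease effects; technical triplicates), the paired treatment dataset and Ct
tables, with per-gene ground truth for every stage. See
`vignettes/tki-independent-signature.Rmd` for the model and its assumptions.

## Worked example

The numbered drivers under `analysis/` run the whole study on synthetic
data (`PERSISTSIG_SEED` selects the seed, default 1):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_differential_expression.R
Rscript analysis/03_margin_equivalence.R
Rscript analysis/04_signature.R
Rscript analysis/05_qpcr.R
```

which prints, stage by stage:

```
simulated 10000 genes (seed 1): 2000 truth-DE
DE at q < 0.1 — A: 2161, B: 1730; treatment contrast: 1840
pooled 720000 replicate differences (SD 0.254)
raw percentiles: [-0.4978, 0.4978] -> margin [-0.5, 0.5]
7239 of 10000 genes non-changing after treatment
de_intersection: 2161/10000 and 1730/10000 DE (q < 0.1), overlap 1605
cross-dataset fold-change correlation: r = 0.615 (p = 0, n = 10000)
signature_classification: 1605 genes — 1201 rescued (74.8%), 188 enhanced, 216 TKI-independent
macro-averaged accuracy: 0.960
paired analysis: 2 of 26 genes non-changing (|median ddCt| < 0.5)
```

Reading this: of the 1605 genes consistently DE in both simulated cohorts,
74.8% are rescued by treatment, and 216 form the TKI-independent signature;
scored against the simulated truth the three labels are recovered with
macro-averaged accuracy 0.96. The same computation is available as one call:

```r
library(persistsig)
res <- run_pipeline(pipeline_config(simulation = simulation_config(seed = 1)),
                    outdir = "results/run")
res$classification
```

All intermediate tables are TSV, and margins/overlaps/manifests are JSON, so
every output round-trips through the package readers.

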