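# cfrnascreen

Presymptomatic screening analysis of first-trimester plasma cell-free
RNA (cfRNA). Maternal plasma cfRNA is a mixture of maternal transcripts
and a small placental component (roughly 5–10% of uniquely assigned
reads in weeks 9–14); this package implements, as tested R functions
plus a set of analysis drivers, the chain of methods needed to ask
whether that placental signal carries presymptomatic information about
pregnancy disorders:

* **QC filtering** — genes with fewer than 120 reads in more than 90% of
  samples are removed; samples are excluded below 1 million uniquely
  assigned reads, at or below 100,000 fetal reads, or below 750 detected
  genes.
* **Fetal RNA fraction** — per sample,
  `100 × mean(RPKM placental genes) / mean(RPKM reference genes)`, with
  reference genes selected by mean/ratio/CV exclusion criteria and
  placental genes taken from the pregnancy differential-expression
  analysis (strongly upregulated, near-absent in non-pregnant plasma).
* **Confounder correction** — a stable-gene panel (cross-correlation
  < 0.5 with maternal age, library size, gestational age, fetal
  fraction, purification batch) feeds a control-gene factor correction
  that protects the pregnant/non-pregnant contrast.
* **Differential expression** — per-gene one-way ANOVA across 2, 3 or 4
  groups on corrected log2 CPM, Benjamini–Hochberg FDR, tiered marker
  lists, and the XIST-style fetal-sex contrast.
* **PSO-enhanced clustering** — a particle swarm tunes the single FDR
  threshold that selects genes for hierarchical clustering, maximising
  the dendrogram's group-separation score (adjusted Rand index of the
  tree cut).
* **Add-one-in (reverse LOOCV)** — each affected sample is added singly
  to the reference cohort, the whole correction/DGE/clustering pipeline
  is rerun, and the sample qualifies only if pregnant/non-pregnant
  separation stays intact, the group test stays most significant, and
  the candidate forms a discrete, statistically supported dendrogram
  arm; qualified samples are pooled into subgroups for the multi-group
  comparison.
* **qPCR validation** — delta-Ct relative quantification (2^−ΔCt), the
  NRIP1/ZEB2 ratio, the linear/circular NRIP1 ratio that discriminates
  pre-eclampsia-like from trisomy-21-like profiles, and Fisher-exact
  pregnancy-specificity testing of a marker assay.

A negative-binomial synthetic cohort generator with complete ground
truth (true fetal fractions, gene classes, confounder effects, designed
perturbations) underpins the test suite: every stage is checked by
parameter recovery against the generator, by brute-force oracles, or by
hand-computed examples. See the methods vignette
(`vignettes/cfrna-screening-methods.Rmd`) for the models, the parameter
choices and their rationale.

## Worked example

The `analysis/` directory holds the numbered drivers
(`01_simulate_cohort.R` … `05_qpcr_validation.R`); run them in order
from the repository root. They simulate a 131-sample cohort (108 normal
pregnancies, 19 non-pregnant controls, 4 affected samples carrying two
designed 30-gene |log2FC| = 2 perturbations), then run the full
analysis, writing tables under `results/`. Condensed output:

```
$ Rscript analysis/02_qc_and_fetal_fraction.R
gene filter: 2000 in, 1966 kept, 34 removed (1.7%)
fetal fraction: 131 samples, median 8.01% (23 placental / 153 reference genes)
median fetal fraction: 8.42% (pregnant), 0.39% (non-pregnant)
sample filter: 131 in, 131 kept, 0 removed (0%)

$ Rscript analysis/03_correction_and_dge.R
stable panel: 1679 genes (max association < 0.50)
corrected matrix: 1966 genes x 127 samples, k = 2 unwanted factor(s)
41 pregnancy markers at FDR < 0.05 (23 with logFC > 2, 15 with logFC > 1)
fetal-sex marker: logFC 2.21 (female vs male), FDR 1e-61

$ Rscript analysis/04_cluster_and_add_one_in.R
PSO-selected FDR threshold 0.0745 -> 68 genes, separation score 1.000
add-one-in: 4 candidates, 4 qualified
pooled comparison: 119 genes at FDR < 0.05 across 4 groups
```

Reading these numbers: the estimated fetal fractions recover the
simulated truth (true pregnant median 7.82%, estimated 8.42%;
non-pregnant background designed at 0.38%, estimated 0.39%); the factor
correction finds exactly the two injected technical factors
(purification batch and gestational age); the marker tiers match the
designed 25 placenta-exclusive plus 15 medium markers; clustering
separates pregnant from non-pregnant samples perfectly; and all four
affected samples qualify and land in their designed subgroups, with the
pooled 4-group table recovering the perturbed genes. The qPCR driver
(`05`) prints the group medians — NRIP1/ZEB2 ratio near 2 in both the
pre-eclampsia-like and trisomy-21-like groups, linear/circular NRIP1
near 2 only in the pre-eclampsia-like group — with the corresponding
Mann–Whitney and Fisher tests.

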