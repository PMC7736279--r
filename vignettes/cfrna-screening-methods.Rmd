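---
title: "Methods: presymptomatic screening analysis of plasma cell-free RNA"
author: "cfrnascreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presymptomatic screening analysis of plasma cell-free RNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Maternal plasma carries a mixture of cell-free RNA (cfRNA): mostly
transcripts of maternal (hematopoietic, hepatic, endothelial) origin, plus
a placental component that grows with gestation. In the first trimester
the placental share is small — of the order of 5–10% of uniquely assigned
reads — and the question this package addresses is whether that small
placental signal, read out by bulk RNA sequencing of plasma between weeks
9 and 14, contains presymptomatic information about pregnancy disorders
such as pre-eclampsia, growth restriction and preterm birth.

`cfrnascreen` implements the full analysis chain as reusable, tested
functions: QC filtering of the gene-level fragment counts, estimation of
the per-sample fetal (placental) RNA fraction, removal of technical and
biological confounding while protecting the biological contrast of
interest, multi-group differential expression, particle-swarm-optimised
hierarchical clustering, an "add-one-in" (reverse leave-one-out)
classification of candidate affected pregnancies, and delta-Ct analysis
of the qPCR validation markers (the NRIP1/ZEB2 ratio and the
linear-versus-circular NRIP1 ratio). A synthetic cohort generator with
complete ground truth makes every stage testable by parameter recovery.

# The synthetic cohort generator

Because each downstream method needs an oracle, the generator is
first-class code, not a test fixture. Its model:

* **Mixture.** For pregnant sample $s$ with true fetal fraction $f_s$,
  the relative expression density of gene $g$ is
  $x_{gs} = m_g c_{gs} + f_s\, p_g$, where $m$ is the maternal baseline
  (log-normal across genes), $p$ the placental signature (non-zero only
  on the placenta-exclusive genes) and $c_{gs}$ collects multiplicative
  confounder and biological-noise terms. Non-pregnant controls receive
  the same mixture at a residual background fraction (default 0.38%),
  representing the low-level placenta-like signal measured in
  non-pregnant plasma. Counts are negative binomial,
  $\mathrm{NB}(\mu = L_s x_{gs}/\sum_g x_{gs},\ \phi)$ with target
  library size $L_s \sim U(2\times10^6, 6\times10^6)$ fragments and
  shared dispersion $\phi = 0.03$; dispersion 0 gives Poisson counts for
  noiseless-limit checks.

* **Calibration of the placental signature.** The signature is scaled so
  that the mean RPKM density of the placental genes equals that of the
  designed reference panel,
  $\overline{p_g/L_g}\big|_P = \overline{m_g/L_g}\big|_R$. Under the
  additive mixture this makes the RPKM-ratio estimator (below) unbiased:
  the estimate equals $100 f_s$ in expectation, so recovery error
  measures estimator noise, not an arbitrary scale mismatch.

* **Biological variability.** Genes outside the housekeeping-like
  reference panel carry per-sample log-normal variability
  ($\sigma = 0.35$ on the natural-log scale, mean-corrected). The
  reference-panel genes carry only the NB noise. This is what gives the
  CV-based reference-gene criteria something real to select on: stable
  low-CV housekeeping genes against more variable maternal genes. The
  placenta-exclusive genes get a smaller residual $\sigma = 0.10$; their
  dominant variation is the shared fetal-fraction signal itself, which is
  the biological premise of fraction estimation from an averaged gene
  panel. The 0.35/0.10 split also makes single-sample four-fold
  expression changes detectable against the reference cohort, which is
  the regime the add-one-in analysis presumes.

* **Confounders.** Gestational age acts multiplicatively on 15% of
  maternal genes and purification batch (two levels) on 30%, with
  per-gene log2 effects drawn from $N(0, 0.5)$ per standardised covariate
  unit; maternal age acts on 5% of genes with the much smaller scale
  $N(0, 0.15)$. The asymmetry is deliberate: first-trimester gestational
  dynamics and extraction batch effects are large, whereas maternal-age
  effects on the plasma transcriptome are subtle — and, importantly,
  maternal age differs systematically between the pregnant and
  non-pregnant arms, so a large age effect would be statistically
  indistinguishable from a pregnancy effect (it is collinear with the
  protected contrast and no control-gene correction can remove it).
  Library-size effects are handled by CPM normalisation; the fetal
  fraction is itself a biological confounder carried by the placental
  genes. The ground truth labels a gene "confounder-driven" when its
  population-level association with a confounder (computable in closed
  form from the injected slope and the gene's noise variance) is at
  least 0.65 — clearly above the 0.5 screening threshold, so that label
  recovery is not dominated by genes sitting exactly at the boundary.

* **Designed markers.** The placenta-exclusive genes (default 25) are the
  strong pregnancy markers (observed logFC about 4); a configurable set
  of well-expressed maternal genes (default 15) is upregulated in
  pregnancy with designed log2 effects in [1.3, 1.7], emulating
  maternal-response markers in the 1–2 tier. One chrX gene mimics XIST:
  upregulated in female-fetus pregnancies proportionally to the fetal
  fraction, with a designed female-vs-male log2 fold change of 2.3 at
  the midpoint fraction. chrY genes are present but kept at zero counts
  (below detection in plasma at this gestation). Affected samples carry
  user-designed perturbations (gene set, log2 effect, subgroup label);
  affected samples with no perturbation are null draws from the normal
  model, used for false-positive control.

What the generator does **not** emulate: isoform structure (counts are
gene-level only), sequence-level artefacts (adapter, mapping,
contamination), count correlation between genes beyond the shared
confounder factors, gestational-age dependence of the fetal fraction
(fractions are drawn i.i.d. from $U(5, 11)$%), and the long-tailed
cellular heterogeneity of real plasma. Passing parameter-recovery tests
therefore demonstrates that the algorithms are implemented correctly and
are well-calibrated under the stated noise model — not that the
biological findings would replicate in a new clinical cohort.

# QC filtering

Gene-level: a gene is removed iff it has fewer than 120 reads in strictly
more than 90% of samples. Sample-level: a pregnant sample is excluded iff
its uniquely assigned reads are below 1 million, its fetal reads (fetal
fraction × unique reads) are 100,000 *or less*, or it detects fewer than
750 genes (count > 0). The wording is implemented literally: strict `>`
for the 90% proportion, `<=` for the fetal-read bound. Non-pregnant
samples are exempt from the fetal-read rule. The 750-gene rule is applied
per sample (with the cohort median logged in the report); whether the
original platform applied it to the per-sample or cohort median is not
determinable from its description, and the per-sample reading is the one
that makes it an exclusion rule at all.

Merged-exon gene lengths are computed from the GTF as the total length of
the union of all annotated exon intervals of the gene (1-based inclusive
coordinates, interval reduction via `GenomicRanges`), which is the
standard gene-level length for RPKM.

# Fetal RNA fraction

Per sample, `fraction = 100 × mean(RPKM of placental genes) /
mean(RPKM of reference genes)`, with
`RPKM = count × 10^9 / (merged exon length × uniquely assigned reads)`.

**Reference genes** are selected on raw RPKM by exclusion: mean below 1
in every group, pregnant/non-pregnant mean ratio outside [0.8, 1.2], or
average coefficient of variation above 0.3. Two details are
underdetermined by the criteria as usually stated and are fixed here as
documented choices: the mean-threshold applies per group ("below 1 in
all samples" read as: in every group), and the CV is computed within
each group and then averaged, so that the pregnancy shift itself does
not masquerade as variability. Criteria are evaluated on raw, not log,
RPKM.

**Placental genes** are the significantly pregnancy-enriched genes
(BH-FDR < 0.05, upregulated) with two additional pipeline-level
restrictions: logFC above 2 (the strongly upregulated tier) and a
control-group abundance ceiling (mean log2(CPM+1) ≤ 6, about 60 CPM in
non-pregnant plasma). Both follow from the estimator's premise — the
numerator must count *added placental material*. Moderately upregulated
genes are typically maternal pregnancy-response genes (their plasma
signal does not scale with the placental contribution), and a gene well
expressed in non-pregnant plasma has a maternal baseline that enters the
numerator as an offset rather than a slope; either contamination
destroys both the scale and the ranking of the estimates, which is
observable directly in the generator's parameter-recovery tests.
Fractions above 100% are arithmetically possible and flagged rather than
clamped.

# Confounder correction

Five covariates are screened: maternal age, library size, gestational
age, fetal fraction, purification batch. The **stable-gene panel** is
every gene whose maximum association with these confounders is below 0.5
— |Pearson r| for numeric covariates, the correlation ratio
$\eta = \sqrt{SS_{between}/SS_{total}}$ for categorical ones (this class
of methods usually leaves the categorical case open; $\eta$ is the
natural analogue of |r|). Associations are computed on complete cases, which matters for
gestational age (undefined for non-pregnant controls).

**Removal of unwanted variation** is control-gene factor analysis in the
RUVg spirit, written against this package's own containers: counts are
transformed to log2(CPM+1); the stable-gene submatrix is centred within
the protected groups per gene (so the group contrast cannot be absorbed
into a factor); its leading right singular vectors are candidate
unwanted factors. The acceptance rule examines the first `k_max = 5`
candidates (one per stated confounder) and keeps exactly those that
associate with at least one confounder at or above the same 0.5
threshold; factors carrying no confounder signal stay in the data. This
subset rule, rather than a leading-prefix rule, is used because a real
unwanted factor can rank below an unstructured biological-noise
direction in singular value. Accepted factors are regressed out of every
gene jointly with the protected group means. With no accepted factor the
input is returned unchanged, which also gives idempotence: a second pass
estimates k = 0.

# Differential expression

Per-gene one-way ANOVA across the sample groups on corrected
log-expression, vectorised over genes; BH adjustment across all tested
genes per contrast. "n-way ANOVA" terminology in this literature is read
as a one-way ANOVA with n groups. The log2 fold change is the difference
of the two named groups' means on the log2(CPM+1) scale (a group-mean
definition, not a GLM coefficient — the underlying platform does not
document which it reports, and group means are the definition the ANOVA
itself uses). Genes with no variance at all get F = 0, p = 1. Singleton
groups are refused by default and permitted (`min_group_size = 1`) only
in the add-one-in stage, where a single added sample legitimately forms
its own group and contributes between-group variation only.

Markers are tiered at logFC > 2 and > 1 and flagged "specific" when
their non-pregnant detection rate (fraction of control samples with a
nonzero count) is below 10%, else "enriched". The XIST-style contrast is
a 3-group ANOVA (female fetus, male fetus, non-pregnant) after
regressing fetal fraction and gestational age out of each gene jointly
with the three group means; both covariates must be removed because the
sex signal rides on the placental component.

One compositional caveat is worth stating: because CPM are relative, the
placental contribution compresses the maternal share of a pregnant
library by roughly the fetal fraction, so genuinely stable genes show a
small negative shift in the pregnant group. This is a property of
relative abundance data, not an artefact of the implementation; tests
that audit false-positive rates therefore score upregulated calls.

# PSO-optimised clustering

Samples are clustered on the Z-scored expression of the genes passing an
FDR threshold — Pearson-correlation distance (1 − r) with complete
linkage by default, the convention of this analysis platform's heatmaps —
and the tree is cut at k = number of groups. The separation score is the
adjusted Rand index between cut and labels, truncated at zero, so 1 is
exactly "the dendrogram arms coincide with the groups" and random
assignment scores about 0.

The particle swarm optimises only the scalar FDR threshold, on
[10^-4, 0.2]; fitness is the separation score; thresholds admitting fewer
than 2 genes score −1. Hyperparameters are the standard constriction
values (inertia 0.72, cognitive/social 1.49, swarm 20, 50 iterations),
all configurable; the optimum can never be worse than the best initial
particle, and the whole trajectory is deterministic given the seed. On a
one-dimensional problem a swarm is admittedly a luxury — a grid would do
— which is exactly why the tests hold the swarm to the grid's optimum.

A geometric caveat discovered in testing and worth knowing: after
per-gene Z-scoring, a signature whose genes all move in the same
direction contributes almost nothing to Pearson correlation between
samples (the block is absorbed into each sample's profile mean).
Separation by correlation distance therefore relies on mixed-direction
signatures, which real differential-expression signatures are.

# Add-one-in classification

The reference cohort (normal pregnancies + non-pregnant controls) must
first cluster perfectly (score 1); otherwise the analysis aborts. Each
affected sample is then added singly, the stable panel, correction,
3-group DGE (labels: normal_pregnant, non_pregnant, candidate) and
PSO-optimised clustering are rerun from scratch, and three
anti-overfitting criteria are evaluated:

1. **Separation intact** — the 2-group cut of the dendrogram recomputed
   without the candidate reproduces the pregnant/non-pregnant partition
   exactly.
2. **The group test stays strongest** — Welch t-tests on the first
   principal component of the selected-gene expression over all group
   pairs with at least 2 samples; the smallest p must belong to the
   pregnant vs non-pregnant pair. (Pairs involving a singleton candidate
   are not computable and are skipped; the criterion binds once samples
   are pooled.)
3. **Discrete arm** — the candidates are monophyletic in the dendrogram,
   the clusters containing them at the k-group cut contain only
   candidates, no candidate co-clusters with a non-pregnant sample at
   the 2-group cut, and the candidates carry at least 5 significantly
   aberrant genes against the normal reference (outlier t statistic for
   a single candidate, Welch t for pooled candidates, BH-FDR < 0.05).

The aberrant-gene requirement is the statistical half of "discrete arm",
and exists for a concrete reason: the threshold optimiser is an active
adversary. Given any added sample — including one drawn from the normal
model — it will search for an FDR threshold whose gene set happens to
isolate that sample, so topology alone qualifies essentially every
candidate. Requiring a multiplicity-corrected set of genuinely deviant
genes restores the false-positive control: under the null, the expected
number of BH discoveries is near zero and five discoveries is a rare
event, while a real 30-gene |log2FC| = 2 perturbation yields dozens.
This is also the natural reading of grouping samples "to reach
statistical significance": a singleton is trivially a clade, so its
discreteness must be carried by evidence, not topology.

For these dendrograms the distance is Euclidean on the Z-scored genes
(complete linkage) rather than correlation: a candidate that deviates on
a subset of genes separates in Euclidean geometry, whereas its
correlation to normal samples is dominated by the shared genome-wide
pregnancy pattern and barely moves. The pregnant/non-pregnant
separation itself is robust to either metric.

Qualified samples are pooled by a configurable metadata key (the
designed subgroup label, standing in for a shared clinical annotation
such as birth-weight percentile class), and the pooled multi-group
comparison is rerun; with two 2-sample subgroups this is the 4-group
ANOVA whose table contains the subgroup-specific markers. A helper
restricts the normal-vs-preterm comparison to an externally supplied
transcript panel, for testing published signatures on cohorts that carry
no early signal.

# qPCR analysis

Replicate Ct values are averaged per sample/assay;
ΔCt = Ct(target) − Ct(reference) (ACTB or TOP1) and relative quantity
2^−ΔCt. Undetermined Ct values are excluded from averaging, and an assay
with no determined replicate is reported absent, not imputed at the
maximum cycle (imputation at cycle 40 is available but off by default:
zero-imputation turns a detection limit into a fake quantity). Samples
whose reference assay is undetermined are dropped with a warning. No
preamplification correction is applied: uniform preamplification cancels
in ΔCt. Group comparisons are two-sided Mann–Whitney tests against the
control group (small-n robustness; skipped with a warning below 2
samples per group). Marker positivity (VGLL3-style) is a determined Ct
below a configurable cutoff, compared between pregnant and non-pregnant
samples by Fisher's exact test.

# Numerical and testing choices

Defaults: 120 reads / 90% abundance filter; 1M unique and 1e5 fetal
reads; 750 detected genes; cross-correlation threshold 0.5 (used both
for gene screening and factor acceptance); k_max 5; FDR 0.05; PSO bounds
(1e-4, 0.2]. All randomness is seeded; cohorts are byte-identical for a
fixed spec and seed, and the pipeline writes an md5 manifest so reruns
are verifiable.

Test problem sizes are chosen to keep the full suite in the minutes
range while retaining statistical power: the default synthetic cohort is
108/19 samples × 2,000 genes (a scaled-down transcriptome; the real
filtered gene space is about 4× larger); replicated operating
characteristics (null qualification rate, effect-size monotonicity, null
ANOVA calibration) run on 30/10 × 400-gene or 60 × 800-gene cohorts over
20–50 seeds. The fetal-fraction recovery criteria (median absolute error
below one percentage point, Spearman ρ > 0.95) are met with the default
25-gene placental panel; a markedly smaller panel or a heavier-tailed
placental expression distribution degrades the effective number of
averaged genes and the rank agreement first.

# Limitations

The generator's unbiasedness calibration ties the placental signature
scale to the designed reference panel; with a real cohort the estimator
is only as good as the reference-gene criteria, and a systematic shift
of selected reference expression between groups propagates directly
into the fraction scale. Confounders collinear with the protected
contrast (here, maternal age by cohort design) are not correctable by
any control-gene method and surface as genuine group differences — the
package screens them out of the placental panel by effect-size and
abundance criteria but cannot remove them from the marker list in
general. The add-one-in procedure inherits the usual caveat of n-of-1
genomics: qualification says a sample is reproducibly unlike the
reference under these criteria, not what clinical entity it is.
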