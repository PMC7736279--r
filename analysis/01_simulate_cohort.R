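#!/usr/bin/env Rscript

# Generates the synthetic first-trimester plasma cfRNA cohort used by the
# downstream analysis steps: 108 normal pregnancies, 19 non-pregnant
# controls and 4 affected pregnancies in two designed subgroups (a fetal
# and a maternal perturbation, 30 genes at |log2FC| = 2 each), plus the
# qPCR validation scenario. Writes everything under results/cohort/.

suppressPackageStartupMessages(library(cfrnascreen))

seed <- 1L
spec <- cohort_spec(
  n_affected = 4,
  affected_perturbations = list(perturbation("fetal", 30, c(2, -2)),
                                perturbation("maternal", 30, c(-2, 2))),
  seed = seed)
cohort <- generate_cohort(spec)
paths <- write_cohort(cohort, "results/cohort")

cat("cohort:", ncol(cohort$counts$counts), "samples x",
    nrow(cohort$counts$counts), "genes\n")
print(table(cohort$meta$group))
cat("true fetal fractions (pregnant): median",
    round(median(cohort$truth$samples$true_fetal_fraction[
      cohort$truth$samples$group != "non_pregnant"]), 2), "%\n")
cat("written:\n"); print(paths)
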