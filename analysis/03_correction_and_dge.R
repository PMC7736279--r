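#!/usr/bin/env Rscript

# Confounder correction and differential expression of normal pregnancies
# versus non-pregnant controls. Selects the stable-gene panel
# (cross-correlation < 0.5 with the five confounders), removes unwanted
# variation while protecting the pregnant/non-pregnant contrast, runs the
# per-gene ANOVA with BH-FDR, tiers the pregnancy markers, and tests the
# XIST-style fetal-sex contrast. Writes results/dge.csv and
# results/markers.csv.

suppressPackageStartupMessages(library(cfrnascreen))

cm <- suppressWarnings(read_counts("results/cohort/counts.tsv",
                                   "results/cohort/genes.gtf"))
meta <- read_sample_meta("results/cohort/sample_meta.csv")
fl <- filter_low_abundance(cm)
ffr <- read.csv("results/fetal_fractions.csv")
meta$fetal_fraction <- ffr$fraction_percent[match(meta$sample_id,
                                                  ffr$sample_id)]

logmat <- log_cpm(fl$counts$counts, meta$library_size)
is_ref <- meta$group != "affected"
grp <- ifelse(meta$group == "non_pregnant", "non_pregnant", "normal_pregnant")
confs <- c("maternal_age", "library_size", "gestational_age",
           "fetal_fraction", "purification")

panel <- select_stable_genes(logmat[, is_ref], meta[is_ref, ],
                             confounders = confs)
print(panel)
corr <- remove_unwanted_variation(logmat[, is_ref], panel,
                                  groups = grp[is_ref],
                                  meta = meta[is_ref, ], confounders = confs)
print(corr)
cat("factor-confounder associations:\n")
print(round(corr$factor_assoc, 3))

dge <- run_dge(corr$mat, grp[is_ref],
               contrast = c("normal_pregnant", "non_pregnant"))
ctrl <- meta$sample_id[is_ref & grp == "non_pregnant"]
markers <- pregnancy_markers(dge, detection_rate(fl$counts, ctrl))
cat(sprintf("%d pregnancy markers at FDR < 0.05 (%d with logFC > 2, %d with logFC > 1)\n",
            nrow(markers), sum(markers$tier == "logFC>2"),
            sum(markers$tier == "logFC>1")))

truth <- read.csv("results/cohort/truth_genes.csv")
sexm <- truth$gene_id[truth$class == "sex_marker"]
sx <- xist_contrast(corr$mat, meta[is_ref, ], sexm)
cat(sprintf("fetal-sex marker: logFC %.2f (female vs male), FDR %.2g\n",
            sx$logFC, sx$fdr))

write.csv(as.data.frame(dge), "results/dge.csv", row.names = FALSE)
write.csv(markers, "results/markers.csv", row.names = FALSE)
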