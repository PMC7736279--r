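#!/usr/bin/env Rscript

# PSO-optimised hierarchical clustering and the add-one-in analysis of the
# affected pregnancies. The particle swarm tunes the FDR threshold that
# selects genes for the heatmap dendrogram; each affected sample is then
# added singly to the reference set, the correction/DGE/clustering rerun,
# and the three anti-overfitting criteria evaluated; qualified samples are
# pooled into subgroups and the 4-group comparison rerun. Writes
# results/add_one_in_report.csv and the dendrogram in Newick format.

suppressPackageStartupMessages(library(cfrnascreen))

seed <- 1L
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
corr <- remove_unwanted_variation(logmat[, is_ref], panel, grp[is_ref],
                                  meta = meta[is_ref, ], confounders = confs)
dge <- run_dge(corr$mat, grp[is_ref],
               contrast = c("normal_pregnant", "non_pregnant"))

opt <- optimize_fdr_threshold(corr$mat, dge, grp[is_ref], seed = seed)
cat(sprintf("PSO-selected FDR threshold %.4f -> %d genes, separation score %.3f\n",
            opt$threshold, length(opt$clustering$genes), opt$clustering$score))
ape::write.tree(ape::as.phylo(opt$clustering$tree),
                "results/dendrogram.nwk")

if (requireNamespace("pheatmap", quietly = TRUE)) {
  ann <- data.frame(group = grp[is_ref],
                    row.names = colnames(opt$clustering$zmat))
  pheatmap::pheatmap(opt$clustering$zmat,
                     cluster_cols = opt$clustering$tree,
                     annotation_col = ann, show_colnames = FALSE,
                     filename = "results/heatmap.png", width = 9, height = 6)
}

aoi <- add_one_in(logmat, meta,
                  config = add_one_in_config(confounders = confs,
                                             seed = seed))
print(aoi)
print(aoi$report)
write.csv(aoi$report, "results/add_one_in_report.csv", row.names = FALSE)

if (!is.null(aoi$pooled)) {
  pooled <- as.data.frame(aoi$pooled$dge)
  write.csv(pooled, "results/pooled_dge.csv", row.names = FALSE)
  cat(sprintf("pooled comparison: %d genes at FDR < 0.05 across %d groups\n",
              sum(pooled$fdr < 0.05), length(unique(aoi$pooled$labels))))
}
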