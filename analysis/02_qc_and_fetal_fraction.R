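#!/usr/bin/env Rscript

# QC filtering and fetal RNA fraction estimation on the simulated cohort.
# Reads results/cohort/, applies the 120-read/90% low-abundance filter,
# estimates per-sample fetal fractions from RPKM ratios of placental vs
# reference genes, applies the sample-level exclusions (1M unique reads,
# 100,000 fetal reads, 750 detected genes), and writes
# results/fetal_fractions.csv plus the filter reports.

suppressPackageStartupMessages(library(cfrnascreen))

cm <- suppressWarnings(read_counts("results/cohort/counts.tsv",
                                   "results/cohort/genes.gtf"))
meta <- read_sample_meta("results/cohort/sample_meta.csv")

fl <- filter_low_abundance(cm)
print(fl$report)

ff <- fetal_fraction_pipeline(fl$counts, meta)
print(ff)
preg <- meta$group != "non_pregnant"
cat(sprintf("median fetal fraction: %.2f%% (pregnant), %.2f%% (non-pregnant)\n",
            median(ff$fraction_percent[meta$sample_id[preg]]),
            median(ff$fraction_percent[meta$sample_id[!preg]])))

fs <- filter_samples(fl$counts, meta, ff)
print(fs$report)

dir.create("results", showWarnings = FALSE)
write.csv(data.frame(sample_id = names(ff$fraction_percent),
                     fraction_percent = ff$fraction_percent,
                     n_placental = length(ff$placental_genes),
                     n_reference = length(ff$reference_genes)),
          "results/fetal_fractions.csv", row.names = FALSE)
jsonlite::write_json(
  list(genes_removed = fl$report$n_removed,
       genes_kept = fl$report$n_kept,
       samples_removed = fs$report$n_removed,
       pct_samples_removed = fs$report$pct_removed),
  "results/filter_report.json", auto_unbox = TRUE, pretty = TRUE)
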