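#!/usr/bin/env Rscript

# qPCR validation arm: delta-Ct quantification of the synthetic Ct tables,
# the NRIP1/ZEB2 ratio (up in both pre-eclampsia and trisomy 21) and the
# linear/circular NRIP1 ratio that discriminates the two, plus the
# VGLL3-style pregnancy-specificity test. Writes results/qpcr_ratios.csv.

suppressPackageStartupMessages(library(cfrnascreen))

seed <- 1L

## scenario: PE doubles linear NRIP1 only; T21 doubles both NRIP1 forms
qs <- expand.grid(sample_id = sprintf("q%02d", 1:30),
                  assay = c("NRIP1_linear", "NRIP1_circ", "ZEB2"),
                  stringsAsFactors = FALSE)
qs$group <- rep(rep(c("control", "PE", "T21"), each = 10), 3)
qs$quantity <- 1
qs$quantity[qs$group == "PE" & qs$assay == "NRIP1_linear"] <- 2
qs$quantity[qs$group == "T21" & qs$assay == "NRIP1_linear"] <- 2
qs$quantity[qs$group == "T21" & qs$assay == "NRIP1_circ"] <- 2

ct <- generate_ct_table(qs, seed = seed)
q <- delta_ct(ct, "ACTB")
mr <- marker_ratios(q)
cat("group medians:\n")
print(aggregate(cbind(target_ratio, lin_circ_ratio) ~ group,
                mr$ratios, median))
cat("Mann-Whitney tests vs control:\n")
print(mr$tests)
write.csv(mr$ratios, "results/qpcr_ratios.csv", row.names = FALSE)

## pregnancy-specific marker: detectable in pregnant plasma only
ctv <- generate_ct_table(
  data.frame(sample_id = sprintf("v%02d", 1:18),
             group = c(rep("pregnant", 10), rep("non_pregnant", 8)),
             assay = "VGLL3",
             quantity = c(rep(1, 10), rep(1e-9, 8))),
  seed = seed)
ctv$ct[ctv$group == "non_pregnant"] <- NA    # below detection
det <- detect_pregnancy_marker(ctv)
print(det$table)
cat(sprintf("Fisher exact p = %.3g\n", det$p_value))
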