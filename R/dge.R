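#' Multi-group differential expression by per-gene one-way ANOVA
#'
#' One-way ANOVA across the sample groups on (corrected) log-expression,
#' computed gene-wise in vectorised form; p-values are Benjamini-Hochberg
#' adjusted across all tested genes. The log2 fold change is the difference
#' of group means for the two groups named in `contrast`. With two groups
#' the F statistic equals the square of the pooled-variance t statistic.
#'
#' Genes with zero between- and within-group variance get F = 0, p = 1.
#' Singleton groups (permitted only when `min_group_size = 1`, as in the
#' add-one-in analysis) contribute to between-group variation only.
#'
#' @param mat numeric matrix (genes x samples), log scale.
#' @param groups group label per sample.
#' @param contrast length-2 character vector `(a, b)`: logFC = mean(a) -
#'   mean(b). Defaults to the first two group levels.
#' @param min_group_size minimum samples per group (default 2).
#' @return data.frame of class `cf_dge`: `gene`, `logFC`, `p_value`, `fdr`,
#'   `F`, and one `mean_<group>` column per group; contrast stored as an
#'   attribute.
#' @export
run_dge <- function(mat, groups, contrast = NULL, min_group_size = 2) {
  groups <- as.factor(as.character(groups))
  if (length(groups) != ncol(mat)) stop("groups must label every sample")
  ng <- nlevels(groups)
  if (ng < 2) stop("need >= 2 groups")
  sizes <- table(groups)
  if (any(sizes < min_group_size))
    stop("group(s) with fewer than ", min_group_size, " samples: ",
         paste(names(sizes)[sizes < min_group_size], collapse = ", "))
  if (is.null(contrast)) contrast <- levels(groups)[1:2]
  if (!all(contrast %in% levels(groups)))
    stop("contrast groups not found: ", paste(contrast, collapse = " vs "))

  N <- ncol(mat)
  means <- vapply(levels(groups), function(g)
    rowMeans(mat[, groups == g, drop = FALSE]), numeric(nrow(mat)))
  means <- matrix(means, nrow = nrow(mat),
                  dimnames = list(rownames(mat), levels(groups)))
  grand <- rowMeans(mat)
  n_g <- as.numeric(sizes[colnames(means)])
  ss_between <- rowSums(sweep((means - grand)^2, 2, n_g, "*"))
  ss_total <- rowSums((mat - grand)^2)
  ss_within <- pmax(ss_total - ss_between, 0)
  df1 <- ng - 1
  df2 <- N - ng
  if (df2 <= 0) stop("no residual degrees of freedom")
  Fst <- (ss_between / df1) / (ss_within / df2)
  Fst[ss_between < 1e-12 & ss_within < 1e-12] <- 0
  p <- stats::pf(Fst, df1, df2, lower.tail = FALSE)
  p[is.na(p)] <- 1

  out <- data.frame(gene = rownames(mat),
                    logFC = means[, contrast[1]] - means[, contrast[2]],
                    p_value = p, fdr = stats::p.adjust(p, "BH"), F = Fst,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (g in colnames(means)) out[[paste0("mean_", g)]] <- means[, g]
  attr(out, "contrast") <- contrast
  attr(out, "groups") <- levels(groups)
  class(out) <- c("cf_dge", class(out))
  out
}

#' Per-gene detection rate in a sample subset
#'
#' Fraction of the given samples with a nonzero count, used to classify
#' markers as pregnancy-specific (essentially absent in controls) versus
#' pregnancy-enriched.
#'
#' @param cm [cf_counts].
#' @param samples sample ids (e.g. the non-pregnant controls).
#' @return named numeric vector in [0, 1].
#' @export
detection_rate <- function(cm, samples) {
  rowMeans(cm$counts[, samples, drop = FALSE] > 0)
}

#' Tiered pregnancy marker list
#'
#' Partitions significant genes (FDR < `fdr_lt`, logFC > 0 on the pregnant
#' vs non-pregnant contrast) into tiers `logFC > 2`, `logFC > 1` and the
#' remainder, and flags each as `specific` (control-group detection rate
#' below `specific_detection`) or `enriched`.
#'
#' @param dge `cf_dge` on the pregnant vs non-pregnant contrast.
#' @param control_detection named per-gene detection rate in the control
#'   group, from [detection_rate()]; `NULL` marks every gene `enriched`.
#' @param fdr_lt significance cutoff (default 0.05).
#' @param logfc_tiers tier boundaries (default `c(1, 2)`).
#' @param specific_detection detection-rate cutoff for "specific"
#'   (default 0.1).
#' @return data.frame with `gene`, `logFC`, `fdr`, `tier`, `status`.
#' @export
pregnancy_markers <- function(dge, control_detection = NULL, fdr_lt = 0.05,
                              logfc_tiers = c(1, 2),
                              specific_detection = 0.1) {
  sig <- dge[dge$fdr < fdr_lt & dge$logFC > 0, , drop = FALSE]
  tier <- ifelse(sig$logFC > logfc_tiers[2], paste0("logFC>", logfc_tiers[2]),
                 ifelse(sig$logFC > logfc_tiers[1],
                        paste0("logFC>", logfc_tiers[1]), "other"))
  status <- rep("enriched", nrow(sig))
  if (!is.null(control_detection))
    status[control_detection[sig$gene] < specific_detection] <- "specific"
  out <- data.frame(gene = sig$gene, logFC = sig$logFC, fdr = sig$fdr,
                    tier = tier, status = status, stringsAsFactors = FALSE)
  out[order(-out$logFC), ]
}

#' Fetal-sex marker contrast (XIST-style 3-group ANOVA)
#'
#' Tests a designated chrX marker for upregulation in female-fetus versus
#' male-fetus pregnancies, with non-pregnant controls as third group.
#' Fetal fraction and gestational age are regressed out per gene (jointly
#' with the three protected group means) before the 3-group ANOVA; both
#' corrections target the placental component of the signal.
#'
#' @param logmat log-expression matrix (genes x samples).
#' @param meta metadata with `group`, `fetal_sex`, `fetal_fraction`,
#'   `gestational_age`.
#' @param marker gene id of the sex marker.
#' @return single-row `cf_dge` for the marker (logFC = female - male),
#'   with the full table in attribute `full`.
#' @export
xist_contrast <- function(logmat, meta, marker) {
  meta <- meta[match(colnames(logmat), meta$sample_id), ]
  if (!marker %in% rownames(logmat)) stop("marker gene not in matrix: ", marker)
  preg <- meta$group != "non_pregnant"
  if (any(preg & is.na(meta$fetal_sex)))
    stop("missing fetal sex labels for pregnant sample(s)")
  grp3 <- ifelse(!preg, "non_pregnant",
                 ifelse(meta$fetal_sex == "female", "female_fetus", "male_fetus"))

  ff <- meta$fetal_fraction
  ga <- meta$gestational_age
  ga[is.na(ga)] <- mean(ga, na.rm = TRUE)
  if (is.null(ff)) stop("fetal_fraction column required in metadata")
  design <- cbind(stats::model.matrix(~ 0 + factor(grp3)), ff = ff, ga = ga)
  qr_d <- qr(design)
  coefs <- t(qr.coef(qr_d, t(logmat)))
  coefs[is.na(coefs)] <- 0
  covar <- design[, c("ff", "ga"), drop = FALSE]
  corrected <- logmat - coefs[, c("ff", "ga"), drop = FALSE] %*% t(covar)

  dge <- run_dge(corrected, grp3, contrast = c("female_fetus", "male_fetus"))
  row <- dge[dge$gene == marker, , drop = FALSE]
  attr(row, "full") <- dge
  row
}
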