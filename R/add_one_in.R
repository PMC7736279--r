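#' Configuration for the add-one-in analysis
#'
#' @param confounders metadata columns used for stable-gene selection and
#'   factor acceptance (intersected with available columns).
#' @param corr_threshold cross-correlation threshold (default 0.5).
#' @param k_max maximum unwanted-variation factors.
#' @param fdr_bounds FDR-threshold search interval for the PSO.
#' @param swarm_size,iterations PSO settings (kept small: the landscape is
#'   one-dimensional).
#' @param marker_fdr FDR cutoff defining the marker panel used for the
#'   criterion (ii) t-tests.
#' @param group_key metadata column used to pool qualified samples into
#'   candidate subgroups (default `"subgroup"`, e.g. a shared clinical
#'   annotation).
#' @param min_panel minimum stable-panel size.
#' @param dist_method,linkage clustering distance and linkage for the
#'   add-one-in dendrograms. Euclidean distance on the Z-scored genes with
#'   complete linkage is the default: an added sample with an aberrant
#'   profile on a subset of genes separates in Euclidean geometry, whereas
#'   correlation distance is dominated by the genome-wide pregnancy
#'   pattern shared with the normal samples.
#' @param min_aberrant minimum number of significantly aberrant genes
#'   (outlier test of the candidate against the normal reference, BH-FDR
#'   < `marker_fdr`) required for qualification; this is the statistical
#'   part of the discrete-arm criterion, preventing a threshold overfit
#'   to chance patterns from qualifying a null sample.
#' @param seed RNG seed for the PSO.
#' @export
add_one_in_config <- function(confounders = c("maternal_age", "library_size",
                                              "gestational_age",
                                              "fetal_fraction", "purification"),
                              corr_threshold = 0.5, k_max = 5,
                              fdr_bounds = c(1e-4, 0.2), swarm_size = 10,
                              iterations = 15, marker_fdr = 0.05,
                              group_key = "subgroup", min_panel = 30,
                              dist_method = "euclidean", linkage = "complete",
                              min_aberrant = 5, seed = 1L) {
  list(confounders = confounders, corr_threshold = corr_threshold,
       k_max = k_max, fdr_bounds = fdr_bounds, swarm_size = swarm_size,
       iterations = iterations, marker_fdr = marker_fdr,
       group_key = group_key, min_panel = min_panel,
       dist_method = dist_method, linkage = linkage,
       min_aberrant = min_aberrant, seed = as.integer(seed))
}

#' Significantly aberrant genes of candidate samples versus a reference
#'
#' Per gene, tests whether the candidate sample(s) deviate from the normal
#' reference group: a single candidate is scored by the outlier t statistic
#' `(x_c - mean_ref) / (sd_ref * sqrt(1 + 1/n_ref))` on `n_ref - 1`
#' degrees of freedom; two or more candidates by a Welch t-test. P-values
#' are BH-adjusted across genes.
#'
#' @param mat (corrected) log-expression matrix.
#' @param ref_ids reference sample ids (normal pregnancies).
#' @param candidate_ids candidate sample id(s).
#' @param fdr_lt significance cutoff (default 0.05).
#' @return character vector of aberrant gene ids, with the per-gene table
#'   as attribute `table`.
#' @export
candidate_aberrant_genes <- function(mat, ref_ids, candidate_ids,
                                     fdr_lt = 0.05) {
  ref <- mat[, ref_ids, drop = FALSE]
  cand <- mat[, candidate_ids, drop = FALSE]
  n_ref <- ncol(ref)
  if (n_ref < 3) stop("need >= 3 reference samples")
  mu <- rowMeans(ref)
  sd_ref <- apply(ref, 1, stats::sd)
  sd_ref[sd_ref == 0] <- Inf
  if (ncol(cand) == 1) {
    tstat <- (cand[, 1] - mu) / (sd_ref * sqrt(1 + 1 / n_ref))
    df <- n_ref - 1
  } else {
    mu_c <- rowMeans(cand)
    sd_c <- apply(cand, 1, stats::sd)
    n_c <- ncol(cand)
    se <- sqrt(sd_c^2 / n_c + sd_ref^2 / n_ref)
    tstat <- (mu_c - mu) / se
    df <- pmax(1, se^4 / (ifelse(sd_c > 0, (sd_c^2 / n_c)^2 / (n_c - 1), 0) +
                            (sd_ref^2 / n_ref)^2 / (n_ref - 1)))
  }
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  fdr <- stats::p.adjust(p, "BH")
  genes <- rownames(mat)[fdr < fdr_lt]
  attr(genes, "table") <- data.frame(gene = rownames(mat), t = tstat,
                                     p_value = p, fdr = fdr,
                                     stringsAsFactors = FALSE, row.names = NULL)
  genes
}

#' Evaluate the three anti-overfitting criteria for candidate samples
#'
#' Given a clustering of the augmented cohort (labels: normal_pregnant,
#' non_pregnant, candidate), checks:
#' \itemize{
#' \item (i) pregnant vs non-pregnant discrimination remains intact: the
#'   2-group cut of the dendrogram recomputed without the candidates
#'   reproduces the pregnant/non-pregnant partition exactly;
#' \item (ii) the pregnant vs non-pregnant group comparison remains the
#'   most significant: Welch t-tests on the first principal component of
#'   the marker-panel expression, over all group pairs with at least two
#'   samples each, are minimised by the pregnant/non-pregnant pair;
#' \item (iii) the candidates form a discrete arm: they are monophyletic in
#'   the dendrogram, the clusters containing them at the k-group cut
#'   contain only candidates, no candidate co-clusters with a non-pregnant
#'   sample at the 2-group cut, and (when `aberrant` is given) the
#'   candidates carry at least `min_aberrant` significantly aberrant genes
#'   against the normal reference — a discrete arm must reflect a real
#'   expression difference, not a clustering threshold overfit to chance.
#' }
#' A single candidate is trivially monophyletic; its discreteness is
#' carried by the own-arm requirement at the k-group cut plus the
#' aberrant-gene requirement.
#'
#' @param clustering `cf_clustering` of the augmented cohort.
#' @param candidate_ids sample ids of the added candidates.
#' @param aberrant number of significantly aberrant candidate genes, from
#'   [candidate_aberrant_genes()]; `NULL` skips that component.
#' @param min_aberrant minimum aberrant genes for criterion (iii)
#'   (default 5).
#' @return named logical vector `(criterion1, criterion2, criterion3)`.
#' @export
evaluate_criteria <- function(clustering, candidate_ids, aberrant = NULL,
                              min_aberrant = 5) {
  labels <- clustering$labels
  sids <- names(clustering$clusters)
  cand <- sids %in% candidate_ids
  nonpreg <- labels == "non_pregnant" & !cand
  preg <- !nonpreg & !cand

  ## (i) 2-group cut excluding candidates
  z_ref <- clustering$zmat[, !cand, drop = FALSE]
  crit1 <- FALSE
  if (sum(preg) >= 1 && sum(nonpreg) >= 1 && ncol(z_ref) >= 2) {
    d <- if (clustering$dist_method == "correlation")
      stats::as.dist(1 - stats::cor(z_ref))
    else stats::dist(t(z_ref), method = clustering$dist_method)
    cut2 <- stats::cutree(stats::hclust(d, method = clustering$linkage), k = 2)
    truth <- ifelse(nonpreg[!cand], "non_pregnant", "pregnant")
    crit1 <- mclust::adjustedRandIndex(cut2, truth) == 1
  }

  ## (ii) smallest Welch t-test p on PC1 among computable group pairs
  pc1 <- stats::prcomp(t(clustering$zmat), center = TRUE, scale. = FALSE)$x[, 1]
  side <- rep("pregnant", length(sids))
  side[nonpreg] <- "non_pregnant"
  side[cand] <- "candidate"
  lv <- unique(side)
  pvals <- c()
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    if (j <= i) next
    a <- pc1[side == lv[i]]; b <- pc1[side == lv[j]]
    if (length(a) < 2 || length(b) < 2) next
    if (stats::sd(c(a, b)) == 0) next
    pvals[paste(lv[i], lv[j], sep = "|")] <-
      stats::t.test(a, b)$p.value
  }
  key <- c("pregnant|non_pregnant", "non_pregnant|pregnant")
  crit2 <- if (!any(names(pvals) %in% key)) TRUE
           else min(pvals[names(pvals) %in% key]) <= min(pvals) + 1e-15

  ## (iii) discrete candidate arm
  crit3 <- FALSE
  if (any(cand)) {
    k_clusters <- clustering$clusters
    cand_clusters <- unique(k_clusters[cand])
    pure <- all(k_clusters %in% cand_clusters == cand)
    mono <- TRUE
    if (sum(cand) >= 2) {
      phy <- ape::as.phylo(clustering$tree)
      mono <- ape::is.monophyletic(phy, sids[cand])
    }
    cut2_full <- stats::cutree(clustering$tree, k = 2)
    with_nonpreg <- any(vapply(which(cand), function(i)
      any(cut2_full[nonpreg] == cut2_full[i]), logical(1)))
    crit3 <- pure && mono && !with_nonpreg
    if (!is.null(aberrant)) crit3 <- crit3 && aberrant >= min_aberrant
  }

  c(criterion1 = crit1, criterion2 = crit2, criterion3 = crit3)
}

#' Add-one-in (reverse leave-one-out) classification of affected samples
#'
#' Each affected sample is added singly to the reference cohort (normal
#' pregnancies plus non-pregnant controls); the correction, multi-group
#' differential expression and PSO-optimised clustering are rerun on the
#' augmented cohort with labels \{normal_pregnant, non_pregnant,
#' candidate\}; and the three anti-overfitting criteria are evaluated.
#' A sample qualifies iff all three pass. Qualified samples are then
#' pooled into subgroups by `config$group_key` and the pooled multi-group
#' comparison is rerun to reach group-level significance.
#'
#' @param logmat log-CPM matrix for reference and affected samples
#'   (genes x samples, already abundance-filtered).
#' @param meta metadata covering every column of `logmat`, including the
#'   correction confounders (`fetal_fraction` column as estimated
#'   upstream) and the `group_key` column for affected samples.
#' @param affected_ids sample ids to test (default: samples with
#'   `group == "affected"`).
#' @param config [add_one_in_config()].
#' @return object of class `cf_addonein`: list with `report` (per-sample
#'   criteria and qualification), `runs` (per-sample clustering and DGE),
#'   `pooled` (pooled DGE + clustering across qualified subgroups, or
#'   NULL), `baseline` (reference clustering).
#' @export
add_one_in <- function(logmat, meta, affected_ids = NULL,
                       config = add_one_in_config()) {
  meta <- meta[match(colnames(logmat), meta$sample_id), ]
  if (is.null(affected_ids))
    affected_ids <- meta$sample_id[meta$group == "affected"]
  if (length(affected_ids) < 1) stop("no affected samples to test")
  ref_ids <- setdiff(meta$sample_id[meta$group != "affected"], affected_ids)
  confs <- intersect(config$confounders, names(meta))

  fit_stage <- function(ids, labels, pso_labels = labels) {
    sub <- logmat[, ids, drop = FALSE]
    msub <- meta[match(ids, meta$sample_id), ]
    panel <- select_stable_genes(sub, msub, confounders = confs,
                                 corr_threshold = config$corr_threshold,
                                 min_panel = config$min_panel)
    corr <- remove_unwanted_variation(sub, panel, groups = labels,
                                      meta = msub, confounders = confs,
                                      k_max = config$k_max,
                                      corr_threshold = config$corr_threshold)
    dge <- run_dge(corr$mat, labels, contrast = dge_contrast(labels),
                   min_group_size = 1)
    opt <- optimize_fdr_threshold(corr$mat, dge, pso_labels,
                                  bounds = config$fdr_bounds,
                                  swarm_size = config$swarm_size,
                                  iterations = config$iterations,
                                  seed = config$seed,
                                  dist_method = config$dist_method,
                                  linkage = config$linkage)
    list(dge = dge, clustering = opt$clustering, threshold = opt$threshold,
         corrected = corr)
  }

  ## baseline: reference cohort must separate perfectly
  ref_labels <- ifelse(meta$group[match(ref_ids, meta$sample_id)] == "non_pregnant",
                       "non_pregnant", "normal_pregnant")
  baseline <- fit_stage(ref_ids, ref_labels)
  if (baseline$clustering$score < 1)
    stop("reference cohort fails baseline pregnant/non-pregnant separation ",
         "(score ", round(baseline$clustering$score, 3), ")")

  runs <- list()
  rows <- list()
  normal_ids <- ref_ids[ref_labels == "normal_pregnant"]
  for (s in affected_ids) {
    ids <- c(ref_ids, s)
    labels <- c(ref_labels, "candidate")
    stage <- fit_stage(ids, labels)
    aberrant <- candidate_aberrant_genes(stage$corrected$mat, normal_ids, s,
                                         fdr_lt = config$marker_fdr)
    stage$aberrant_genes <- aberrant
    crit <- evaluate_criteria(stage$clustering, s,
                              aberrant = length(aberrant),
                              min_aberrant = config$min_aberrant)
    rows[[s]] <- data.frame(sample_id = s,
                            criterion1 = crit[["criterion1"]],
                            criterion2 = crit[["criterion2"]],
                            criterion3 = crit[["criterion3"]],
                            qualified = all(crit),
                            stringsAsFactors = FALSE)
    runs[[s]] <- stage
  }
  report <- do.call(rbind, c(rows, make.row.names = FALSE))
  report$subgroup <- NA_character_
  qual <- report$sample_id[report$qualified]
  if (length(qual) && config$group_key %in% names(meta)) {
    report$subgroup[report$qualified] <-
      as.character(meta[[config$group_key]][match(qual, meta$sample_id)])
  }

  pooled <- NULL
  if (length(qual) >= 1) {
    sub_lab <- report$subgroup[report$qualified]
    sub_lab[is.na(sub_lab)] <- "candidate"
    ids <- c(ref_ids, qual)
    labels <- c(ref_labels, paste0("candidate_", sub_lab))
    stage <- fit_stage(ids, labels)
    pooled <- list(dge = stage$dge, clustering = stage$clustering,
                   threshold = stage$threshold, labels = labels, ids = ids)
  }

  structure(list(report = report, runs = runs, pooled = pooled,
                 baseline = baseline),
            class = "cf_addonein")
}

# contrast for the DGE stage: normal pregnant vs non-pregnant when present
dge_contrast <- function(labels) {
  lv <- unique(labels)
  if (all(c("normal_pregnant", "non_pregnant") %in% lv))
    c("normal_pregnant", "non_pregnant")
  else lv[1:2]
}

#' @export
print.cf_addonein <- function(x, ...) {
  cat(sprintf("add-one-in: %d candidates, %d qualified\n",
              nrow(x$report), sum(x$report$qualified)))
  invisible(x)
}

#' Restricted differential expression on a transcript panel
#'
#' Limits the normal vs SPB (or any two-group) comparison to a supplied
#' transcript panel, e.g. a published late-pregnancy preterm-birth
#' signature. Panel genes absent from the matrix are dropped with a
#' warning; an empty intersection is an error.
#'
#' @param mat corrected log-expression matrix.
#' @param meta metadata with `group`/`subgroup` labels.
#' @param transcript_panel character vector of gene ids.
#' @param case_label subgroup label of the cases (default `"SPB"`).
#' @return `cf_dge` restricted to the panel, contrast case vs normal.
#' @export
classify_spb_panel <- function(mat, meta, transcript_panel,
                               case_label = "SPB") {
  meta <- meta[match(colnames(mat), meta$sample_id), ]
  panel <- intersect(transcript_panel, rownames(mat))
  if (length(panel) == 0)
    stop("none of the panel transcripts are present in the matrix")
  if (length(panel) < length(transcript_panel))
    warning(length(transcript_panel) - length(panel),
            " panel transcript(s) absent from matrix; proceeding on the intersection")
  is_case <- !is.na(meta$subgroup) & meta$subgroup == case_label
  is_normal <- meta$group == "normal_pregnant"
  keep <- is_case | is_normal
  if (sum(is_case) < 2) stop("fewer than 2 '", case_label, "' samples")
  grp <- ifelse(is_case[keep], case_label, "normal_pregnant")
  run_dge(mat[panel, keep, drop = FALSE], grp,
          contrast = c(case_label, "normal_pregnant"))
}
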