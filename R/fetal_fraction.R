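#' Reads per kilobase of merged exon model per million assigned reads
#'
#' `RPKM = count * 1e9 / (length_bp * library_size)`, with the library size
#' taken as the uniquely-assigned exonic read total per sample.
#'
#' @param cm [cf_counts].
#' @param library_sizes per-sample totals; defaults to column sums of the
#'   (unfiltered) matrix. Pass the metadata library sizes when the matrix
#'   has been gene-filtered.
#' @return numeric matrix (genes x samples) of class `cf_rpkm` with the
#'   derivation metadata attached as attributes.
#' @export
compute_rpkm <- function(cm, library_sizes = colSums(cm$counts)) {
  if (!inherits(cm, "cf_counts")) stop("cm must be a cf_counts object")
  if (any(library_sizes <= 0)) stop("zero or negative library size")
  len <- as.numeric(cm$genes$length_bp)
  if (any(len <= 0)) stop("non-positive gene length")
  library_sizes <- as.numeric(library_sizes)
  rpkm <- cm$counts * 1e9 / (len * rep(library_sizes, each = nrow(cm$counts)))
  structure(rpkm, class = c("cf_rpkm", class(rpkm)),
            library_sizes = library_sizes, length_bp = len)
}

#' Select stably expressed reference genes for fetal-fraction estimation
#'
#' A gene qualifies as a reference gene unless it is excluded by any of:
#' mean RPKM below `mean_min` in every group; pregnant/non-pregnant mean
#' ratio outside `ratio_bounds`; or average coefficient of variation
#' (computed per group, then averaged) above `cv_max`. Criteria are applied
#' on raw RPKM values.
#'
#' @param rpkm RPKM matrix from [compute_rpkm()].
#' @param meta metadata with `sample_id`, `group`; both pregnant and
#'   non-pregnant samples must be present.
#' @param mean_min minimum group-mean RPKM (default 1).
#' @param ratio_bounds admissible pregnant/non-pregnant mean ratio
#'   (default `c(0.8, 1.2)`).
#' @param cv_max maximum average CV (default 0.3).
#' @return character vector of reference gene ids, with the per-gene
#'   criteria table attached as attribute `criteria`.
#' @export
select_reference_genes <- function(rpkm, meta, mean_min = 1,
                                   ratio_bounds = c(0.8, 1.2), cv_max = 0.3) {
  meta <- meta[match(colnames(rpkm), meta$sample_id), ]
  preg <- meta$group != "non_pregnant"
  if (!any(preg) || !any(!preg))
    stop("both pregnant and non-pregnant samples are required")
  mean_p <- rowMeans(rpkm[, preg, drop = FALSE])
  mean_n <- rowMeans(rpkm[, !preg, drop = FALSE])
  cv <- function(m) {
    mu <- rowMeans(m)
    s <- apply(m, 1, stats::sd)
    ifelse(mu > 0, s / mu, Inf)
  }
  avg_cv <- (cv(rpkm[, preg, drop = FALSE]) + cv(rpkm[, !preg, drop = FALSE])) / 2
  ratio <- ifelse(mean_n > 0, mean_p / mean_n, Inf)
  ok <- (mean_p >= mean_min | mean_n >= mean_min) &
    ratio >= ratio_bounds[1] & ratio <= ratio_bounds[2] &
    avg_cv <= cv_max
  genes <- rownames(rpkm)[ok]
  if (length(genes) == 0)
    stop("no reference genes satisfy the criteria; enlarge the gene panel ",
         "or relax mean_min/ratio_bounds/cv_max")
  attr(genes, "criteria") <- data.frame(
    gene_id = rownames(rpkm), mean_pregnant = mean_p, mean_nonpregnant = mean_n,
    ratio = ratio, avg_cv = avg_cv, selected = ok, stringsAsFactors = FALSE)
  genes
}

#' Select placental (pregnancy-enriched) genes from a DGE table
#'
#' Genes significant at `fdr_lt` with higher expression in pregnant than
#' non-pregnant samples. The fraction denominator must measure added
#' placental material, hence the restriction to upregulated genes.
#'
#' @param dge a `cf_dge` table from [run_dge()] on the pregnant vs
#'   non-pregnant contrast (logFC oriented pregnant minus non-pregnant).
#' @param fdr_lt FDR cutoff (default 0.05).
#' @param logfc_gt additional lower bound on logFC (default 0). The
#'   fetal-fraction pipeline uses 2: the strongly upregulated tier
#'   corresponds to the placenta-exclusive genes whose plasma signal is
#'   proportional to the placental contribution, whereas moderately
#'   upregulated genes are typically maternal pregnancy-response genes
#'   that would inflate the numerator.
#' @param max_control_mean upper bound on the control-group mean
#'   log2(CPM+1) (default `Inf`). The fraction numerator must count added
#'   placental material, so genes with an appreciable maternal baseline
#'   (well expressed in non-pregnant plasma) are excluded even when
#'   strongly upregulated; requires a `mean_<control_group>` column.
#' @param control_group control group name (default `"non_pregnant"`).
#' @export
select_placental_genes <- function(dge, fdr_lt = 0.05, logfc_gt = 0,
                                   max_control_mean = Inf,
                                   control_group = "non_pregnant") {
  sel <- dge$fdr < fdr_lt & dge$logFC > logfc_gt
  if (is.finite(max_control_mean)) {
    col <- paste0("mean_", control_group)
    if (!col %in% names(dge))
      stop("column '", col, "' required for max_control_mean")
    sel <- sel & dge[[col]] <= max_control_mean
  }
  if (!any(sel, na.rm = TRUE))
    stop("no significant pregnancy-enriched genes at FDR < ", fdr_lt,
         " with logFC > ", logfc_gt)
  dge$gene[which(sel)]
}

#' Estimate per-sample fetal RNA fraction
#'
#' `fraction = 100 * mean(RPKM over placental genes) /
#'             mean(RPKM over reference genes)` per sample.
#' Fractions above 100% are arithmetically allowed but flagged.
#'
#' @param rpkm RPKM matrix.
#' @param placental,reference disjoint, non-empty gene-id sets.
#' @return object of class `fetal_fraction_result`: list with
#'   `fraction_percent` (named per-sample vector), the gene sets, and QC
#'   flags.
#' @export
estimate_fetal_fraction <- function(rpkm, placental, reference) {
  placental <- intersect(placental, rownames(rpkm))
  reference <- intersect(reference, rownames(rpkm))
  if (length(placental) == 0 || length(reference) == 0)
    stop("placental and reference gene sets must be non-empty")
  if (length(intersect(placental, reference)) > 0)
    stop("placental and reference gene sets must be disjoint")
  num <- colMeans(rpkm[placental, , drop = FALSE])
  den <- colMeans(rpkm[reference, , drop = FALSE])
  if (any(den == 0)) stop("zero mean reference RPKM for sample(s): ",
                          paste(colnames(rpkm)[den == 0], collapse = ", "))
  frac <- 100 * num / den
  if (any(frac > 100))
    warning("fetal fraction above 100% for ", sum(frac > 100), " sample(s)")
  structure(list(placental_genes = placental, reference_genes = reference,
                 fraction_percent = frac,
                 flagged = names(frac)[frac > 100]),
            class = "fetal_fraction_result")
}

#' @export
print.fetal_fraction_result <- function(x, ...) {
  cat(sprintf("fetal fraction: %d samples, median %.2f%% (%d placental / %d reference genes)\n",
              length(x$fraction_percent), stats::median(x$fraction_percent),
              length(x$placental_genes), length(x$reference_genes)))
  invisible(x)
}

#' Full fetal-fraction estimation from counts and metadata
#'
#' Convenience wrapper chaining RPKM computation, placental-gene selection
#' (pregnant vs non-pregnant differential expression on log-CPM at
#' `fdr_lt`), reference-gene selection, and the RPKM-ratio estimate.
#'
#' @inheritParams compute_rpkm
#' @param meta sample metadata.
#' @param fdr_lt FDR cutoff for placental genes.
#' @param placental_logfc_gt logFC bound for the placental panel (default
#'   2, the strongly upregulated tier; see [select_placental_genes()]).
#' @param placental_max_control_mean control-group abundance ceiling,
#'   log2(CPM+1) (default 6, i.e. about 60 CPM in non-pregnant plasma).
#' @param ... passed to [select_reference_genes()].
#' @export
fetal_fraction_pipeline <- function(cm, meta, fdr_lt = 0.05,
                                    placental_logfc_gt = 2,
                                    placental_max_control_mean = 6,
                                    library_sizes = NULL, ...) {
  meta <- meta[match(colnames(cm$counts), meta$sample_id), ]
  lib <- library_sizes %||% meta$library_size %||% colSums(cm$counts)
  rpkm <- compute_rpkm(cm, lib)
  grp <- ifelse(meta$group == "non_pregnant", "non_pregnant", "pregnant")
  dge <- run_dge(log_cpm(cm$counts, lib), grp,
                 contrast = c("pregnant", "non_pregnant"))
  placental <- select_placental_genes(dge, fdr_lt, placental_logfc_gt,
                                      placental_max_control_mean)
  reference <- setdiff(select_reference_genes(rpkm, meta, ...), placental)
  estimate_fetal_fraction(rpkm, placental, reference)
}
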