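#' Pipeline configuration
#'
#' Collects paths (or an in-memory synthetic cohort spec), the QC
#' thresholds, the confounder list and the PSO settings for a full run.
#' Defaults equal the analysis' stated thresholds: 120 reads / 90% of
#' samples for gene abundance, 1 million unique reads and 100,000 fetal
#' reads per sample, 750 detected genes, cross-correlation 0.5, FDR 0.05.
#'
#' @param counts_path,gtf_path,meta_path input files (ignored when
#'   `spec` is given).
#' @param spec optional [cohort_spec()]: generate the cohort instead of
#'   reading files.
#' @param out_dir output directory; `NULL` disables file output.
#' @param min_reads,frac_samples gene abundance filter thresholds.
#' @param min_unique_reads,min_fetal_reads,min_genes_detected sample QC
#'   thresholds.
#' @param corr_threshold cross-correlation threshold for stable genes and
#'   factor acceptance.
#' @param fdr marker significance cutoff.
#' @param confounders corrected covariates (the five stated ones).
#' @param k_max maximum unwanted-variation factors.
#' @param pso list of PSO settings (`bounds`, `swarm_size`, `iterations`).
#' @param run_add_one_in evaluate affected samples by add-one-in when
#'   present.
#' @param seed integer seed recorded in every output and used for the PSO.
#' @export
pipeline_config <- function(counts_path = NULL, gtf_path = NULL,
                            meta_path = NULL, spec = NULL, out_dir = NULL,
                            min_reads = 120, frac_samples = 0.90,
                            min_unique_reads = 1e6, min_fetal_reads = 1e5,
                            min_genes_detected = 750, corr_threshold = 0.5,
                            fdr = 0.05,
                            confounders = c("maternal_age", "library_size",
                                            "gestational_age",
                                            "fetal_fraction", "purification"),
                            k_max = 5,
                            pso = list(bounds = c(1e-4, 0.2),
                                       swarm_size = 20, iterations = 30),
                            run_add_one_in = TRUE, seed = 1L) {
  thr <- c(min_reads = min_reads, frac_samples = frac_samples,
           min_unique_reads = min_unique_reads,
           min_fetal_reads = min_fetal_reads,
           min_genes_detected = min_genes_detected,
           corr_threshold = corr_threshold, fdr = fdr)
  if (any(thr <= 0)) stop("all thresholds must be positive")
  if (is.null(spec) && (is.null(counts_path) || is.null(gtf_path) ||
                        is.null(meta_path)))
    stop("either a cohort spec or counts/gtf/meta paths are required")
  structure(list(counts_path = counts_path, gtf_path = gtf_path,
                 meta_path = meta_path, spec = spec, out_dir = out_dir,
                 thresholds = as.list(thr), confounders = confounders,
                 k_max = k_max, pso = pso, run_add_one_in = run_add_one_in,
                 seed = as.integer(seed)), class = "cf_pipeline_config")
}

#' Run the full cfRNA screening analysis
#'
#' Stages, in order: load or generate the cohort; low-abundance gene
#' filter; fetal-fraction estimation (RPKM ratios with data-driven
#' placental and reference gene sets); sample QC filter; stable-gene
#' panel and unwanted-variation correction protecting the
#' pregnant/non-pregnant contrast; multi-group differential expression
#' with BH-FDR; tiered pregnancy markers; PSO-optimised hierarchical
#' clustering; and, when affected samples are present, the add-one-in
#' classification. When `out_dir` is set every stage output is written
#' (TSV/CSV/JSON) and hashed into a manifest, so a rerun with the same
#' config and seed reproduces identical hashes.
#'
#' @param config [pipeline_config()].
#' @return list of stage results (class `cf_pipeline_result`), invisibly
#'   when writing to disk.
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  thr <- config$thresholds
  res <- list(seed = config$seed, thresholds = thr)

  if (!is.null(config$spec)) {
    cohort <- stage("synth", generate_cohort(config$spec))
    cm <- cohort$counts; meta <- cohort$meta
    res$truth <- cohort$truth
  } else {
    cm <- stage("read_counts", read_counts(config$counts_path, config$gtf_path))
    meta <- stage("read_meta", read_sample_meta(config$meta_path))
  }
  meta <- meta[match(colnames(cm$counts), meta$sample_id), ]
  if (is.null(meta$library_size)) meta$library_size <- colSums(cm$counts)

  fl <- stage("filter_low_abundance",
              filter_low_abundance(cm, thr$min_reads, thr$frac_samples))
  res$gene_filter <- fl$report

  ff <- stage("fetal_fraction",
              fetal_fraction_pipeline(fl$counts, meta, fdr_lt = thr$fdr,
                                      library_sizes = meta$library_size))
  res$fetal_fraction <- ff
  meta$fetal_fraction <- ff$fraction_percent[meta$sample_id]

  fs <- stage("filter_samples",
              filter_samples(fl$counts, meta, ff,
                             thr$min_unique_reads, thr$min_fetal_reads,
                             thr$min_genes_detected))
  res$sample_filter <- fs$report
  cmf <- fs$counts; meta <- fs$meta

  logmat <- log_cpm(cmf$counts, meta$library_size)
  groups2 <- ifelse(meta$group == "non_pregnant", "non_pregnant",
                    "normal_pregnant")
  is_ref <- meta$group != "affected"

  panel <- stage("stable_panel",
                 select_stable_genes(logmat[, is_ref, drop = FALSE],
                                     meta[is_ref, ],
                                     confounders = intersect(config$confounders,
                                                             names(meta)),
                                     corr_threshold = thr$corr_threshold))
  res$stable_panel <- panel

  corr <- stage("correction",
                remove_unwanted_variation(
                  logmat[, is_ref, drop = FALSE], panel,
                  groups = groups2[is_ref], meta = meta[is_ref, ],
                  confounders = intersect(config$confounders, names(meta)),
                  k_max = config$k_max, corr_threshold = thr$corr_threshold))
  res$correction <- corr

  dge <- stage("dge", run_dge(corr$mat, groups2[is_ref],
                              contrast = c("normal_pregnant", "non_pregnant")))
  res$dge <- dge
  ctrl_ids <- meta$sample_id[is_ref & groups2 == "non_pregnant"]
  res$markers <- stage("markers",
                       pregnancy_markers(dge, detection_rate(cmf, ctrl_ids),
                                         fdr_lt = thr$fdr))

  res$clustering <- stage("pso_cluster",
                          optimize_fdr_threshold(
                            corr$mat, dge, groups2[is_ref],
                            bounds = config$pso$bounds,
                            swarm_size = config$pso$swarm_size,
                            iterations = config$pso$iterations,
                            seed = config$seed))

  if (config$run_add_one_in && any(meta$group == "affected")) {
    res$add_one_in <- stage("add_one_in",
      add_one_in(logmat, meta,
                 config = add_one_in_config(
                   confounders = intersect(config$confounders, names(meta)),
                   corr_threshold = thr$corr_threshold,
                   k_max = config$k_max, fdr_bounds = config$pso$bounds,
                   seed = config$seed)))
  } else if (config$run_add_one_in) {
    res$skipped_add_one_in <- "no affected samples; add-one-in stage skipped"
  }

  class(res) <- "cf_pipeline_result"
  if (!is.null(config$out_dir)) {
    write_pipeline_outputs(res, meta, cmf, config)
    return(invisible(res))
  }
  res
}

write_pipeline_outputs <- function(res, meta, cmf, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  utils::write.table(
    data.frame(gene_id = rownames(cmf$counts), cmf$counts, check.names = FALSE),
    p("filtered_counts.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(meta, p("sample_meta_filtered.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(sample_id = names(res$fetal_fraction$fraction_percent),
               fraction_percent = res$fetal_fraction$fraction_percent,
               n_placental = length(res$fetal_fraction$placental_genes),
               n_reference = length(res$fetal_fraction$reference_genes)),
    p("fetal_fractions.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(res$dge), p("dge.csv"), row.names = FALSE)
  utils::write.csv(res$markers, p("markers.csv"), row.names = FALSE)
  summary <- list(
    seed = res$seed, thresholds = res$thresholds,
    genes_removed = res$gene_filter$n_removed,
    genes_kept = res$gene_filter$n_kept,
    samples_removed = res$sample_filter$n_removed,
    pct_samples_removed = res$sample_filter$pct_removed,
    median_fetal_fraction =
      stats::median(res$fetal_fraction$fraction_percent[
        meta$sample_id[meta$group != "non_pregnant"]], na.rm = TRUE),
    k_unwanted_factors = res$correction$k,
    stable_panel_size = length(res$stable_panel$genes),
    n_markers = nrow(res$markers),
    fdr_threshold = res$clustering$threshold,
    separation_score = res$clustering$clustering$score)
  if (!is.null(res$add_one_in)) {
    summary$n_qualified <- sum(res$add_one_in$report$qualified)
  }
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- list.files(config$out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- as.list(tools::md5sum(files))
  names(manifest) <- basename(files)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(NULL)
}
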