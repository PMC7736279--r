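#' Low-abundance gene filter
#'
#' Removes a gene if and only if its count is below `min_reads` in strictly
#' more than `frac_samples` of the samples (default: fewer than 120 reads
#' in more than 90% of samples).
#'
#' @param cm [cf_counts].
#' @param min_reads read threshold (default 120).
#' @param frac_samples sample-proportion threshold (default 0.90, strict).
#' @return list with `counts` (filtered [cf_counts]) and `report`
#'   (a `cf_filter_report`).
#' @export
filter_low_abundance <- function(cm, min_reads = 120, frac_samples = 0.90) {
  if (!inherits(cm, "cf_counts")) stop("cm must be a cf_counts object")
  if (nrow(cm$counts) == 0 || ncol(cm$counts) == 0)
    stop("empty count matrix")
  if (min_reads < 0 || frac_samples < 0 || frac_samples > 1)
    stop("thresholds out of range")
  prop_low <- rowMeans(cm$counts < min_reads)
  drop <- prop_low > frac_samples
  report <- filter_report(
    unit = "gene",
    kept = rownames(cm$counts)[!drop],
    removed = rownames(cm$counts)[drop],
    reason = ifelse(drop[drop], "low_abundance", character(0)),
    thresholds = list(min_reads = min_reads, frac_samples = frac_samples))
  list(counts = subset_counts(cm, genes = !drop), report = report)
}

#' Sample-level QC filter
#'
#' Excludes a pregnant sample when any of: uniquely-assigned reads below
#' `min_unique_reads` (1 million); fetal reads (fetal fraction x unique
#' reads) at or below `min_fetal_reads` (100,000); or fewer than
#' `min_genes_detected` genes with a nonzero count (750). Non-pregnant
#' samples are exempt from the fetal-read rule.
#'
#' @param cm [cf_counts].
#' @param meta sample metadata with `sample_id`, `group`, `library_size`.
#' @param ff [fetal_fraction_result] or a named vector of per-sample fetal
#'   fractions in percent (required for pregnant samples).
#' @param min_unique_reads minimum uniquely-assigned reads (default 1e6).
#' @param min_fetal_reads exclusion bound on fetal reads: excluded when
#'   fetal reads are `<=` this value (default 1e5).
#' @param min_genes_detected minimum genes with count > 0 (default 750).
#' @return list with `counts`, `meta` (both filtered) and `report`.
#' @export
filter_samples <- function(cm, meta, ff, min_unique_reads = 1e6,
                           min_fetal_reads = 1e5, min_genes_detected = 750) {
  if (!inherits(cm, "cf_counts")) stop("cm must be a cf_counts object")
  sids <- colnames(cm$counts)
  meta <- meta[match(sids, meta$sample_id), ]
  if (anyNA(meta$sample_id)) stop("metadata missing for some samples")
  frac <- if (inherits(ff, "fetal_fraction_result")) ff$fraction_percent else ff
  frac <- frac[sids]
  pregnant <- meta$group != "non_pregnant"
  if (any(pregnant & is.na(frac)))
    stop("missing fetal fraction for pregnant sample(s): ",
         paste(utils::head(sids[pregnant & is.na(frac)], 5), collapse = ", "))

  unique_reads <- meta$library_size
  fetal_reads <- frac / 100 * unique_reads
  detected <- colSums(cm$counts > 0)

  low_reads <- unique_reads < min_unique_reads
  low_fetal <- pregnant & fetal_reads <= min_fetal_reads
  low_genes <- detected < min_genes_detected
  drop <- low_reads | low_fetal | low_genes
  reason <- ifelse(low_reads, "unique_reads",
                   ifelse(low_fetal, "fetal_reads", "genes_detected"))[drop]

  report <- filter_report(
    unit = "sample", kept = sids[!drop], removed = sids[drop], reason = reason,
    thresholds = list(min_unique_reads = min_unique_reads,
                      min_fetal_reads = min_fetal_reads,
                      min_genes_detected = min_genes_detected),
    extra = list(median_genes_detected = stats::median(detected)))
  list(counts = subset_counts(cm, samples = !drop),
       meta = meta[!drop, , drop = FALSE], report = report)
}

# Internal constructor; checks the kept/removed partition.
filter_report <- function(unit, kept, removed, reason, thresholds,
                          extra = list()) {
  total <- length(kept) + length(removed)
  if (anyDuplicated(c(kept, removed)))
    stop("filter report does not partition the input")
  structure(list(
    unit = unit, n_in = total, n_kept = length(kept),
    n_removed = length(removed),
    pct_removed = if (total > 0) pct(length(removed), total) else NA_real_,
    kept = kept,
    removed = if (length(removed))
      data.frame(id = removed, reason = reason, stringsAsFactors = FALSE)
    else data.frame(id = character(), reason = character()),
    thresholds = thresholds, extra = extra), class = "cf_filter_report")
}

#' @export
print.cf_filter_report <- function(x, ...) {
  cat(sprintf("%s filter: %d in, %d kept, %d removed (%s%%)\n",
              x$unit, x$n_in, x$n_kept, x$n_removed, x$pct_removed))
  invisible(x)
}
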