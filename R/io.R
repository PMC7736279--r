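#' Gene-level count container for plasma cfRNA data
#'
#' Thin container pairing a genes x samples integer fragment-count matrix
#' with per-gene annotation (chromosome, merged-exon length). Counts are
#' expected to be uniquely-assigned fragment counts summarised at the gene
#' (meta-feature) level, i.e. all isoforms of a gene pooled.
#'
#' @param counts integer matrix, genes x samples, with rownames (gene ids)
#'   and colnames (sample ids).
#' @param genes data.frame with columns `gene_id`, `chrom`, `length_bp`
#'   (merged-exon length in bp), one row per row of `counts`.
#' @return object of class `cf_counts`: list with elements `counts`, `genes`.
#' @export
cf_counts <- function(counts, genes) {
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    stop("counts must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integral")
  req <- c("gene_id", "chrom", "length_bp")
  if (!all(req %in% names(genes)))
    stop("genes must have columns: ", paste(req, collapse = ", "))
  if (!identical(as.character(genes$gene_id),
                 as.character(rownames(counts) %||% character())))
    stop("genes$gene_id must match rownames(counts) in order")
  if (any(genes$length_bp <= 0)) stop("gene lengths must be positive")
  structure(list(counts = counts, genes = genes), class = "cf_counts")
}

#' @export
dim.cf_counts <- function(x) dim(x$counts)

#' @export
print.cf_counts <- function(x, ...) {
  cat(sprintf("cf_counts: %d genes x %d samples\n", nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

# Subset a cf_counts by gene and/or sample index/names.
subset_counts <- function(cm, genes = NULL, samples = NULL) {
  counts <- cm$counts
  ginfo <- cm$genes
  if (!is.null(genes)) {
    counts <- counts[genes, , drop = FALSE]
    ginfo <- ginfo[match(rownames(counts), ginfo$gene_id), , drop = FALSE]
  }
  if (!is.null(samples)) counts <- counts[, samples, drop = FALSE]
  cf_counts(counts, ginfo)
}

#' Merged-exon gene lengths from a GTF gene model
#'
#' Computes, for every gene, the total length of the union of its annotated
#' exon intervals (all isoforms merged), the standard gene-level length used
#' for RPKM. GTF coordinates are 1-based inclusive; the union is computed on
#' that convention via interval reduction.
#'
#' @param gtf_path path to a standard 9-column GTF file.
#' @return data.frame with `gene_id`, `chrom`, `length_bp`, `n_exons`.
#' @export
gene_lengths_from_gtf <- function(gtf_path) {
  if (!file.exists(gtf_path)) stop("GTF file not found: ", gtf_path)
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) stop("no exon features in GTF: ", gtf_path)
  by_gene <- S4Vectors::split(gr, gr$gene_id)
  merged <- GenomicRanges::reduce(by_gene)
  len <- sum(GenomicRanges::width(merged))
  nex <- S4Vectors::elementNROWS(merged)
  chrom <- vapply(S4Vectors::split(as.character(GenomicRanges::seqnames(gr)), gr$gene_id),
                  function(x) x[[1]], character(1))
  data.frame(gene_id = names(len), chrom = chrom[names(len)],
             length_bp = as.integer(len), n_exons = as.integer(nex),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a gene-level count table plus GTF gene model
#'
#' Reads a featureCounts/VERSE-style tab-separated table (first column gene
#' id, one column per sample) and annotates genes with merged-exon lengths
#' from the GTF. Genes on excluded chromosomes (default chrM) or in excluded
#' clusters are dropped; genes absent from the GTF are dropped with a
#' warning listing them.
#'
#' @param path counts TSV path.
#' @param gtf_path GTF path for gene lengths.
#' @param exclude_chroms chromosomes to drop (default `"chrM"`).
#' @param exclude_genes gene ids (e.g. a problematic cluster) to drop.
#' @return `cf_counts`.
#' @export
read_counts <- function(path, gtf_path, exclude_chroms = "chrM",
                        exclude_genes = character()) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  tab <- tryCatch(
    utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("malformed counts table '", path, "': ",
                             conditionMessage(e)))
  if (ncol(tab) < 2) stop("counts table needs a gene column plus >= 1 sample")
  bad <- which(!vapply(tab[-1], is.numeric, logical(1)))
  if (length(bad))
    stop("non-numeric count column(s): ", paste(names(tab[-1])[bad], collapse = ", "))
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- as.character(tab[[1]])
  storage.mode(mat) <- "integer"

  ann <- gene_lengths_from_gtf(gtf_path)
  missing <- setdiff(rownames(mat), ann$gene_id)
  if (length(missing)) {
    warning(length(missing), " gene(s) in counts absent from GTF, excluded: ",
            paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ...")
    mat <- mat[setdiff(rownames(mat), missing), , drop = FALSE]
  }
  ann <- ann[match(rownames(mat), ann$gene_id), ]
  drop <- ann$chrom %in% exclude_chroms | ann$gene_id %in% exclude_genes
  mat <- mat[!drop, , drop = FALSE]
  ann <- ann[!drop, , drop = FALSE]
  cf_counts(mat, ann[, c("gene_id", "chrom", "length_bp")])
}

#' Read a sample metadata table
#'
#' @param path CSV with at least `sample_id` and `group` columns; `group`
#'   levels are `normal_pregnant`, `non_pregnant`, `affected`.
#' @return data.frame.
#' @export
read_sample_meta <- function(path) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(meta)))
    stop("metadata must have sample_id and group columns")
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample ids in metadata")
  meta
}

#' Write a cohort to plain-text files
#'
#' Writes the count matrix as TSV (gene_id + one column per sample), the
#' metadata and ground truth as CSV, and a minimal exon-per-gene GTF
#' carrying the merged-exon lengths.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cm <- cohort$counts
  paths <- c(counts = file.path(dir, "counts.tsv"),
             meta = file.path(dir, "sample_meta.csv"),
             truth_samples = file.path(dir, "truth_samples.csv"),
             truth_genes = file.path(dir, "truth_genes.csv"),
             gtf = file.path(dir, "genes.gtf"))
  tab <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                    check.names = FALSE)
  utils::write.table(tab, paths["counts"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(cohort$meta, paths["meta"], row.names = FALSE)
  utils::write.csv(cohort$truth$samples, paths["truth_samples"], row.names = FALSE)
  utils::write.csv(cohort$truth$genes, paths["truth_genes"], row.names = FALSE)
  g <- cm$genes
  gtf <- sprintf(
    '%s\tsynthetic\texon\t1\t%d\t.\t+\t.\tgene_id "%s"; transcript_id "%s.1";',
    g$chrom, g$length_bp, g$gene_id, g$gene_id)
  writeLines(gtf, paths["gtf"])
  invisible(paths)
}
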