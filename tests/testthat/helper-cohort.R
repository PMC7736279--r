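# Shared fixture builders. All cohorts are generated in code at test time;
# sizes are scaled down from the default spec to keep tests fast.

small_spec <- function(seed = 1, ...) {
  args <- list(seed = seed, n_normal = 30, n_nonpregnant = 10,
               n_genes = 400, n_reference_like = 60)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(cohort_spec, args)
}

# cohort + abundance-filtered counts + metadata with estimated fetal fraction
prepared_cohort <- function(spec) {
  co <- generate_cohort(spec)
  fl <- filter_low_abundance(co$counts)
  meta <- co$meta
  ff <- suppressWarnings(fetal_fraction_pipeline(fl$counts, meta))
  meta$fetal_fraction <- ff$fraction_percent[meta$sample_id]
  list(cohort = co, counts = fl$counts, meta = meta, ff = ff,
       logmat = log_cpm(fl$counts$counts, meta$library_size))
}

# hand-built cf_counts from a plain matrix
toy_counts <- function(mat, lengths = NULL, chrom = NULL) {
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("g%03d", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("s%03d", seq_len(ncol(mat)))
  cf_counts(mat, data.frame(
    gene_id = rownames(mat),
    chrom = chrom %||% rep("chr1", nrow(mat)),
    length_bp = lengths %||% rep(1000L, nrow(mat)),
    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# five-gene GTF with overlapping isoforms, used for merged-length tests
write_toy_gtf <- function(path) {
  lines <- c(
    # gA: [100,200] and [150,300] overlap -> union 201 bases (1-based incl.)
    'chr1\ttest\texon\t100\t200\t.\t+\t.\tgene_id "gA"; transcript_id "gA.1";',
    'chr1\ttest\texon\t150\t300\t.\t+\t.\tgene_id "gA"; transcript_id "gA.2";',
    # gB: two disjoint 100-base exons -> 200
    'chr1\ttest\texon\t1000\t1099\t.\t+\t.\tgene_id "gB"; transcript_id "gB.1";',
    'chr1\ttest\texon\t2000\t2099\t.\t+\t.\tgene_id "gB"; transcript_id "gB.1";',
    # gC: nested exons -> outer wins
    'chr2\ttest\texon\t500\t1500\t.\t-\t.\tgene_id "gC"; transcript_id "gC.1";',
    'chr2\ttest\texon\t700\t900\t.\t-\t.\tgene_id "gC"; transcript_id "gC.2";',
    # gD: three staggered isoforms
    'chr2\ttest\texon\t100\t250\t.\t+\t.\tgene_id "gD"; transcript_id "gD.1";',
    'chr2\ttest\texon\t200\t400\t.\t+\t.\tgene_id "gD"; transcript_id "gD.2";',
    'chr2\ttest\texon\t380\t420\t.\t+\t.\tgene_id "gD"; transcript_id "gD.3";',
    # gE: single exon on chrM (excluded by default in read_counts)
    'chrM\ttest\texon\t1\t500\t.\t+\t.\tgene_id "gE"; transcript_id "gE.1";')
  writeLines(lines, path)
  path
}

# brute-force merged exon length: per-base boolean mask over 1-based
# inclusive GTF coordinates
brute_force_gtf_lengths <- function(path) {
  fields <- read.delim(path, header = FALSE, quote = "", stringsAsFactors = FALSE)
  gid <- sub('.*gene_id "([^"]+)".*', "\\1", fields$V9)
  out <- sapply(split(seq_len(nrow(fields)), gid), function(idx) {
    mx <- max(fields$V5[idx])
    mask <- logical(mx)
    for (i in idx) mask[fields$V4[i]:fields$V5[i]] <- TRUE
    sum(mask)
  })
  out[order(names(out))]
}
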