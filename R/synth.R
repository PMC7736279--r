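#' Specification of a synthetic plasma cfRNA cohort
#'
#' Defines the generative conditions for [generate_cohort()]: a maternal
#' baseline transcriptome with a placental gene signature mixed in at a
#' known per-sample fetal fraction (~5-11% in pregnancy, ~0.4% residual
#' background in non-pregnant controls), gestational-age / maternal-age /
#' purification-batch confounding on designated gene subsets, an
#' XIST-like chrX marker tracking female fetuses, silent chrY genes, and
#' optional directional perturbations carried by affected samples.
#'
#' Counts are negative binomial with a shared dispersion; genes outside the
#' stable reference panel additionally carry per-sample biological
#' log-normal variability, which is what makes the reference-gene selection
#' criteria (CV-based) informative.
#'
#' @param n_normal,n_nonpregnant,n_affected cohort sizes; defaults mirror a
#'   first-trimester screening cohort of 108 normal pregnancies, 19
#'   non-pregnant controls and no affected samples.
#' @param n_genes total genes simulated (scaled-down transcriptome).
#' @param n_placental placenta-exclusive signature genes (strong pregnancy
#'   markers, used for fetal-fraction estimation).
#' @param n_reference_like stably expressed housekeeping-like genes
#'   (low dispersion, no confounder effects) forming the designed
#'   reference panel.
#' @param n_pregnancy_medium maternal genes moderately upregulated in
#'   pregnancy (designed log2 fold change drawn from `medium_log2fc`).
#' @param medium_log2fc range of designed log2 effects for medium markers.
#' @param fetal_fraction_range true fetal fraction range in percent,
#'   sampled uniformly per pregnant sample.
#' @param nonpregnant_background_fraction residual placental background in
#'   non-pregnant controls, percent.
#' @param dispersion shared negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param biological_sd natural-log SD of per-sample biological
#'   variability on non-reference genes.
#' @param placental_biological_sd natural-log SD of residual gene-level
#'   variability on placental genes (their main variation is the shared
#'   fetal-fraction signal).
#' @param library_size_range uniquely-assigned fragment totals, sampled
#'   uniformly.
#' @param covariate_effects list with elements `gestational_age`,
#'   `maternal_age`, `purification`, each `list(frac_genes=, effect_sd=)`:
#'   the fraction of genes carrying that confounder and the SD (log2 per
#'   standardised covariate unit) of per-gene effects.
#' @param affected_perturbations list of [perturbation()] entries defining
#'   affected subgroups; affected samples are assigned to entries
#'   round-robin. Empty list with `n_affected > 0` yields null affected
#'   samples (drawn from the normal model).
#' @param female_fetus_marker simulate an XIST-like chrX gene upregulated
#'   with the fetal fraction in female-fetus pregnancies.
#' @param sex_marker_log2fc designed female-vs-male log2 fold change of
#'   that marker at the midpoint fetal fraction.
#' @param n_chry chrY genes kept at zero (below detection in plasma).
#' @param seed integer RNG seed; fixed seed gives bit-identical cohorts.
#' @return object of class `cohort_spec` (a validated list).
#' @export
cohort_spec <- function(n_normal = 108, n_nonpregnant = 19, n_affected = 0,
                        n_genes = 2000, n_placental = 25,
                        n_reference_like = 150, n_pregnancy_medium = 15,
                        medium_log2fc = c(1.3, 1.7),
                        fetal_fraction_range = c(5, 11),
                        nonpregnant_background_fraction = 0.38,
                        dispersion = 0.03,
                        biological_sd = 0.35,
                        placental_biological_sd = 0.1,
                        library_size_range = c(2e6, 6e6),
                        covariate_effects = list(
                          gestational_age = list(frac_genes = 0.15, effect_sd = 0.5),
                          maternal_age = list(frac_genes = 0.05, effect_sd = 0.15),
                          purification = list(frac_genes = 0.30, effect_sd = 0.5)),
                        affected_perturbations = list(),
                        female_fetus_marker = TRUE,
                        sex_marker_log2fc = 2.3,
                        n_chry = 10,
                        seed = 1L) {
  spec <- list(n_normal = n_normal, n_nonpregnant = n_nonpregnant,
               n_affected = n_affected, n_genes = n_genes,
               n_placental = n_placental, n_reference_like = n_reference_like,
               n_pregnancy_medium = n_pregnancy_medium,
               medium_log2fc = medium_log2fc,
               fetal_fraction_range = fetal_fraction_range,
               nonpregnant_background_fraction = nonpregnant_background_fraction,
               dispersion = dispersion, biological_sd = biological_sd,
               placental_biological_sd = placental_biological_sd,
               library_size_range = library_size_range,
               covariate_effects = covariate_effects,
               affected_perturbations = affected_perturbations,
               female_fetus_marker = female_fetus_marker,
               sex_marker_log2fc = sex_marker_log2fc,
               n_chry = n_chry, seed = as.integer(seed))
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  chk_count <- function(field) {
    v <- spec[[field]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v != round(v))
      stop("invalid field '", field, "': must be a non-negative count")
  }
  for (f in c("n_normal", "n_nonpregnant", "n_affected", "n_genes",
              "n_placental", "n_reference_like", "n_pregnancy_medium",
              "n_chry"))
    chk_count(f)
  chk_range <- function(field) {
    v <- spec[[field]]
    if (!is.numeric(v) || length(v) != 2 || v[1] > v[2])
      stop("invalid field '", field, "': must be (lo, hi) with lo <= hi")
  }
  for (f in c("fetal_fraction_range", "library_size_range", "medium_log2fc"))
    chk_range(f)
  if (any(spec$fetal_fraction_range < 0) || any(spec$fetal_fraction_range > 100))
    stop("invalid field 'fetal_fraction_range': must lie within [0, 100]")
  if (spec$nonpregnant_background_fraction < 0 ||
      spec$nonpregnant_background_fraction > 100)
    stop("invalid field 'nonpregnant_background_fraction': percent in [0, 100]")
  if (spec$dispersion < 0) stop("invalid field 'dispersion': must be >= 0")
  if (spec$biological_sd < 0 || spec$placental_biological_sd < 0)
    stop("invalid field 'biological_sd': must be >= 0")
  if (any(spec$library_size_range <= 0))
    stop("invalid field 'library_size_range': must be positive")
  n_conf <- sum(vapply(spec$covariate_effects, function(e) e$frac_genes,
                       numeric(1)))
  reserved <- spec$n_placental + spec$n_reference_like +
    spec$n_pregnancy_medium + spec$n_chry + 1
  if (reserved + ceiling(n_conf * spec$n_genes) > spec$n_genes)
    stop("invalid field 'n_genes': too small for the designated gene classes")
  for (p in spec$affected_perturbations) {
    if (is.null(p$label) || is.null(p$n_genes) || is.null(p$log2fc))
      stop("invalid field 'affected_perturbations': entries need label, n_genes, log2fc")
  }
  invisible(spec)
}

#' Define an affected-subgroup perturbation
#'
#' @param label subgroup label recorded in metadata and ground truth.
#' @param n_genes number of (well-expressed maternal) genes perturbed.
#' @param log2fc log2 effect size(s), recycled over the perturbed genes;
#'   e.g. `c(2, -2)` alternates up/down regulation.
#' @export
perturbation <- function(label, n_genes = 30, log2fc = c(2, -2)) {
  list(label = label, n_genes = n_genes, log2fc = log2fc)
}

#' Generate a synthetic plasma cfRNA cohort with known ground truth
#'
#' Simulates gene-level fragment counts under a maternal/placental mixture
#' model. For pregnant sample s with true fetal fraction f_s, the relative
#' expression density of gene g is
#' `x_gs = m_g * c_gs + f_s * p_g (+ perturbations)`,
#' where m is the maternal baseline, p the placental signature (zero off the
#' signature genes) and c_gs collects confounder and biological multipliers;
#' counts are NB(mu = library_size * x_s / sum(x_s), dispersion). The
#' placental signature is scaled so that the RPKM-ratio fetal-fraction
#' estimator is unbiased at the designed reference panel, making the
#' generator a parameter-recovery oracle for the estimation pipeline.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `cf_cohort`: `counts` ([cf_counts]), `meta`
#'   (sample metadata data.frame), `truth` (list with `samples`, `genes`,
#'   `perturbations` data.frames).
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  with_local_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  n_genes <- spec$n_genes
  has_sex_marker <- isTRUE(spec$female_fetus_marker) && spec$n_placental > 0

  ## --- genes ------------------------------------------------------------
  gene_id <- sprintf("gene%05d", seq_len(n_genes))
  length_bp <- pmax(200L, as.integer(round(exp(stats::rnorm(n_genes, log(2000), 0.6)))))
  chrom <- sample(paste0("chr", c(1:22, "X")), n_genes, replace = TRUE)

  class <- rep("maternal", n_genes)
  idx <- seq_len(n_genes)
  take <- function(n) {
    pool <- idx[class == "maternal"]
    s <- if (n > 0) sample(pool, n) else integer()
    s
  }
  i_pl <- take(spec$n_placental); class[i_pl] <- "placental"
  i_ref <- take(spec$n_reference_like); class[i_ref] <- "reference"
  i_y <- take(spec$n_chry); class[i_y] <- "chrY"
  chrom[i_y] <- "chrY"
  i_sex <- integer()
  if (has_sex_marker) {
    i_sex <- take(1); class[i_sex] <- "sex_marker"; chrom[i_sex] <- "chrX"
  }

  ## maternal baseline densities
  m <- exp(stats::rnorm(n_genes, 0, 1.2))
  m[i_ref] <- exp(stats::rnorm(length(i_ref), log(2), 0.7))
  m[i_pl] <- 0
  m[i_y] <- 0
  if (has_sex_marker) m[i_sex] <- exp(stats::rnorm(1, log(1.5), 0.3))

  ## medium pregnancy markers: well-expressed maternal genes up in pregnancy
  pool <- idx[class == "maternal" & m >= stats::median(m[class == "maternal"])]
  i_med <- if (spec$n_pregnancy_medium > 0) sample(pool, spec$n_pregnancy_medium) else integer()
  pregnancy_log2fc <- rep(0, n_genes)
  pregnancy_log2fc[i_med] <- stats::runif(length(i_med), spec$medium_log2fc[1],
                                          spec$medium_log2fc[2])

  ## placental signature, calibrated so the RPKM-ratio estimator is unbiased:
  ## mean(p/L over placental genes) == mean(m/L over designed reference genes)
  p <- rep(0, n_genes)
  if (spec$n_placental > 0) {
    raw <- exp(stats::rnorm(length(i_pl), 0, 0.5))
    if (length(i_ref) == 0)
      stop("invalid field 'n_reference_like': must be > 0 when n_placental > 0")
    target <- mean(m[i_ref] / length_bp[i_ref])
    p[i_pl] <- raw * target / mean(raw / length_bp[i_pl])
  }
  f_mid <- mean(spec$fetal_fraction_range) / 100
  sex_p <- 0
  if (has_sex_marker && f_mid > 0) {
    sex_p <- (2^spec$sex_marker_log2fc - 1) * m[i_sex] / f_mid
  }

  ## confounder-driven genes (disjoint subsets of the maternal pool)
  eff <- spec$covariate_effects
  slope <- list()
  for (cv in c("gestational_age", "maternal_age", "purification")) {
    sl <- rep(0, n_genes)
    e <- eff[[cv]]
    if (!is.null(e) && e$frac_genes > 0) {
      n_cv <- round(e$frac_genes * n_genes)
      i_cv <- sample(idx[class == "maternal" & slopes_free(slope, idx)], n_cv)
      sl[i_cv] <- stats::rnorm(n_cv, 0, e$effect_sd)
    }
    slope[[cv]] <- sl
  }

  ## affected perturbation genes: well-expressed, unreserved maternal genes
  pert <- list()
  used <- integer()
  for (p_def in spec$affected_perturbations) {
    pool <- setdiff(idx[class == "maternal" &
                          m >= stats::median(m[class == "maternal"])],
                    c(i_med, used))
    if (length(pool) < p_def$n_genes)
      stop("invalid field 'affected_perturbations': not enough free genes")
    g <- sample(pool, p_def$n_genes)
    used <- c(used, g)
    pert[[p_def$label]] <- data.frame(
      label = p_def$label, gene_id = gene_id[g],
      gene_idx = g, log2fc = rep_len(p_def$log2fc, p_def$n_genes),
      stringsAsFactors = FALSE)
  }
  perturbations <- if (length(pert)) do.call(rbind, c(pert, make.row.names = FALSE))
                   else data.frame(label = character(), gene_id = character(),
                                   gene_idx = integer(), log2fc = numeric())

  ## --- samples ----------------------------------------------------------
  n_total <- spec$n_normal + spec$n_nonpregnant + spec$n_affected
  if (n_total == 0) stop("invalid field 'n_normal': cohort has no samples")
  group <- rep(c("normal_pregnant", "non_pregnant", "affected"),
               c(spec$n_normal, spec$n_nonpregnant, spec$n_affected))
  sample_id <- sprintf("S%04d", seq_len(n_total))
  pregnant <- group != "non_pregnant"

  ga <- ifelse(pregnant, round(stats::runif(n_total, 63, 97)), NA_real_)
  age <- round(ifelse(pregnant, stats::rnorm(n_total, 35, 3.5),
                      stats::rnorm(n_total, 29, 4)), 1)
  batch <- sample(c("batch1", "batch2"), n_total, replace = TRUE)
  lib_target <- round(stats::runif(n_total, spec$library_size_range[1],
                                   spec$library_size_range[2]))
  fetal_sex <- ifelse(pregnant, sample(c("female", "male"), n_total, replace = TRUE),
                      NA_character_)
  ff <- numeric(n_total)
  ff[pregnant] <- stats::runif(sum(pregnant), spec$fetal_fraction_range[1],
                               spec$fetal_fraction_range[2])
  ff[!pregnant] <- spec$nonpregnant_background_fraction

  subgroup <- rep(NA_character_, n_total)
  labels <- names(pert)
  if (spec$n_affected > 0 && length(labels) > 0) {
    subgroup[group == "affected"] <-
      rep_len(labels, spec$n_affected)
  }

  ## standardized covariates for confounder effects
  z_ga <- rep(0, n_total)
  if (any(pregnant)) {
    mu_ga <- mean(ga[pregnant]); sd_ga <- stats::sd(ga[pregnant])
    if (is.na(sd_ga) || sd_ga == 0) sd_ga <- 1
    z_ga[pregnant] <- (ga[pregnant] - mu_ga) / sd_ga
  }
  z_age <- (age - mean(age)) / max(stats::sd(age), 1e-8)
  z_batch <- ifelse(batch == "batch2", 0.5, -0.5)

  ## --- expected densities and counts ------------------------------------
  bio_sd <- rep(spec$biological_sd, n_genes)
  bio_sd[i_ref] <- 0
  bio_sd[i_pl] <- spec$placental_biological_sd
  if (has_sex_marker) bio_sd[i_sex] <- spec$placental_biological_sd

  log2_conf <- outer(slope$gestational_age, z_ga) +
    outer(slope$maternal_age, z_age) +
    outer(slope$purification, z_batch)
  jitter <- matrix(stats::rnorm(n_genes * n_total, -bio_sd^2 / 2, bio_sd),
                   n_genes, n_total)

  x <- (m * 2^log2_conf) * exp(jitter)
  fet <- ff / 100
  p_mat <- outer(p, fet)
  if (has_sex_marker) {
    fem <- !is.na(fetal_sex) & fetal_sex == "female"
    p_mat[i_sex, fem] <- sex_p * fet[fem]
  }
  x <- x + p_mat
  x[i_med, pregnant] <- x[i_med, pregnant] *
    2^(pregnancy_log2fc[i_med])
  if (nrow(perturbations) > 0) {
    for (lab in unique(perturbations$label)) {
      pw <- perturbations[perturbations$label == lab, ]
      cols <- which(!is.na(subgroup) & subgroup == lab)
      if (length(cols))
        x[pw$gene_idx, cols] <- x[pw$gene_idx, cols] * 2^pw$log2fc
    }
  }

  mu <- sweep(sweep(x, 2, colSums(x), "/"), 2, lib_target, "*")
  counts <- if (spec$dispersion > 0) {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / spec$dispersion),
           n_genes, n_total)
  } else {
    matrix(stats::rpois(length(mu), lambda = mu), n_genes, n_total)
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(gene_id, sample_id)

  meta <- data.frame(
    sample_id = sample_id, group = group, subgroup = subgroup,
    fetal_sex = fetal_sex, maternal_age = age, gestational_age = ga,
    library_size = colSums(counts), purification = batch,
    stringsAsFactors = FALSE)

  truth_samples <- data.frame(
    sample_id = sample_id, group = group, subgroup = subgroup,
    fetal_sex = fetal_sex, true_fetal_fraction = ff,
    stringsAsFactors = FALSE)
  ## population association of each gene with each confounder, from the
  ## generative model: |slope| / sqrt(slope^2 + noise^2) for standardised
  ## numeric covariates, the correlation-ratio analogue for batch. Genes
  ## whose population association clearly exceeds the 0.5 screening
  ## threshold (>= 0.65) are labelled confounder-driven.
  sigma_g <- sqrt(bio_sd^2 + spec$dispersion) / log(2)
  pop_num <- function(s) abs(s) / sqrt(s^2 + sigma_g^2)
  pop_batch <- (abs(slope$purification) / 2) /
    sqrt(slope$purification^2 / 4 + sigma_g^2)
  pop_assoc <- pmax(pop_num(slope$gestational_age),
                    pop_num(slope$maternal_age), pop_batch)

  truth_genes <- data.frame(
    gene_id = gene_id, class = class,
    maternal_density = m, placental_density = p, length_bp = length_bp,
    pregnancy_log2fc = pregnancy_log2fc,
    ga_slope = slope$gestational_age, age_slope = slope$maternal_age,
    batch_shift = slope$purification,
    pop_confounder_assoc = pop_assoc,
    confounder_driven = pop_assoc >= 0.65,
    stringsAsFactors = FALSE)

  cm <- cf_counts(counts, data.frame(gene_id = gene_id, chrom = chrom,
                                     length_bp = length_bp,
                                     stringsAsFactors = FALSE))
  structure(list(counts = cm, meta = meta,
                 truth = list(samples = truth_samples, genes = truth_genes,
                              perturbations = perturbations[, c("label", "gene_id", "log2fc")],
                              sex_marker = if (has_sex_marker) gene_id[i_sex] else NA_character_)),
            class = "cf_cohort")
}

# indices not yet claimed by an earlier confounder's slope vector
slopes_free <- function(slope, idx) {
  if (!length(slope)) return(rep(TRUE, length(idx)))
  Reduce(`&`, lapply(slope, function(s) s == 0))
}

#' Generate a synthetic qPCR Ct table
#'
#' Emulates delta-Ct data: for a sample with true relative quantity q of an
#' assay (relative to the reference assay), each replicate Ct is
#' `reference_ct - log2(q) + N(0, noise_sd)`. The reference assay itself is
#' emitted at quantity 1.
#'
#' @param quantities data.frame with columns `sample_id`, `group`, `assay`,
#'   `quantity` (true relative quantity, > 0).
#' @param reference_assay name of the reference assay (e.g. `"ACTB"`).
#' @param reference_ct baseline Ct of the reference assay.
#' @param noise_sd Gaussian Ct noise per replicate (cycles).
#' @param n_replicates technical replicates per sample/assay (default 2,
#'   i.e. duplicates).
#' @param seed RNG seed.
#' @return data.frame with columns `sample_id`, `group`, `assay`,
#'   `replicate`, `ct`.
#' @export
generate_ct_table <- function(quantities, reference_assay = "ACTB",
                              reference_ct = 20, noise_sd = 0.15,
                              n_replicates = 2, seed = 1L) {
  req <- c("sample_id", "group", "assay", "quantity")
  if (!all(req %in% names(quantities)))
    stop("quantities must have columns: ", paste(req, collapse = ", "))
  if (any(quantities$quantity <= 0))
    stop("true quantities must be positive")
  samples <- unique(quantities[, c("sample_id", "group")])
  if (!reference_assay %in% quantities$assay) {
    ref <- data.frame(sample_id = samples$sample_id, group = samples$group,
                      assay = reference_assay, quantity = 1,
                      stringsAsFactors = FALSE)
    quantities <- rbind(quantities[, req], ref)
  }
  with_local_seed(seed, {
    out <- quantities[rep(seq_len(nrow(quantities)), each = n_replicates), ]
    out$replicate <- rep(seq_len(n_replicates), nrow(quantities))
    out$ct <- reference_ct - log2(out$quantity) +
      stats::rnorm(nrow(out), 0, noise_sd)
    rownames(out) <- NULL
    out[, c("sample_id", "group", "assay", "replicate", "ct")]
  })
}
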