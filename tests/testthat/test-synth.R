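test_that("cohort generation is deterministic and validates its spec", {
  s <- small_spec(seed = 42)
  a <- generate_cohort(s)
  b <- generate_cohort(s)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth, b$truth)

  c2 <- generate_cohort(small_spec(seed = 43))
  expect_false(identical(a$counts$counts, c2$counts$counts))

  expect_error(cohort_spec(n_normal = -1), "n_normal")
  expect_error(cohort_spec(fetal_fraction_range = c(11, 5)), "fetal_fraction_range")
  expect_error(cohort_spec(fetal_fraction_range = c(5, 120)), "fetal_fraction_range")
  expect_error(cohort_spec(dispersion = -0.1), "dispersion")
  expect_error(cohort_spec(library_size_range = c(0, 1e6)), "library_size_range")
  expect_error(cohort_spec(n_genes = 50), "n_genes")
})

test_that("every sample and gene has exactly one ground-truth record", {
  co <- generate_cohort(small_spec(seed = 2, n_affected = 3))
  expect_setequal(co$truth$samples$sample_id, colnames(co$counts$counts))
  expect_setequal(co$truth$genes$gene_id, rownames(co$counts$counts))
  expect_false(anyDuplicated(co$truth$samples$sample_id) > 0)
  expect_false(anyDuplicated(co$truth$genes$gene_id) > 0)
  expect_true(all(co$counts$counts >= 0))
  expect_true(all(co$counts$counts == round(co$counts$counts)))
  # all five confounder covariates populated
  expect_true(all(c("maternal_age", "library_size", "gestational_age",
                    "purification") %in% names(co$meta)))
})

test_that("counts are overdispersed for dispersion > 0 (negative binomial)", {
  co <- generate_cohort(small_spec(seed = 3, n_normal = 80, n_nonpregnant = 0))
  tg <- co$truth$genes
  # reference genes isolate the NB part (no extra biological jitter);
  # their variance must exceed the Poisson mean
  ref <- co$counts$counts[tg$gene_id[tg$class == "reference"], ]
  vmr <- apply(ref, 1, var) / rowMeans(ref)
  expect_gt(median(vmr), 1.5)
})

test_that("doubling the fetal fraction doubles the placental excess", {
  # mixture linearity, checked on expectations at large n via group means
  base <- small_spec(seed = 4, n_normal = 150, n_nonpregnant = 0,
                     fetal_fraction_range = c(4, 4), dispersion = 0)
  dbl <- small_spec(seed = 4, n_normal = 150, n_nonpregnant = 0,
                    fetal_fraction_range = c(8, 8), dispersion = 0)
  co1 <- generate_cohort(base)
  co2 <- generate_cohort(dbl)
  pl <- co1$truth$genes$gene_id[co1$truth$genes$class == "placental"]
  # placental genes have zero maternal baseline, so the excess is the signal
  cpm <- function(co) rowMeans(sweep(co$counts$counts[pl, ], 2,
                                     colSums(co$counts$counts) / 1e6, "/"))
  ratio <- sum(cpm(co2)) / sum(cpm(co1))
  expect_equal(ratio, 2, tolerance = 0.05)
})

test_that("noiseless limit recovers the designed fraction exactly", {
  s <- small_spec(seed = 5, fetal_fraction_range = c(7, 7), dispersion = 0,
                  biological_sd = 0, placental_biological_sd = 0,
                  library_size_range = c(6e6, 6e6))
  co <- generate_cohort(s)
  tg <- co$truth$genes
  rpkm <- compute_rpkm(co$counts, co$meta$library_size)
  est <- estimate_fetal_fraction(rpkm,
                                 tg$gene_id[tg$class == "placental"],
                                 tg$gene_id[tg$class == "reference"])
  preg <- co$meta$group != "non_pregnant"
  expect_equal(unname(median(est$fraction_percent[preg])), 7, tolerance = 0.05)
  expect_equal(unname(median(est$fraction_percent[!preg])), 0.38,
               tolerance = 0.05)
})

test_that("a spec without placental genes yields no placental signal", {
  s <- small_spec(seed = 6, n_placental = 0)
  co <- generate_cohort(s)
  expect_false("placental" %in% co$truth$genes$class)
  lib <- co$meta$library_size
  grp <- ifelse(co$meta$group == "non_pregnant", "non_pregnant", "pregnant")
  dge <- run_dge(log_cpm(co$counts$counts, lib), grp,
                 contrast = c("pregnant", "non_pregnant"))
  expect_error(select_placental_genes(dge, 0.05, logfc_gt = 2,
                                      max_control_mean = 6),
               "no significant")
})

test_that("chrY genes stay at zero and the sex marker rides the fetal fraction", {
  co <- generate_cohort(small_spec(seed = 7))
  tg <- co$truth$genes
  expect_true(all(co$counts$counts[tg$gene_id[tg$class == "chrY"], ] == 0))
  sx <- co$truth$sex_marker
  fem <- !is.na(co$meta$fetal_sex) & co$meta$fetal_sex == "female"
  male <- !is.na(co$meta$fetal_sex) & co$meta$fetal_sex == "male"
  cpm <- log_cpm(co$counts$counts, co$meta$library_size)
  expect_gt(mean(cpm[sx, fem]) - mean(cpm[sx, male]), 1.5)
})

test_that("ct table generation obeys the delta-Ct identities", {
  q <- data.frame(sample_id = c("a", "b"), group = "g",
                  assay = "X", quantity = c(1, 2))
  ct <- generate_ct_table(q, noise_sd = 0, reference_ct = 20, seed = 1)
  cta <- ct$ct[ct$sample_id == "a" & ct$assay == "X"]
  ctb <- ct$ct[ct$sample_id == "b" & ct$assay == "X"]
  expect_equal(unique(cta), 20)          # ratio 1 -> Ct equals reference
  expect_equal(unique(ctb), 19)          # doubling -> exactly one cycle less
  expect_equal(nrow(ct[ct$sample_id == "a", ]), 4)  # duplicates incl. reference
  expect_error(generate_ct_table(data.frame(sample_id = "a", group = "g",
                                            assay = "X", quantity = 0)),
               "positive")
})
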