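test_that("two-group ANOVA equals the squared t statistic and hand values", {
  # 4-sample toy table, hand-computed one-way ANOVA
  m <- matrix(c(1, 2, 5, 6), 1, 4, dimnames = list("g1", paste0("s", 1:4)))
  grp <- c("a", "a", "b", "b")
  dge <- run_dge(m, grp, contrast = c("b", "a"))
  # means 1.5 and 5.5; SSB = 2*(2^2)*2 = 16; SSW = 0.5+0.5 = 1; F = 16/(1/2)
  expect_equal(dge$F, 32)
  expect_equal(dge$logFC, 4)
  expect_equal(dge$p_value, pf(32, 1, 2, lower.tail = FALSE))

  set.seed(11)
  m2 <- matrix(rnorm(80), 8, 10, dimnames = list(paste0("g", 1:8), NULL))
  colnames(m2) <- paste0("s", 1:10)
  grp2 <- rep(c("x", "y"), each = 5)
  dge2 <- run_dge(m2, grp2, contrast = c("x", "y"))
  ts <- apply(m2, 1, function(r)
    t.test(r[grp2 == "x"], r[grp2 == "y"], var.equal = TRUE)$statistic)
  expect_equal(dge2$F, unname(ts^2), tolerance = 1e-9)
  # cross-check against stats::aov on one gene
  a <- anova(aov(m2[3, ] ~ grp2))
  expect_equal(dge2$F[3], a$`F value`[1])
  expect_equal(dge2$p_value[3], a$`Pr(>F)`[1])
})

test_that("identical group means with no noise give F = 0 and p = 1", {
  m <- matrix(rep(c(1, 2, 3), 4), 3, 4)
  rownames(m) <- paste0("g", 1:3); colnames(m) <- paste0("s", 1:4)
  dge <- run_dge(m, c("a", "a", "b", "b"))
  expect_true(all(dge$F == 0))
  expect_true(all(dge$p_value == 1))
  expect_error(run_dge(m, c("a", "a", "a", "b")), "fewer than 2")
  expect_s3_class(run_dge(m, c("a", "a", "a", "b"), min_group_size = 1),
                  "cf_dge")
})

test_that("BH adjustment is the monotone step-up transform", {
  set.seed(12)
  m <- matrix(rnorm(500 * 12), 500, 12,
              dimnames = list(paste0("g", 1:500), paste0("s", 1:12)))
  dge <- run_dge(m, rep(c("a", "b", "c"), each = 4))
  expect_equal(dge$fdr, p.adjust(dge$p_value, "BH"))
  expect_true(all(dge$fdr >= dge$p_value))
  o <- order(dge$p_value)
  expect_true(all(diff(dge$fdr[o]) >= 0))
})

test_that("designed differential genes are recovered with controlled FDR", {
  # maternal-age effects are disabled here: the pregnant and control arms
  # differ in age, so age-driven genes are genuine group differences, not
  # false positives; calibration is what this test isolates
  prep <- prepared_cohort(small_spec(
    seed = 30, n_normal = 60, n_genes = 600,
    n_pregnancy_medium = 15, medium_log2fc = c(2, 2),
    covariate_effects = list(
      gestational_age = list(frac_genes = 0.15, effect_sd = 0.5),
      maternal_age = list(frac_genes = 0, effect_sd = 0),
      purification = list(frac_genes = 0.30, effect_sd = 0.5))))
  grp <- ifelse(prep$meta$group == "non_pregnant", "non_pregnant", "pregnant")
  dge <- run_dge(prep$logmat, grp, contrast = c("pregnant", "non_pregnant"))
  tg <- prep$cohort$truth$genes
  true_pos <- intersect(
    tg$gene_id[tg$class %in% c("placental", "sex_marker") |
                 tg$pregnancy_log2fc > 0], dge$gene)
  calls <- dge$gene[dge$fdr < 0.05]
  expect_gte(mean(true_pos %in% calls), 0.9)
  # empirical FDR among upregulated calls stays controlled. Downregulated
  # calls are excluded from the accounting: the placental contribution
  # compresses the maternal share of the library in pregnant samples, so
  # stable genes show a genuine small negative compositional shift
  up_calls <- dge$gene[dge$fdr < 0.05 & dge$logFC > 0]
  expect_lte(mean(!up_calls %in% true_pos), 0.1)
})

test_that("marker tiers follow the designed strong/medium split", {
  prep <- prepared_cohort(small_spec(seed = 31, n_normal = 60))
  grp <- ifelse(prep$meta$group == "non_pregnant", "non_pregnant", "pregnant")
  dge <- run_dge(prep$logmat, grp, contrast = c("pregnant", "non_pregnant"))
  ctrl <- prep$meta$sample_id[grp == "non_pregnant"]
  mk <- pregnancy_markers(dge, detection_rate(prep$counts, ctrl))
  # single-gene tier checks
  expect_equal(mk$tier[1], "logFC>2")          # sorted by logFC
  expect_true(all(mk$fdr < 0.05))
  expect_true(all(mk$logFC > 0))
  # designed counts: the placental signature populates the strong tier,
  # the medium markers the logFC > 1 tier (Poisson-ish slack of 5)
  tg <- prep$cohort$truth$genes
  n_strong_design <- sum(tg$class == "placental")
  n_med_design <- sum(tg$pregnancy_log2fc > 0)
  expect_lte(abs(sum(mk$tier == "logFC>2") - n_strong_design), 5)
  expect_lte(abs(sum(mk$tier == "logFC>1") - n_med_design), 5)
})

test_that("the sex-marker contrast recovers the designed effect", {
  prep <- prepared_cohort(small_spec(seed = 32, n_normal = 60))
  row <- xist_contrast(prep$logmat, prep$meta, prep$cohort$truth$sex_marker)
  expect_lt(abs(row$logFC - 2.3), 0.4)
  expect_lt(row$fdr, 0.05)
  # permuting the sex labels destroys the signal in most runs
  hits <- 0
  for (i in 1:10) {
    meta2 <- prep$meta
    preg <- meta2$group != "non_pregnant"
    set.seed(100 + i)
    meta2$fetal_sex[preg] <- sample(meta2$fetal_sex[preg])
    r <- xist_contrast(prep$logmat, meta2, prep$cohort$truth$sex_marker)
    if (r$fdr < 0.05) hits <- hits + 1
  }
  expect_lte(hits, 2)
  # fetal fraction zero -> marker carries no fetal signal -> non-significant
  co0 <- generate_cohort(small_spec(seed = 33, n_normal = 60,
                                    fetal_fraction_range = c(0, 0),
                                    nonpregnant_background_fraction = 0))
  meta0 <- co0$meta
  meta0$fetal_fraction <- 0
  lm0 <- log_cpm(co0$counts$counts, meta0$library_size)
  r0 <- xist_contrast(lm0, meta0, co0$truth$sex_marker)
  expect_gt(r0$fdr, 0.05)
  # missing sex labels are an error
  meta_na <- prep$meta
  meta_na$fetal_sex[meta_na$group != "non_pregnant"] <- NA
  expect_error(xist_contrast(prep$logmat, meta_na,
                             prep$cohort$truth$sex_marker), "sex labels")
})
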