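# deterministic toy clustering whose tree topology is known: two tight
# reference blocks (pregnant high / non-pregnant low) plus candidates
# placed either as a discrete arm or inside the pregnant block
toy_clustering <- function(candidate_kind = c("arm", "interleaved"),
                           n_candidates = 1) {
  candidate_kind <- match.arg(candidate_kind)
  set.seed(50)
  n_p <- 8; n_n <- 4
  ids <- c(paste0("p", 1:n_p), paste0("n", 1:n_n),
           paste0("c", seq_len(n_candidates)))
  base <- cbind(matrix(rep(c(2, 0), c(12, 12)), 24, n_p),
                matrix(rep(c(0, 2), c(12, 12)), 24, n_n))
  cand <- matrix(rep(c(2, 0), c(12, 12)), 24, n_candidates)
  if (candidate_kind == "arm") cand[13:18, ] <- 6   # strong private block
  mat <- cbind(base, cand) + matrix(rnorm(24 * length(ids), 0, 0.05),
                                    24, length(ids))
  rownames(mat) <- paste0("g", 1:24)
  colnames(mat) <- ids
  labels <- c(rep("normal_pregnant", n_p), rep("non_pregnant", n_n),
              rep("candidate", n_candidates))
  cluster_samples(mat, rownames(mat), labels, dist_method = "euclidean")
}

test_that("criteria evaluation reads the dendrogram topology correctly", {
  # two-leaf candidate clade -> all criteria pass
  cl <- toy_clustering("arm", 2)
  crit <- evaluate_criteria(cl, c("c1", "c2"))
  expect_true(all(crit))

  # candidates interleaved among the normals -> criterion (iii) fails
  cl2 <- toy_clustering("interleaved", 2)
  crit2 <- evaluate_criteria(cl2, c("c1", "c2"))
  expect_true(crit2[["criterion1"]])
  expect_false(crit2[["criterion3"]])

  # single candidate as the external leaf of the pregnant arm
  cl3 <- toy_clustering("arm", 1)
  expect_true(evaluate_criteria(cl3, "c1")[["criterion3"]])

  # the aberrant-gene requirement is conjunctive
  expect_false(evaluate_criteria(cl3, "c1", aberrant = 2,
                                 min_aberrant = 5)[["criterion3"]])
  expect_true(evaluate_criteria(cl3, "c1", aberrant = 12,
                                min_aberrant = 5)[["criterion3"]])
})

test_that("aberrant-gene outlier test finds designed deviations only", {
  set.seed(51)
  mat <- matrix(rnorm(200 * 21), 200, 21,
                dimnames = list(paste0("g", 1:200), paste0("s", 1:21)))
  mat[1:15, 21] <- mat[1:15, 21] + 5
  ab <- candidate_aberrant_genes(mat, paste0("s", 1:20), "s21")
  expect_gte(sum(paste0("g", 1:15) %in% ab), 13)
  expect_lte(length(setdiff(ab, paste0("g", 1:15))), 2)
  # null candidate: essentially no discoveries
  ab0 <- candidate_aberrant_genes(mat, paste0("s", 1:20), "s20")
  expect_lte(length(ab0), 2)
})

test_that("a designed perturbed sample qualifies and a null sample does not", {
  pert <- list(perturbation("sub1", n_genes = 30, log2fc = c(2, -2)))
  prep <- prepared_cohort(small_spec(seed = 52, n_affected = 1,
                                     affected_perturbations = pert))
  res <- add_one_in(prep$logmat, prep$meta,
                    config = add_one_in_config(seed = 52))
  expect_true(res$report$qualified)
  expect_equal(res$report$subgroup, "sub1")
  expect_equal(res$baseline$clustering$score, 1)

  # a null affected sample (no perturbation) fails the discrete-arm criterion
  prep0 <- prepared_cohort(small_spec(seed = 52, n_affected = 1))
  res0 <- add_one_in(prep0$logmat, prep0$meta,
                     config = add_one_in_config(seed = 52))
  expect_false(res0$report$qualified)
})

test_that("the reference cohort is left untouched by the loop", {
  pert <- list(perturbation("sub1", n_genes = 30, log2fc = c(2, -2)))
  prep <- prepared_cohort(small_spec(seed = 53, n_affected = 1,
                                     affected_perturbations = pert))
  logmat_before <- prep$logmat + 0
  meta_before <- prep$meta
  invisible(add_one_in(prep$logmat, prep$meta,
                       config = add_one_in_config(seed = 53)))
  expect_identical(prep$logmat, logmat_before)
  expect_identical(prep$meta, meta_before)
})

test_that("qualified samples pool into subgroups with significant markers", {
  perts <- list(perturbation("fetal", 30, c(2, -2)),
                perturbation("maternal", 30, c(-2, 2)))
  prep <- prepared_cohort(small_spec(seed = 54, n_affected = 4,
                                     affected_perturbations = perts))
  res <- add_one_in(prep$logmat, prep$meta,
                    config = add_one_in_config(seed = 54))
  expect_true(all(res$report$qualified))
  expect_setequal(unique(res$report$subgroup), c("fetal", "maternal"))
  # pooled 4-group comparison recovers the perturbed genes at FDR < 0.05
  pg <- intersect(prep$cohort$truth$perturbations$gene_id,
                  res$pooled$dge$gene)
  hit <- res$pooled$dge$fdr[match(pg, res$pooled$dge$gene)] < 0.05
  expect_gte(mean(hit), 0.8)
  expect_equal(sort(unique(res$pooled$labels)),
               sort(c("normal_pregnant", "non_pregnant",
                      "candidate_fetal", "candidate_maternal")))
})

test_that("panel-restricted comparison stays null without injected signal", {
  # emulates restricting the analysis to an externally reported transcript
  # panel: SPB-labelled samples drawn from the normal generative model
  prep <- prepared_cohort(small_spec(seed = 55, n_affected = 6))
  meta <- prep$meta
  meta$subgroup[meta$group == "affected"] <- "SPB"
  panel <- sample(rownames(prep$logmat), 51)
  dge <- classify_spb_panel(prep$logmat, meta, panel)
  expect_true(all(dge$fdr >= 0.05))
  expect_equal(nrow(dge), length(intersect(panel, rownames(prep$logmat))))

  # a panel of genuinely perturbed genes recovers signal
  pert <- list(perturbation("SPB", 30, c(2, -2)))
  prep2 <- prepared_cohort(small_spec(seed = 56, n_affected = 6,
                                      affected_perturbations = pert))
  meta2 <- prep2$meta
  pg <- prep2$cohort$truth$perturbations$gene_id
  dge2 <- suppressWarnings(classify_spb_panel(prep2$logmat, meta2,
                                              c(pg, "absent_gene")))
  expect_true(any(dge2$fdr < 0.05))
  # absent panel genes warn; an empty intersection errors
  expect_warning(classify_spb_panel(prep2$logmat, meta2, c(pg, "absent_gene")),
                 "absent")
  expect_error(classify_spb_panel(prep2$logmat, meta2, c("nope1", "nope2")),
               "none of the panel")
})
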