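test_that("delta-Ct quantification obeys the 2^-dCt identities", {
  ct <- data.frame(
    sample_id = rep(c("a", "b", "c"), each = 4),
    group = "g",
    assay = rep(c("X", "X", "ACTB", "ACTB"), 3),
    replicate = rep(1:2, 6),
    ct = c(20, 20, 20, 20,      # Ct(target) = Ct(ref) -> quantity 1
           19, 19, 20, 20,      # one cycle less -> quantity 2
           24.0, 24.2, 20.0, 20.0))  # duplicates: dCt 4.1 -> 2^-4.1
  q <- delta_ct(ct, "ACTB")
  expect_equal(q$quantities["a", "X"], 1)
  expect_equal(q$quantities["b", "X"], 2)
  expect_equal(q$delta_ct["c", "X"], 4.1)
  expect_equal(q$quantities["c", "X"], 2^-4.1)
})

test_that("undetermined values are excluded, not zero-imputed", {
  ct <- data.frame(
    sample_id = rep(c("a", "b"), each = 4),
    group = "g",
    assay = rep(c("X", "X", "ACTB", "ACTB"), 2),
    replicate = rep(1:2, 4),
    ct = c("25", "undetermined", "20", "20",     # one replicate used
           "25", "25", "Undetermined", "undetermined"),  # no reference
    stringsAsFactors = FALSE)
  expect_warning(q <- delta_ct(ct, "ACTB"), "excluding sample")
  expect_equal(q$quantities["a", "X"], 2^-5)
  expect_false("b" %in% q$quantities$sample_id)
  expect_equal(q$excluded, "b")
  # max-cycle imputation is available but off by default
  q2 <- delta_ct(ct, "ACTB", undetermined = "max_cycle", max_cycle = 40)
  expect_true("b" %in% q2$quantities$sample_id)
})

test_that("quantity ratios are invariant to the reference-gene choice", {
  qs <- data.frame(sample_id = rep(c("a", "b"), each = 3),
                   group = "g",
                   assay = rep(c("NRIP1_linear", "ZEB2", "TOP1"), 2),
                   quantity = c(2, 1, 1, 4, 2, 1))
  ct <- generate_ct_table(qs, reference_assay = "ACTB", noise_sd = 0, seed = 1)
  qa <- delta_ct(ct, "ACTB")$quantities
  qt <- delta_ct(ct, "TOP1")$quantities
  ra <- qa$NRIP1_linear / qa$ZEB2
  rt <- qt$NRIP1_linear / qt$ZEB2
  expect_lt(max(abs(ra - rt)), 1e-9)
})

test_that("marker ratios recover injected group patterns and test them", {
  qs <- expand.grid(sample_id = sprintf("q%02d", 1:30),
                    assay = c("NRIP1_linear", "NRIP1_circ", "ZEB2"),
                    stringsAsFactors = FALSE)
  qs$group <- rep(rep(c("control", "PE", "T21"), each = 10), 3)
  qs$quantity <- 1
  qs$quantity[qs$group == "PE" & qs$assay == "NRIP1_linear"] <- 2
  qs$quantity[qs$group == "T21" & qs$assay == "NRIP1_linear"] <- 2
  qs$quantity[qs$group == "T21" & qs$assay == "NRIP1_circ"] <- 2
  ct <- generate_ct_table(qs, seed = 8)
  mr <- marker_ratios(delta_ct(ct, "ACTB"))
  med <- aggregate(cbind(target_ratio, lin_circ_ratio) ~ group,
                   mr$ratios, median)
  # NRIP1/ZEB2 up in both PE and T21; linear/circular discriminates them
  expect_equal(med$target_ratio[med$group == "PE"], 2, tolerance = 0.25)
  expect_equal(med$target_ratio[med$group == "T21"], 2, tolerance = 0.25)
  expect_equal(med$lin_circ_ratio[med$group == "PE"], 2, tolerance = 0.25)
  expect_equal(med$lin_circ_ratio[med$group == "T21"], 1, tolerance = 0.25)
  expect_equal(med$lin_circ_ratio[med$group == "control"], 1, tolerance = 0.25)
  tst <- mr$tests
  expect_lt(tst$p_target_ratio[tst$group == "PE"], 0.05)
  expect_lt(tst$p_lin_circ[tst$group == "PE"], 0.05)
  expect_gt(tst$p_lin_circ[tst$group == "T21"], 0.05)

  # equal quantities everywhere -> ratios 1, tests null
  qs0 <- qs; qs0$quantity <- 1
  mr0 <- marker_ratios(delta_ct(generate_ct_table(qs0, seed = 9), "ACTB"))
  expect_equal(median(mr0$ratios$target_ratio), 1, tolerance = 0.15)
  expect_true(all(mr0$tests$p_target_ratio > 0.05))

  # single-sample group -> test skipped with a warning
  qs1 <- qs[qs$sample_id %in% c(sprintf("q%02d", 1:10), "q11"), ]
  expect_warning(mr1 <- marker_ratios(delta_ct(generate_ct_table(qs1, seed = 10),
                                               "ACTB")), "skipped")
  expect_true(is.na(mr1$tests$p_target_ratio[mr1$tests$group == "PE"]))
})

test_that("round trip: delta_ct recovers the quantities fed to the generator", {
  set.seed(60)
  qs <- data.frame(sample_id = rep(sprintf("r%02d", 1:12), each = 2),
                   group = "g",
                   assay = rep(c("X", "Y"), 12),
                   quantity = exp(runif(24, -2, 2)))
  ct <- generate_ct_table(qs, noise_sd = 0.1, n_replicates = 2, seed = 61)
  q <- delta_ct(ct, "ACTB")
  for (a in c("X", "Y")) {
    truth <- qs$quantity[qs$assay == a][match(q$quantities$sample_id,
                                              qs$sample_id[qs$assay == a])]
    err <- log2(q$quantities[[a]]) - log2(truth)
    expect_lt(max(abs(err)), 4 * 0.1)  # within noise bounds (2 reps, sd 0.1)
  }
})

test_that("pregnancy-marker positivity matches the exact hypergeometric test", {
  ct <- data.frame(
    sample_id = rep(sprintf("v%02d", 1:18), each = 2),
    group = rep(c(rep("pregnant", 10), rep("non_pregnant", 8)), each = 2),
    assay = "VGLL3", replicate = 1:2,
    ct = c(rep("30", 20), rep("undetermined", 16)),
    stringsAsFactors = FALSE)
  det <- detect_pregnancy_marker(ct)
  expect_true(all(det$per_sample$positive[det$per_sample$group == "pregnant"]))
  expect_false(any(det$per_sample$positive[det$per_sample$group == "non_pregnant"]))
  # brute-force two-sided Fisher: enumerate the hypergeometric support and
  # sum the probabilities of tables at most as likely as the observed one
  p_obs <- dhyper(10, 10, 8, 10)
  p_oracle <- sum(vapply(0:10, function(k) {
    pk <- dhyper(k, 10, 8, 10)
    if (pk <= p_obs * (1 + 1e-7)) pk else 0
  }, numeric(1)))
  expect_equal(det$p_value, p_oracle, tolerance = 1e-12)

  # one pregnant sample undetermined -> flagged false-negative
  ct$ct[ct$sample_id == "v01"] <- "undetermined"
  det2 <- detect_pregnancy_marker(ct)
  expect_false(det2$per_sample$positive[det2$per_sample$sample_id == "v01"])
  expect_equal(sum(det2$per_sample$positive), 9)
  expect_lt(det2$p_value, 0.01)
})
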