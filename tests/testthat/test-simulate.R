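test_that("config validation rejects impossible settings", {
  expect_error(simulation_config(frac_de = 1.2), "frac_de")
  expect_error(simulation_config(tech_rep_sd = -1), "tech_rep_sd")
  expect_error(simulation_config(n_genes = 0), "n_genes")
  expect_error(simulation_config(class_probs = c(0.5, 0.5, 0.5)),
               "class_probs")
  expect_error(simulation_config(cross_dataset_rho = 2), "cross_dataset_rho")
})

test_that("cohort pair honours the design arithmetic and the DE fraction", {
  cfg <- simulation_config(n_genes = 1000, frac_de = 0.2, n_per_group_A = 3,
                           n_tech_reps = 2, seed = 7)
  sim <- generate_cohort_pair(cfg)
  expect_equal(sum(sim$truth$is_de), 200)
  expect_equal(ncol(sim$matrix_A$values), 2 * (3 + 3))
  expect_equal(ncol(sim$matrix_B$values), 2 * cfg$n_per_group_B)
  expect_equal(nrow(sim$matrix_A$values), 1000)
  # non-DE genes carry no effect in either dataset and no treatment class
  expect_true(all(sim$truth$delta_A[!sim$truth$is_de] == 0))
  expect_true(all(sim$truth$delta_B[!sim$truth$is_de] == 0))
  expect_true(all((sim$truth$treat_class == "none") == !sim$truth$is_de))
  # DE effect magnitudes respect the configured uniform bounds
  de <- abs(sim$truth$delta_A[sim$truth$is_de])
  expect_true(all(de >= cfg$effect_low & de <= cfg$effect_high))
})

test_that("identical config and seed reproduce every output bitwise", {
  cfg <- simulation_config(n_genes = 300, seed = 42)
  s1 <- generate_cohort_pair(cfg)
  s2 <- generate_cohort_pair(cfg)
  expect_identical(s1, s2)
  t1 <- generate_treatment_dataset(s1$truth, cfg)
  t2 <- generate_treatment_dataset(s2$truth, cfg)
  expect_identical(t1, t2)
  q1 <- generate_qpcr_table(s1$truth, cfg, n_test_genes = 10)
  q2 <- generate_qpcr_table(s2$truth, cfg, n_test_genes = 10)
  expect_identical(q1, q2)
})

test_that("cross_dataset_rho = 1 copies the disease effect exactly", {
  cfg <- simulation_config(n_genes = 500, cross_dataset_rho = 1, seed = 3)
  tr <- generate_cohort_pair(cfg)$truth
  de <- tr$is_de
  expect_equal(stats::cor(tr$delta_A[de], tr$delta_B[de]), 1)
  expect_equal(tr$delta_A[de], tr$delta_B[de])
})

test_that("simulated gene variances follow the scaled inverse chi-square law", {
  cfg <- simulation_config(n_genes = 10000, d0_true = 4, s0_true = 0.04,
                           seed = 5)
  tr <- generate_cohort_pair(cfg)$truth
  probs <- seq(0.05, 0.95, by = 0.05)
  emp <- stats::quantile(tr$sigma2, probs, names = FALSE)
  theo <- cfg$s0_true * cfg$d0_true / stats::qchisq(1 - probs, cfg$d0_true)
  slope <- stats::coef(stats::lm(emp ~ theo))[2]
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)
})

test_that("every rescued gene's treatment effect cancels its disease effect", {
  tr <- generate_cohort_pair(simulation_config(n_genes = 2000, seed = 9))$truth
  resc <- tr$treat_class == "rescued"
  enh <- tr$treat_class == "enhanced"
  ind <- tr$treat_class == "independent"
  expect_true(any(resc) && any(enh) && any(ind))
  expect_equal(tr$delta_A[resc] + tr$treat_effect[resc], rep(0, sum(resc)))
  expect_true(all(tr$treat_effect[ind] == 0))
  expect_true(all(sign(tr$treat_effect[enh]) == sign(tr$delta_A[enh])))
  expect_true(all(abs(tr$treat_effect[enh]) >= 0.7 &
                    abs(tr$treat_effect[enh]) <= 2.0))
})

test_that("treatment dataset is a paired design with the configured size", {
  cfg <- simulation_config(n_genes = 200, n_patients_treatment = 5, seed = 2)
  sim <- generate_cohort_pair(cfg)
  tm <- generate_treatment_dataset(sim$truth, cfg)
  expect_equal(ncol(tm$values), 10)
  expect_equal(length(unique(tm$samples$patient_id)), 5)
  expect_true(all(table(tm$samples$patient_id) == 2))
  # expected treated-minus-baseline difference tracks the truth
  big <- simulation_config(n_genes = 200, n_patients_treatment = 60, seed = 2)
  tm2 <- generate_treatment_dataset(sim$truth, big)
  tr_i <- tm2$samples$group == "treated"
  diffs <- rowMeans(tm2$values[, tr_i]) - rowMeans(tm2$values[, !tr_i])
  resc <- which(sim$truth$treat_class == "rescued")[1]
  ind <- which(sim$truth$treat_class == "independent")[1]
  expect_equal(diffs[[resc]], -sim$truth$delta_A[resc], tolerance = 0.3)
  expect_equal(diffs[[ind]], 0, tolerance = 0.3)
  expect_error(generate_treatment_dataset(sim$truth[1:10, ], cfg),
               "mismatch")
})

test_that("estimated cross-dataset fold-change correlation tracks its target", {
  # at the default attenuation-calibrated rho the estimated-FC correlation
  # should land within +/- 0.1 of 0.63, across several seeds
  rs <- vapply(1:5, function(s) {
    cfg <- simulation_config(n_genes = 10000, seed = 100 + s)
    sim <- generate_cohort_pair(cfg)
    fa <- fit_gene_models(average_technical_replicates(sim$matrix_A))
    fb <- fit_gene_models(sim$matrix_B)
    stats::cor(fa$beta, fb$beta)
  }, numeric(1))
  expect_true(all(abs(rs - 0.63) < 0.1))
})

test_that("qPCR table follows the Ct-scale contract", {
  cfg0 <- simulation_config(n_genes = 100, ct_noise_sd = 0, seed = 4)
  tr <- generate_cohort_pair(cfg0)$truth
  tab <- generate_qpcr_table(tr, cfg0, n_ref_genes = 3, n_test_genes = 8)
  expect_error(generate_qpcr_table(tr, cfg0, n_ref_genes = 1), "reference")
  # zero noise: reference genes constant across every sample
  refs <- names(tab$roles)[tab$roles == "reference"]
  for (r in refs) expect_equal(stats::sd(tab$ct[r, ]), 0)
  # a treatment effect of -1 on the expression scale raises treated Ct by 1
  g_resc <- intersect(rownames(tab$ct),
                      tr$gene_id[tr$treat_class == "rescued"])
  if (length(g_resc)) {
    g <- g_resc[1]
    eff <- tr$treat_effect[match(g, tr$gene_id)]
    s <- tab$samples
    ct_tr <- tab$ct[g, s$group == "treated"][1]
    ct_ba <- tab$ct[g, s$group == "baseline"][1]
    expect_equal(unname(ct_tr - ct_ba), -eff)
  }
})
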