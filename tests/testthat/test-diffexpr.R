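test_that("technical replicate averaging collapses to biological samples", {
  v <- matrix(c(5, 6, 1, 3), nrow = 1)
  em <- make_em(v, group = rep("disease", 4),
                patient = c("p1", "p1", "p2", "p2"),
                rep_index = c(1L, 2L, 1L, 2L))
  avg <- average_technical_replicates(em)
  expect_equal(ncol(avg$values), 2)
  expect_equal(unname(avg$values[1, ]), c(5.5, 2))
  # all-singleton replicates: output values identical to input
  em1 <- make_em(matrix(rnorm(12), 3), group = rep(c("disease", "control"), 2))
  avg1 <- average_technical_replicates(em1)
  expect_equal(unname(avg1$values), unname(em1$values))
  # generator design: 12 replicate columns -> 6 biological samples
  cfg <- simulation_config(n_genes = 50, n_per_group_A = 3, n_tech_reps = 2,
                           seed = 1)
  expect_equal(ncol(average_technical_replicates(
    generate_cohort_pair(cfg)$matrix_A)$values), 6)
})

test_that("two-group fits match hand-computed pooled statistics", {
  em <- make_two_group_em(matrix(c(1, 1), 1), matrix(c(0, 0), 1))
  f <- fit_gene_models(em)
  expect_equal(f$beta, 1)
  expect_equal(f$s2, 0)
  expect_equal(f$df_resid, 2)

  em2 <- make_two_group_em(matrix(c(2, 3, 4), 1), matrix(c(1, 2, 3), 1))
  f2 <- fit_gene_models(em2)
  expect_equal(f2$beta, 1)
  expect_equal(f2$s2, 1)
  expect_equal(f2$stdev_unscaled, sqrt(2 / 3))
  expect_equal(f2$df_resid, 4)

  expect_error(fit_gene_models(make_em(matrix(1:3, 1),
                                       c("disease", "control", "control"))),
               ">= 2 samples")
})

test_that("paired fits use within-patient differences", {
  v <- matrix(c(3, 4, 5, 6), nrow = 1)  # p1 base/treat, p2 base/treat
  em <- make_em(v, group = rep(c("baseline", "treated"), 2),
                patient = c("p1", "p1", "p2", "p2"))
  f <- fit_gene_models(em, c("treated", "baseline"), paired = TRUE)
  expect_equal(f$beta, 1)
  expect_equal(f$s2, 0)
  expect_equal(f$df_resid, 1)
  expect_equal(f$stdev_unscaled, sqrt(1 / 2))
})

test_that("moderation reports an infinite prior for homogeneous variances", {
  set.seed(1)
  em <- make_two_group_em(matrix(rnorm(300), 100), matrix(rnorm(300), 100))
  fits <- fit_gene_models(em)
  fits$s2 <- rep(0.25, 100)  # identical residual variances
  p <- estimate_moderation(fits)
  expect_true(is.infinite(p$d0))
  expect_equal(p$s0_2, 0.25, tolerance = 1e-6)
})

test_that("moderation recovers the generating hyperparameters", {
  set.seed(7)
  n <- 10000
  df <- 10
  s2 <- 0.04 * 4 / rchisq(n, 4) * rchisq(n, df) / df
  fits <- data.frame(gene_id = sprintf("g%d", 1:n), beta = 0, s2 = s2,
                     stdev_unscaled = 1, df_resid = df)
  p <- estimate_moderation(fits)
  expect_equal(p$d0, 4, tolerance = 0.2)
  expect_equal(p$s0_2, 0.04, tolerance = 0.1)
})

test_that("trigamma inversion matches an independent bisection oracle", {
  # two well-separated variances repeated equally at df = 4 (spread wide
  # enough for a finite prior): d0 must solve the moment equation
  # trigamma(d0/2) = excess log-variance; solve it here by plain bisection
  s2 <- rep(c(0.01, 0.25), each = 50)
  df <- rep(4, 100)
  fits <- data.frame(gene_id = sprintf("g%d", 1:100), beta = 0, s2 = s2,
                     stdev_unscaled = 1, df_resid = df)
  p <- estimate_moderation(fits)
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - mean(trigamma(df / 2))
  f <- function(x) trigamma(x) - evar
  lo <- 1e-6; hi <- 1e6
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  expect_equal(p$d0, 2 * (lo + hi) / 2, tolerance = 1e-6)
  # and agrees with limma's independent implementation on random variances
  set.seed(11)
  s2r <- 0.05 * 6 / rchisq(2000, 6) * rchisq(2000, 8) / 8
  fitr <- data.frame(gene_id = sprintf("g%d", 1:2000), beta = 0, s2 = s2r,
                     stdev_unscaled = 1, df_resid = 8)
  pr <- estimate_moderation(fitr)
  sq <- limma::squeezeVar(s2r, df = 8)
  expect_equal(pr$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(pr$s0_2, sq$var.prior, tolerance = 1e-6)
})

test_that("moderation refuses too few informative genes", {
  fits <- data.frame(gene_id = sprintf("g%d", 1:20), beta = 0, s2 = runif(20),
                     stdev_unscaled = 1, df_resid = 4)
  expect_error(estimate_moderation(fits), "50 genes")
})

test_that("d0 = 0 reproduces the classical two-sample t test exactly", {
  set.seed(3)
  x <- matrix(rnorm(40, sd = 0.5), nrow = 5)
  em <- make_two_group_em(x[, 1:4], x[, 5:8] + 0.3)
  fits <- fit_gene_models(em)
  res <- moderate_and_test(fits, list(d0 = 0, s0_2 = NA))
  for (g in 1:5) {
    tt <- t.test(x[g, 1:4], x[g, 5:8] + 0.3, var.equal = TRUE)
    expect_equal(res$t_mod[g], unname(tt$statistic))
    expect_equal(res$p[g], tt$p.value)
    expect_equal(c(res$ci_lo[g], res$ci_hi[g]), as.numeric(tt$conf.int))
  }
})

test_that("posterior variances shrink between s2 and s0_2 and hit both limits", {
  set.seed(5)
  em <- make_two_group_em(matrix(rnorm(600), 100), matrix(rnorm(600), 100))
  fits <- fit_gene_models(em)
  params <- estimate_moderation(fits)
  res <- moderate_and_test(fits, params)
  expect_true(all(res$s2_post >= pmin(fits$s2, params$s0_2) - 1e-12))
  expect_true(all(res$s2_post <= pmax(fits$s2, params$s0_2) + 1e-12))
  expect_equal(res$df_total, fits$df_resid + params$d0)
  # d0 -> Inf collapses onto the prior; d0 = 0 onto the gene-wise variance
  res_inf <- moderate_and_test(fits, list(d0 = Inf, s0_2 = 0.9))
  expect_true(all(res_inf$s2_post == 0.9))
  res_0 <- moderate_and_test(fits, list(d0 = 0, s0_2 = 0.9))
  expect_equal(res_0$s2_post, fits$s2)
  expect_equal(res_0$df_total, fits$df_resid)
  # a zero effect estimate yields p = 1 and a CI symmetric about 0
  fits1 <- fits[1, ]
  fits1$beta <- 0
  r1 <- moderate_and_test(fits1, params)
  expect_equal(r1$p, 1)
  expect_equal(r1$ci_lo, -r1$ci_hi)
})

test_that("moderated p-values are uniform under the generator's null", {
  cfg <- simulation_config(n_genes = 10000, frac_de = 0, seed = 21)
  sim <- generate_cohort_pair(cfg)
  fits <- fit_gene_models(average_technical_replicates(sim$matrix_A))
  res <- moderate_and_test(fits, estimate_moderation(fits))
  ks <- suppressWarnings(stats::ks.test(res$p, "punif"))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("BH step-up matches its definition, p.adjust and a brute-force oracle", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.3), 0.3)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(13)
  for (i in 1:50) {
    m <- sample(1:12, 1)
    p <- round(runif(m), 3)  # rounding forces ties regularly
    q <- benjamini_hochberg(p)
    expect_equal(q, bh_oracle(p))
    expect_equal(q, stats::p.adjust(p, "BH"))
  }
})

test_that("BH is permutation-equivariant and monotone in p", {
  set.seed(17)
  p <- runif(200)
  q <- benjamini_hochberg(p)
  perm <- sample(200)
  expect_equal(benjamini_hochberg(p[perm]), q[perm])
  expect_true(all(q >= p - 1e-15) && all(q <= 1))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
})
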