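test_that("expected case frequencies: self and independence limits", {
  # candidate IS the disease variant: diagonal joint, pi = P(D')
  pd <- c(0.5, 0.4, 0.1)
  diag_joint <- diag(c(0.6, 0.3, 0.1))
  e <- expected_case_freqs(diag_joint, pd)
  expect_equal(unname(e$pi), pd, tolerance = 1e-12)

  # no genotype LD: joint = outer product, pi = control margins whatever P(D')
  mg <- c(0.49, 0.42, 0.09)
  md <- c(0.64, 0.32, 0.04)
  e <- expected_case_freqs(outer(mg, md), c(0.1, 0.3, 0.6))
  expect_equal(unname(e$pi), mg, tolerance = 1e-12)
})

test_that("expected case frequencies match per-individual reweighting", {
  # oracle: every individual gets importance weight P(D'_j)/P(D_j) for its
  # disease genotype j; pi_i is the weighted frequency of candidate genotype i
  for (seed in c(2, 9)) {
    p <- random_small_panel(20, 3, seed = seed)
    g <- genotypes(p)
    pd_case <- c(0.2, 0.5, 0.3)
    pd_ctl <- sapply(0:2, function(j) mean(g[, 2] == j))
    if (any(pd_ctl == 0)) next
    w <- pd_case[g[, 2] + 1L] / pd_ctl[g[, 2] + 1L]
    oracle <- sapply(0:2, function(i) mean(w * (g[, 1] == i)))
    e <- expected_case_freqs(joint_genotype_freq(g[, 1], g[, 2]), pd_case)
    expect_equal(unname(e$pi), oracle, tolerance = 1e-12)
    expect_equal(sum(e$pi), 1, tolerance = 1e-12)
  }
})

test_that("unreachable case genotypes are an error", {
  joint <- matrix(c(0.5, 0, 0, 0.5, 0, 0, 0, 0, 0), 3, 3)
  expect_error(expected_case_freqs(joint, c(0.5, 0.3, 0.2)), "unreachable")
})

test_that("multinomial covariance: binomial case and Monte-Carlo determinant", {
  s <- multinomial_covariance(c(0.3, 0.7), 100)
  expect_equal(as.numeric(s), 21)
  expect_equal(attr(s, "df"), 1L)

  pi <- c(0.25, 0.5, 0.25)
  s <- multinomial_covariance(pi, 100)
  expect_equal(attr(s, "df"), 2L)
  set.seed(15)
  draws <- t(stats::rmultinom(1e5, 100, pi)[1:2, ])
  expect_lt(abs(det(cov(draws)) / det(s) - 1), 0.03)

  # zero category reduces the dimension
  s0 <- multinomial_covariance(c(0.4, 0, 0.6), 50)
  expect_equal(attr(s0, "df"), 1L)
  expect_equal(attr(s0, "categories"), c(1L, 3L))
})

test_that("lrt_statistic closed form, zero conventions and sentinels", {
  # exact fit with unit determinant ratio
  r <- lrt_statistic(c(25, 50, 25), c(0.25, 0.5, 0.25), 1, 1)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_lower, 0)
  expect_equal(r$df, 2L)

  # fixed toy counts: direct evaluation of the log-likelihood ratio
  o <- c(30, 50, 20); pi <- c(0.25, 0.5, 0.25)
  oracle <- 2 * (30 * log(30 / 25) + 50 * log(50 / 50) + 20 * log(20 / 25))
  r <- lrt_statistic(o, pi, 1, 1)
  expect_equal(r$statistic, oracle, tolerance = 1e-12)
  expect_equal(r$g_raw, oracle, tolerance = 1e-12)
  expect_equal(r$p_lower, pchisq(oracle, 2), tolerance = 1e-12)

  # zero observed count contributes 0
  r <- lrt_statistic(c(0, 50, 50), c(0.25, 0.5, 0.25), 1, 1)
  expect_true(is.finite(r$statistic))

  # zero expected with nonzero observed rejects the model outright
  r <- lrt_statistic(c(10, 90, 0), c(0, 0.9, 0.1), 1, 1)
  expect_equal(r$statistic, Inf)
  expect_equal(r$p_lower, 1)
  expect_true(r$rejected_support)

  # determinant correction scales the statistic; equal determinants leave it
  r1 <- lrt_statistic(o, pi, 4, 1)
  r2 <- lrt_statistic(o, pi, 1, 1)
  expect_equal(r1$statistic, r2$statistic * 2)  # (4/1)^(1/2)
  expect_equal(r1$correction, 2)
})

test_that("the statistic is invariant to genotype category order", {
  o <- c(30, 50, 20); pi <- c(0.25, 0.5, 0.25)
  perm <- c(2, 3, 1)
  r1 <- lrt_statistic(o, pi, 2.5, 1.5)
  r2 <- lrt_statistic(o[perm], pi[perm], 2.5, 1.5)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
})

test_that("simulated variance is deterministic and flags low precision", {
  p <- apoe_panel()
  ctl <- subset_individuals(p, 1:400)
  model <- disease_model("no18", mode = "dominant", or = 1.5)
  d1 <- simulated_variance(ctl, model, "no7", n_cases = 200, reps = 60,
                           seed = 9)
  d2 <- simulated_variance(ctl, model, "no7", n_cases = 200, reps = 60,
                           seed = 9)
  expect_equal(as.numeric(d1), as.numeric(d2))
  expect_true(isTRUE(attr(d1, "low_precision")))
  expect_gt(as.numeric(d1), 0)
  d3 <- simulated_variance(ctl, model, "no7", n_cases = 200, reps = 2,
                           seed = 1)
  expect_true(isTRUE(attr(d3, "low_precision")))
})

test_that("without LD or control-sampling noise |sigma| approaches |Sigma|", {
  # two independent variants; controls outnumber pseudo-cases so the
  # control-sampling term is negligible
  cfg <- panel_config(rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1)),
                      c(0.42, 0.28, 0.18, 0.12),
                      data.frame(id = c("a", "b")))
  ctl <- synth_panel(cfg, 1500, seed = 3)
  model <- disease_model("a", mode = "dominant", y = 0.3)
  det_sim <- simulated_variance(ctl, model, "b", n_cases = 100, reps = 1000,
                                seed = 5)
  virt <- collapse_variants(ctl, "a")
  triple <- rev(sapply(0:2, function(j) mean(virt$genotypes == j)))
  pd <- geno_probs(case_genotype_freqs(triple, 0.3, "dominant"))
  e <- expected_case_freqs(
    joint_genotype_freq(genotypes(ctl)[, 2], virt$genotypes), pd)
  det_model <- det(multinomial_covariance(e$pi, 100))
  expect_lt(abs(as.numeric(det_sim) / det_model - 1), 0.25)
})
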