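make_groups <- function() {
  list(seeds = paste0("s", 1:10), background = paste0("b", 1:50))
}

test_that("binary annotation screening matches hypergeometric enumeration", {
  g <- make_groups()
  genes <- c(g$seeds, g$background)
  # present in all 10 seeds, 0 of 50 background
  B <- matrix(c(rep(1, 10), rep(0, 50)), ncol = 1,
              dimnames = list(genes, "a1"))
  sel <- select_binary_annotations(B, g$seeds, g$background)
  expect_equal(sel$p_value, 1 / choose(60, 10), tolerance = 1e-12)
  expect_true(sel$selected)

  # identical prevalence in both groups: not enriched
  B2 <- matrix(c(rep(c(1, 0), 5), rep(c(1, 0), 25)), ncol = 1,
               dimnames = list(genes, "a1"))
  sel2 <- select_binary_annotations(B2, g$seeds, g$background)
  expect_gte(sel2$p_value, 0.5)
  expect_false(sel2$selected)

  # 8/10 seeds vs 5/50 background: one-sided tail by direct summation
  B3 <- matrix(c(rep(1, 8), 0, 0, rep(1, 5), rep(0, 45)), ncol = 1,
               dimnames = list(genes, "a1"))
  sel3 <- select_binary_annotations(B3, g$seeds, g$background)
  tail_p <- sum(dhyper(8:10, 13, 47, 10))
  expect_equal(sel3$p_value, tail_p, tolerance = 1e-12)

  # entirely missing in one group: flagged, not selected
  B4 <- matrix(c(rep(NA, 10), rep(0, 50)), ncol = 1,
               dimnames = list(genes, "a1"))
  sel4 <- select_binary_annotations(B4, g$seeds, g$background)
  expect_true(sel4$flagged)
  expect_false(sel4$selected)
})

test_that("continuous screening reproduces the Welch t-test formula", {
  g <- make_groups()
  genes <- c(g$seeds, g$background)
  set.seed(31)
  vals <- c(rnorm(10, 1), rnorm(50, 0))
  C <- matrix(vals, ncol = 1, dimnames = list(genes, "c1"))
  sel <- select_continuous_annotations(C, g$seeds, g$background)
  vs <- vals[1:10]; vb <- vals[11:60]
  tstat <- (mean(vs) - mean(vb)) / sqrt(var(vs) / 10 + var(vb) / 50)
  df <- (var(vs) / 10 + var(vb) / 50)^2 /
    ((var(vs) / 10)^2 / 9 + (var(vb) / 50)^2 / 49)
  expect_equal(sel$statistic, tstat, tolerance = 1e-12)
  expect_equal(sel$p_value, 2 * pt(-abs(tstat), df), tolerance = 1e-12)

  # identical samples in both groups: t = 0, p = 1
  C2 <- matrix(c(rep(c(0, 1), 5), rep(c(0, 1), 25)), ncol = 1,
               dimnames = list(genes, "c1"))
  sel2 <- select_continuous_annotations(C2, g$seeds, g$background)
  expect_equal(sel2$p_value, 1, tolerance = 1e-12)
  expect_false(sel2$selected)

  # well-separated near-constant groups are selected
  C3 <- matrix(c(1 + seq(0, 1e-6, length.out = 10),
                 0 + seq(0, 1e-6, length.out = 50)), ncol = 1,
               dimnames = list(genes, "c1"))
  sel3 <- select_continuous_annotations(C3, g$seeds, g$background)
  expect_true(sel3$selected)
})

test_that("beta hyperparameter fits follow the smoothed-frequency rule", {
  hp <- fit_beta_hyperparams(k = 65, n = 65, annotation = "a")
  expect_equal(c(hp$alpha, hp$beta), c(66, 1))
  hp0 <- fit_beta_hyperparams(k = 0, n = 500)
  expect_equal(c(hp0$alpha, hp0$beta), c(1, 501))
  # implied single-gene marginal p(D = 1) = (k+1)/(n+2)
  hp2 <- fit_beta_hyperparams(k = 13, n = 40)
  expect_equal(binary_marginal(1, 1, hp2), 14 / 42, tolerance = 1e-14)
})

test_that("Beta-Bernoulli marginal matches quadrature and normalizes", {
  expect_equal(binary_marginal(1, 1, list(alpha = 1, beta = 1)), 0.5)
  expect_equal(binary_marginal(1, 1, list(alpha = 2, beta = 3)), 0.4)
  expect_error(binary_marginal(1, 1, list(alpha = 0, beta = 1)), "positive")

  hp <- list(alpha = 2.5, beta = 7.1)
  expect_equal(binary_marginal(2, 6, hp), quad_beta_marginal(2, 6, 2.5, 7.1),
               tolerance = 1e-8)

  set.seed(8)
  for (i in 1:25) {
    a <- runif(1, 0.2, 10); b <- runif(1, 0.2, 10); n <- sample(1:12, 1)
    hp <- list(alpha = a, beta = b)
    total <- sum(vapply(0:n, function(k)
      choose(n, k) * binary_marginal(k, n, hp), numeric(1)))
    expect_equal(total, 1, tolerance = 1e-10)
  }
})

test_that("binary Bayes factors behave as marginal ratios", {
  hp1 <- list(alpha = 66, beta = 1)
  hp0 <- list(alpha = 1, beta = 501)
  expect_equal(binary_bf(1, hp1, hp0)$bf, (66 / 67) / (1 / 502),
               tolerance = 1e-12)
  expect_equal(binary_bf(0, hp1, hp0)$bf, (1 / 67) / (501 / 502),
               tolerance = 1e-12)
  expect_equal(binary_bf(1, hp1, hp1)$bf, 1)
  miss <- binary_bf(NA, hp1, hp0)
  expect_true(miss$missing)
  expect_identical(miss$bf, 1)
})

test_that("NIG fits moment-match the group mean and variance", {
  hp <- fit_nig_hyperparams(values = c(0, 0, 2, 2))
  expect_equal(hp$mu0, 1)
  expect_equal(hp$kappa, 4)
  expect_equal(hp$nu, 3)
  expect_equal(hp$sigma2, 16 / 45, tolerance = 1e-14)
  # implied marginal variance equals the sample variance exactly
  v_marg <- hp$sigma2 * (1 + hp$kappa) / hp$kappa * hp$nu / (hp$nu - 2)
  expect_equal(v_marg, var(c(0, 0, 2, 2)), tolerance = 1e-14)

  expect_error(fit_nig_hyperparams(values = c(1, 2, 3)), ">= 4")
  expect_error(fit_nig_hyperparams(values = rep(1, 6)), "variance")

  # Monte-Carlo consistency: large-sample fit recovers the truth
  set.seed(12)
  x <- rnorm(20000, mean = 3, sd = 2)
  hp_big <- fit_nig_hyperparams(values = x)
  expect_equal(hp_big$mu0, 3, tolerance = 0.05)
  v_big <- hp_big$sigma2 * (1 + hp_big$kappa) / hp_big$kappa *
    hp_big$nu / (hp_big$nu - 2)
  expect_equal(v_big, 4, tolerance = 0.15)
})

test_that("non-standardized t marginal matches 2-D NIG quadrature", {
  set.seed(3)
  for (i in 1:5) {
    mu0 <- runif(1, -2, 2); kappa <- runif(1, 0.5, 8)
    nu <- sample(3:15, 1); sigma2 <- runif(1, 0.3, 2.5)
    s2 <- sigma2 * (1 + kappa) / kappa
    for (d in mu0 + c(-2, 0, 1.3)) {
      expect_equal(dt_ns(d, nu, mu0, s2),
                   quad_nig_marginal(d, mu0, kappa, nu, sigma2),
                   tolerance = 1e-6)
    }
  }
})

test_that("continuous Bayes factors compare the two fitted t densities", {
  hp1 <- fit_nig_hyperparams(values = c(2, 3, 4, 5, 6))
  hp0 <- fit_nig_hyperparams(values = c(-2, -1, 0, 1, 2))
  expect_equal(continuous_bf(4, hp1, hp1)$bf, 1)
  expect_gt(continuous_bf(4, hp1, hp0)$bf, 1)
  expect_lt(continuous_bf(0, hp1, hp0)$bf, 1)
  expect_true(continuous_bf(NA, hp1, hp0)$missing)
  # antisymmetry: swapping the models inverts the BF
  b <- continuous_bf(2.2, hp1, hp0)
  binv <- continuous_bf(2.2, hp0, hp1)
  expect_equal(b$bf * binv$bf, 1, tolerance = 1e-12)
})

test_that("gene-level Bayes factor is the log-space product over annotations", {
  genes <- paste0("g", 1:30)
  set.seed(77)
  B <- matrix(rbinom(30 * 4, 1, 0.3), 30, 4,
              dimnames = list(genes, paste0("b", 1:4)))
  C <- matrix(rnorm(30 * 4), 30, 4,
              dimnames = list(genes, paste0("c", 1:4)))
  sel <- data.frame(annotation = c(paste0("b", 1:4), paste0("c", 1:4)),
                    kind = rep(c("binary", "continuous"), each = 4),
                    statistic = NA, p_value = 0.01, selected = TRUE,
                    flagged = FALSE)
  models <- fit_annotation_models(B, C, sel, genes[1:10], genes[11:30])
  lbf <- gene_bayes_factor(genes, B, C, models)

  # total equals direct per-annotation product
  for (g in sample(genes, 5)) {
    direct <- 1
    for (a in paste0("b", 1:4)) {
      direct <- direct * binary_bf(B[g, a], models$binary[[a]]$hp1,
                                   models$binary[[a]]$hp0)$bf
    }
    for (a in paste0("c", 1:4)) {
      direct <- direct * continuous_bf(C[g, a], models$continuous[[a]]$hp1,
                                       models$continuous[[a]]$hp0)$bf
    }
    expect_equal(exp(lbf[g, ".total"]), direct, tolerance = 1e-12)
  }

  # identical fitting groups give BF = 1 everywhere
  same <- fit_annotation_models(B, C, sel, genes[1:10], genes[1:10])
  lbf_same <- gene_bayes_factor(genes, B, C, same)
  expect_true(all(abs(lbf_same) < 1e-12))

  # swapping M1 and M0 inverts every per-annotation BF
  swapped <- models
  for (a in names(swapped$binary))
    swapped$binary[[a]] <- list(hp1 = models$binary[[a]]$hp0,
                                hp0 = models$binary[[a]]$hp1)
  for (a in names(swapped$continuous))
    swapped$continuous[[a]] <- list(hp1 = models$continuous[[a]]$hp0,
                                    hp0 = models$continuous[[a]]$hp1)
  lbf_sw <- gene_bayes_factor(genes, B, C, swapped)
  expect_equal(lbf_sw[, 1:8], -lbf[, 1:8], tolerance = 1e-12)

  # genes missing from the matrices are evidence-neutral
  lbf_new <- gene_bayes_factor(c("zz1", "zz2"), B, C, models)
  expect_true(all(lbf_new == 0))
})

test_that("planted rate differences push log-BFs in the right direction", {
  cfg <- simulation_config(n_genes = 1000L, n_risk = 120L,
                           n_seeds_observed = 60L, rng_seed = 14)
  b <- simulate_universe(cfg)
  bg <- sample_background(b$universe, b$seeds, n = 300, rng_seed = 15)
  sel <- rbind(select_binary_annotations(b$binary, b$seeds, bg),
               select_continuous_annotations(b$continuous, b$seeds, bg))
  models <- fit_annotation_models(b$binary, b$continuous, sel, b$seeds, bg)
  lbf <- gene_bayes_factor(b$universe, b$binary, b$continuous, models)
  risk <- b$universe %in% b$risk
  expect_gt(mean(lbf[risk, ".total"]), 0)
  expect_lt(mean(lbf[!risk, ".total"]), 0)
})
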