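# Design encoding, fixed-effect fitting, variance components, heritability,
# Gibbs estimation.

test_that("design encoding follows the fixed conventions", {
  panel <- balanced_two_snp_panel(40)
  truth <- simulation_truth(mu = 20)
  ph <- exact_phenotype(panel, truth)
  spec <- design_spec(loci = c("2L_1000_T", "2L_2000_G"),
                      pairs = "2L_1000_T:2L_2000_G",
                      qe_loci = "2L_1000_T",
                      qqe_pairs = "2L_1000_T:2L_2000_G")
  d <- encode_design(spec, panel, phenotypes = ph)
  expect_identical(colnames(d$X),
                   c("(mu)", "sex", "q:2L_1000_T", "q:2L_2000_G",
                     "qq:2L_1000_T:2L_2000_G", "qe:2L_1000_T",
                     "qqe:2L_1000_T:2L_2000_G"))
  u1 <- d$X[, "q:2L_1000_T"]; u2 <- d$X[, "q:2L_2000_G"]
  # major/major -> +1, minor/minor -> -1
  expect_setequal(unique(u1), c(-1, 1))
  expect_identical(unname(u1[1:40]), unname(1 - panel$calls[, "2L_1000_T"]))
  # product coding: codes (+1, -1) give pair coefficient -1
  expect_identical(d$X[, "qq:2L_1000_T:2L_2000_G"], u1 * u2)
  # qe = main code x sex contrast (+1 female, -1 male)
  s <- d$X[, "sex"]
  expect_identical(unique(s[1:40]), 1)
  expect_identical(unique(s[41:80]), -1)
  expect_identical(d$X[, "qe:2L_1000_T"], u1 * s)
  expect_identical(d$X[, "qqe:2L_1000_T:2L_2000_G"], u1 * u2 * s)
})

test_that("transcript predictors are standardized within each sex", {
  s <- seeded_signal_panel(21, n_lines = 60, n_snps = 20, n_transcripts = 5)
  spec <- design_spec(loci = "T0002", response = "phenotype")
  d <- encode_design(spec, s$genotypes, s$expression, s$phenotype)
  z <- d$X[, "q:T0002"]
  n <- 60
  for (b in 1:2) {
    idx <- seq_len(n) + (b - 1L) * n
    expect_equal(mean(z[idx]), 0, tolerance = 1e-12)
    expect_equal(sd(z[idx]), 1, tolerance = 1e-12)
  }
})

test_that("noise-free balanced single-locus data recovers the effect exactly", {
  panel <- balanced_two_snp_panel(40)
  truth <- simulation_truth(mu = 20, qts_effects = c("2L_1000_T" = 2))
  ph <- exact_phenotype(panel, truth)
  d <- encode_design(design_spec(loci = "2L_1000_T"), panel, phenotypes = ph)
  f <- fit_qtx(d)
  expect_equal(unname(coef(f)[["q:2L_1000_T"]]), 2, tolerance = 1e-12)
  expect_equal(unname(coef(f)[["(mu)"]]), 20, tolerance = 1e-12)
})

test_that("fixed-model estimates match brute-force normal equations on random designs", {
  set.seed(404)
  for (rep in 1:20) {
    n <- sample(10:30, 1)
    p <- sample(2:4, 1)
    X <- cbind(1, matrix(rnorm(n * p), n, p))
    colnames(X) <- c("(mu)", paste0("q:snp", seq_len(p)))
    y <- rnorm(n)
    d <- structure(
      list(X = X, y = y, obs = NULL,
           terms = data.frame(name = colnames(X),
                              group = c("intercept", rep("main", p)),
                              id1 = NA, id2 = NA, scale = 1),
           n_lines = n, line_ids = NULL),
      class = "qtx_design"
    )
    f <- fit_qtx(d)
    expect_equal(unname(coef(f)), unname(normal_equations_oracle(X, y)),
                 tolerance = 1e-10)
  }
})

test_that("nominal P values are uniform under the null", {
  set.seed(99)
  n <- 24
  pvals <- replicate(1000, {
    X <- cbind(1, sample(c(-1, 1), n, replace = TRUE))
    colnames(X) <- c("(mu)", "q:s")
    while (var(X[, 2]) == 0) X[, 2] <- sample(c(-1, 1), n, replace = TRUE)
    d <- structure(
      list(X = X, y = rnorm(n), obs = NULL,
           terms = data.frame(name = colnames(X),
                              group = c("intercept", "main"),
                              id1 = NA, id2 = NA, scale = 1),
           n_lines = n, line_ids = NULL),
      class = "qtx_design"
    )
    fit_qtx(d)$p[["q:s"]]
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("rank-deficient designs are rejected naming the aliased column", {
  panel <- balanced_two_snp_panel(40)
  calls3 <- cbind(panel$calls, `2L_3000_C` = panel$calls[, 1])
  snps3 <- rbind(panel$snps,
                 data.frame(id = "2L_3000_C", chrom = "2L", pos = 3000L,
                            major = "A", minor = "C"))
  p3 <- genotype_panel(calls3, snps3)
  ph <- exact_phenotype(p3, simulation_truth(mu = 20))
  d <- encode_design(design_spec(loci = c("2L_1000_T", "2L_3000_C")), p3,
                     phenotypes = ph)
  expect_error(fit_qtx(d), "aliased.*2L_3000_C")
})

test_that("variance components follow the population-variance convention and sum to V_P", {
  panel <- balanced_two_snp_panel(40)
  truth <- simulation_truth(mu = 20, qts_effects = c("2L_1000_T" = 2))
  ph <- exact_phenotype(panel, truth)
  d <- encode_design(design_spec(loci = "2L_1000_T"), panel, phenotypes = ph)
  f <- fit_qtx(d)
  vc <- variance_components(f)
  # balanced +/-1 coding with q = 2: V_Q = q^2 = 4
  expect_equal(vc$V_Q, 4, tolerance = 1e-10)
  expect_equal(vc$V_QQ, 0)  # no epistatic terms in the model
  expect_equal(vc$V_P, vc$V_Q + vc$V_QQ + vc$V_QE + vc$V_QQE + vc$V_eps,
               tolerance = 1e-8)
})

test_that("variance components recover generator truth on a large panel", {
  n <- 500
  cfg0 <- sim_config(n_lines = n, n_snps = 30, seed = 31)
  g <- simulate_genotypes(cfg0)
  ids <- g$snps$id[c(3, 12, 25)]
  truth <- simulation_truth(
    mu = 25, qts_effects = stats::setNames(c(1.5, -1, 0.8), ids),
    epistasis_effects = stats::setNames(0.7, pair_key <- paste(ids[1], ids[2], sep = ":")),
    sex_effect = 0.5,
    qe_effects = stats::setNames(0.6, ids[3])
  )
  cfg <- sim_config(n_lines = n, n_snps = 30, truth = truth,
                    residual_sd_pheno = 1, seed = 31)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(g, cfg)$phenotype
  d <- encode_design(
    design_spec(loci = ids, pairs = pair_key, qe_loci = ids[3]),
    g, phenotypes = ph
  )
  f <- fit_qtx(d)
  vc <- variance_components(f)
  # plug-in truth: population variance of the true term contributions on the
  # realized genotypes (the generator's own design matrix)
  u <- 1 - g$calls
  gQ <- u[, ids] %*% c(1.5, -1, 0.8)
  vQ_true <- mean((gQ - mean(gQ))^2)
  vQQ_true <- {
    x <- 0.7 * u[, ids[1]] * u[, ids[2]]
    mean((x - mean(x))^2)
  }
  vQE_true <- {
    x <- c(0.6 * u[, ids[3]], -0.6 * u[, ids[3]])
    mean((x - mean(x))^2)
  }
  # estimation error is driven by coefficient noise: se(q) ~ sd/sqrt(2n);
  # 3 MC SEs on each component (delta method, dV/dq = 2q var(u))
  tol_q <- 3 * 2 * max(abs(c(1.5, 1, 0.8))) * 1 / sqrt(2 * n) * 2
  expect_equal(vc$V_Q, vQ_true, tolerance = tol_q / vQ_true)
  expect_equal(vc$V_QQ, vQQ_true, tolerance = tol_q / vQQ_true)
  expect_equal(vc$V_QE, vQE_true, tolerance = tol_q / vQE_true)
  # residual variance near sigma^2 / replicates
  expect_equal(vc$V_eps, 0.5, tolerance = 0.2)
})

test_that("heritability identities hold and degenerate inputs error", {
  vc <- qtx_varcomp(V_Q = 3, V_QQ = 1, V_QE = 0.5, V_QQE = 0.25, V_eps = 0.25)
  h <- heritability(vc)
  expect_equal(h$h2_T, h$h2_Q + h$h2_QQ + h$h2_QE + h$h2_QQE)
  expect_equal(h$h2_T, 4.75 / 5)
  expect_error(heritability(qtx_varcomp()), "zero")
  h0 <- heritability(qtx_varcomp(V_eps = 2))
  expect_equal(h0$h2_T, 0)
})

test_that("noise-free simulations give total heritability and R2 of exactly 1", {
  panel <- balanced_two_snp_panel(40)
  truth <- simulation_truth(
    mu = 20, qts_effects = c("2L_1000_T" = 2, "2L_2000_G" = -1),
    epistasis_effects = c("2L_1000_T:2L_2000_G" = 0.5)
  )
  ph <- exact_phenotype(panel, truth)
  d <- encode_design(
    design_spec(loci = c("2L_1000_T", "2L_2000_G"),
                pairs = "2L_1000_T:2L_2000_G", include_sex = TRUE),
    panel, phenotypes = ph
  )
  f <- fit_qtx(d)
  h <- heritability(f)
  expect_equal(h$h2_T, 1, tolerance = 1e-10)
  expect_equal(predict_r2(f)$r2, 1, tolerance = 1e-10)
})

test_that("R2 tracks simulated heritability and collapses for permuted predictions", {
  n <- 500
  cfg0 <- sim_config(n_lines = n, n_snps = 20, seed = 77)
  g <- simulate_genotypes(cfg0)
  id <- g$snps$id[5]
  # single locus, q chosen so h2 ~ 0.5: q^2 var(u) = sigma_eff^2
  truth <- simulation_truth(mu = 25, qts_effects = stats::setNames(1, id))
  cfg <- sim_config(n_lines = n, n_snps = 20, truth = truth,
                    residual_sd_pheno = sqrt(2), replicate_count = 2, seed = 77)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(g, cfg)$phenotype
  d <- encode_design(design_spec(loci = id), g, phenotypes = ph)
  f <- fit_qtx(d)
  pr <- predict_r2(f)
  h2_implied <- {
    u <- 1 - g$calls[, id]
    vq <- mean((u - mean(u))^2)
    vq / (vq + 2 / 2)   # residual of line x sex means: sigma^2 / replicates
  }
  expect_equal(pr$r2, h2_implied, tolerance = 0.05 / h2_implied)
  set.seed(1)
  r2_perm <- cor(sample(pr$genetic_values), f$design$y)^2
  expect_lt(r2_perm, 0.05)
})

test_that("Gibbs posterior agrees with least squares under vague priors and is seed-reproducible", {
  s <- seeded_signal_panel(55, n_lines = 100, n_snps = 30, n_transcripts = 5)
  d <- encode_design(design_spec(loci = s$qts_ids), s$genotypes,
                     phenotypes = s$phenotype)
  f <- fit_qtx(d)
  gb <- gibbs_estimate(d, gibbs_config(iterations = 4000, seed = 2))
  for (j in seq_along(coef(f))) {
    expect_lt(abs(gb$estimates$mean[j] - coef(f)[j]), 2 * gb$estimates$sd[j])
  }
  gb2 <- gibbs_estimate(d, gibbs_config(iterations = 4000, seed = 2))
  expect_identical(gb$estimates, gb2$estimates)
})

test_that("Gibbs posteriors for a constant response center at zero with small spread", {
  panel <- balanced_two_snp_panel(40)
  ph <- exact_phenotype(panel, simulation_truth(mu = 20))
  d <- encode_design(design_spec(loci = c("2L_1000_T", "2L_2000_G")),
                     panel, phenotypes = ph)
  gb <- gibbs_estimate(d, gibbs_config(iterations = 4000, seed = 3))
  eff <- gb$estimates[gb$estimates$group == "main", ]
  expect_true(all(abs(eff$mean) < 0.01))
  expect_true(all(eff$sd < 0.05))
})

test_that("replicate-level fitting agrees with line x sex means on noise-free data", {
  panel <- balanced_two_snp_panel(40)
  truth <- simulation_truth(mu = 20, qts_effects = c("2L_1000_T" = 2),
                            sex_effect = 0.5)
  ph <- exact_phenotype(panel, truth, replicates = 3)
  d_means <- encode_design(design_spec(loci = "2L_1000_T"), panel,
                           phenotypes = ph)
  d_reps <- encode_design(design_spec(loci = "2L_1000_T",
                                      observation_unit = "replicates"),
                          panel, phenotypes = ph)
  expect_equal(nrow(d_reps$X), 3 * nrow(d_means$X))
  f1 <- fit_qtx(d_means)
  f2 <- fit_qtx(d_reps)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)
  expect_equal(unname(coef(f2)[["q:2L_1000_T"]]), 2, tolerance = 1e-12)
  expect_equal(unname(coef(f2)[["sex"]]), 0.5, tolerance = 1e-12)
})
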