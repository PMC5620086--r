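# Synthetic inbred-panel generator: genotypes, expression, phenotype, files.

test_that("simulated genotypes are homozygous, complete, and respect the minor-allele floor", {
  cfg <- sim_config(n_lines = 100, n_snps = 500, min_minor_lines = 4, seed = 1)
  g <- simulate_genotypes(cfg)
  expect_true(all(g$calls %in% c(0, 2)))
  expect_false(anyNA(g$calls))
  expect_gte(min(colSums(g$calls == 2)), 4)
  # minor allele is the rarer one by construction
  expect_lte(max(colSums(g$calls == 2)), 50)
  # positions strictly increasing within chromosome
  for (ch in unique(g$snps$chrom)) {
    expect_true(all(diff(g$snps$pos[g$snps$chrom == ch]) > 0))
  }
})

test_that("genotype simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_lines = 60, n_snps = 120, seed = 42)
  expect_identical(simulate_genotypes(cfg), simulate_genotypes(cfg))
  cfg2 <- sim_config(n_lines = 60, n_snps = 120, seed = 43)
  expect_false(identical(simulate_genotypes(cfg)$calls,
                         simulate_genotypes(cfg2)$calls))
})

test_that("independent SNPs are uncorrelated on average; LD blocks are correlated", {
  cfg <- sim_config(n_lines = 200, n_snps = 100, ld_block_size = 1, seed = 7)
  g <- simulate_genotypes(cfg)
  cm <- cor(g$calls)
  off <- cm[upper.tri(cm)]
  expect_lt(abs(mean(off)), 0.02)

  cfg_ld <- sim_config(n_lines = 200, n_snps = 100, ld_block_size = 5,
                       ld_mutation_rate = 0.02, seed = 7)
  gl <- simulate_genotypes(cfg_ld)
  # within the first block of one chromosome, correlations are strong
  blk <- which(gl$snps$chrom == gl$snps$chrom[1])[1:5]
  cb <- cor(gl$calls[, blk])
  expect_gt(mean(abs(cb[upper.tri(cb)])), 0.5)
})

test_that("a panel too small for the minor-allele floor is rejected", {
  expect_error(sim_config(n_lines = 6, n_snps = 10, min_minor_lines = 4),
               "min_minor_lines")
})

test_that("noise-free cis effects shift transcripts by twice the effect between homozygote classes", {
  cfg0 <- sim_config(n_lines = 40, n_snps = 10, n_transcripts = 3,
                     residual_sd_expr = 0, seed = 5)
  g <- simulate_genotypes(cfg0)
  snp <- g$snps$id[1]
  truth <- simulation_truth(
    cis_trans_effects = data.frame(snp = snp, transcript = "T0001", effect = 2)
  )
  cfg <- sim_config(n_lines = 40, n_snps = 10, n_transcripts = 3,
                    residual_sd_expr = 0, truth = truth, seed = 5)
  e <- simulate_expression(g, cfg)
  v <- e$values[, "T0001", "female"]
  major <- v[g$calls[, snp] == 0]
  minor <- v[g$calls[, snp] == 2]
  expect_equal(unique(round(major - mean(major), 10)), 0)
  expect_equal(mean(major) - mean(minor), 4.0, tolerance = 1e-12)
})

test_that("transcript-on-transcript truth propagates exactly and rejects cycles", {
  cfg0 <- sim_config(n_lines = 30, n_snps = 10, n_transcripts = 3,
                     residual_sd_expr = 0, seed = 2)
  g <- simulate_genotypes(cfg0)
  truth <- simulation_truth(
    tt_effects = data.frame(regulator = "T0001", target = "T0002", effect = 1)
  )
  cfg <- sim_config(n_lines = 30, n_snps = 10, n_transcripts = 3,
                    residual_sd_expr = 0, truth = truth, seed = 2)
  e <- simulate_expression(g, cfg)
  # T0002 = baseline2 + 1.0 * T0001; subtracting baselines they are identical
  d <- e$values[, "T0002", "male"] - e$values[, "T0001", "male"]
  expect_equal(max(d) - min(d), 0, tolerance = 1e-12)

  cyc <- simulation_truth(tt_effects = data.frame(
    regulator = c("T0001", "T0002"), target = c("T0002", "T0001"),
    effect = c(1, 1)
  ))
  cfgc <- sim_config(n_lines = 30, n_snps = 10, n_transcripts = 3,
                     truth = cyc, seed = 2)
  expect_error(simulate_expression(g, cfgc), "acyclic")
  expect_error(
    simulation_truth(tt_effects = data.frame(regulator = "T0001",
                                             target = "T0001", effect = 1)),
    "self-regulation"
  )
})

test_that("noise-only expression has the configured residual variance", {
  n <- 300
  cfg <- sim_config(n_lines = n, n_snps = 10, n_transcripts = 5,
                    residual_sd_expr = 1.5, seed = 9)
  g <- simulate_genotypes(cfg)
  e <- simulate_expression(g, cfg)
  v <- apply(e$values, 2:3, var)
  # sampling SE of a variance estimate: sigma^2 * sqrt(2 / (n - 1))
  se <- 1.5^2 * sqrt(2 / (n - 1))
  expect_true(all(abs(v - 1.5^2) < 3 * se))
})

test_that("phenotype truth is reproduced exactly at zero noise", {
  panel <- balanced_two_snp_panel(40)
  truth <- simulation_truth(mu = 20,
                            qts_effects = c("2L_1000_T" = 2))
  ph <- exact_phenotype(panel, truth)
  m <- tapply(ph$value, ph$line, mean)[panel$line_ids]
  u <- 1 - panel$calls[, "2L_1000_T"]
  expect_equal(as.numeric(m), unname(20 + 2 * u), tolerance = 1e-12)
})

test_that("epistasis-only truth leaves single-locus means flat but splits the 2x2 cells", {
  panel <- balanced_two_snp_panel(40)
  truth <- simulation_truth(mu = 20,
                            epistasis_effects = c("2L_1000_T:2L_2000_G" = 3))
  ph <- exact_phenotype(panel, truth)
  m <- tapply(ph$value, ph$line, mean)[panel$line_ids]
  u1 <- 1 - panel$calls[, "2L_1000_T"]
  u2 <- 1 - panel$calls[, "2L_2000_G"]
  # brute force over the 2x2 genotype table: cell mean = mu + 3 * u1 * u2
  for (a in c(-1, 1)) {
    for (b in c(-1, 1)) {
      expect_equal(unname(mean(m[u1 == a & u2 == b])), 20 + 3 * a * b,
                   tolerance = 1e-12)
    }
    # single-locus group means are flat (balanced design)
    expect_equal(unname(mean(m[u1 == a])), 20, tolerance = 1e-12)
    expect_equal(unname(mean(m[u2 == a])), 20, tolerance = 1e-12)
  }
})

test_that("sex effect shifts females and males symmetrically", {
  panel <- balanced_two_snp_panel(40)
  truth <- simulation_truth(mu = 20, sex_effect = 1)  # female +1, male -1
  ph <- exact_phenotype(panel, truth)
  expect_equal(mean(ph$value[ph$sex == "female"]) -
                 mean(ph$value[ph$sex == "male"]), 2, tolerance = 1e-12)
})

test_that("out-of-range truth means warn, and bounding clips on request", {
  panel <- balanced_two_snp_panel(40)
  truth <- simulation_truth(mu = 44, qts_effects = c("2L_1000_T" = 5))
  cfg <- sim_config(n_lines = 40, n_snps = 2, truth = truth,
                    residual_sd_pheno = 0, seed = 1)
  expect_warning(simulate_phenotype(panel, cfg), "\\[0, 45\\]")
  cfgb <- sim_config(n_lines = 40, n_snps = 2, truth = truth,
                     residual_sd_pheno = 0, bound_phenotype = TRUE, seed = 1)
  ph <- suppressWarnings(simulate_phenotype(panel, cfgb)$phenotype)
  expect_lte(max(ph$value), 45)
})

test_that("make_panel writes five files plus a manifest that round-trips and is seed-stable", {
  cfg <- sim_config(n_lines = 30, n_snps = 20, n_transcripts = 5, seed = 13)
  d1 <- file.path(tempdir(), "panel_a")
  d2 <- file.path(tempdir(), "panel_b")
  m1 <- make_panel(cfg, d1)
  m2 <- make_panel(cfg, d2)
  expect_setequal(m1$file, c("genotypes.tsv", "genotypes.vcf", "expression.tsv",
                             "phenotypes.tsv", "truth.yaml"))
  expect_true(file.exists(file.path(d1, "manifest.tsv")))
  expect_identical(m1$md5, m2$md5)  # checksums stable under fixed seed

  g <- simulate_genotypes(cfg)
  g_tsv <- read_genotypes(file.path(d1, "genotypes.tsv"), "tsv")
  expect_identical(g_tsv$calls, g$calls)
  g_vcf <- read_genotypes(file.path(d1, "genotypes.vcf"), "vcf")
  expect_identical(unname(g_vcf$calls), unname(g$calls))
  expect_identical(g_vcf$snps, g$snps)

  e <- simulate_expression(g, cfg)
  e2 <- read_expression(file.path(d1, "expression.tsv"))
  expect_equal(e2$values, e$values, tolerance = 1e-12)
  unlink(c(d1, d2), recursive = TRUE)
})
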