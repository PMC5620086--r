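# Two-step detection: pre-screen, permutation critical F, 1D/2D scans,
# model selection.

# canonical-order response from a phenotype table
resp <- function(pheno, panel) startlenet:::pheno_means(pheno, panel$line_ids)

snp_P <- function(panel) startlenet:::snp_predictors(panel)$P

test_that("pre-screen retains an overwhelming signal and defaults to the P < 0.001 rule", {
  cfg_sc <- scan_config(n_permutations = 50)
  expect_equal(cfg_sc$prescreen_alpha, 0.001)
  s <- seeded_signal_panel(61, n_lines = 200, n_snps = 50, q = c(10, 0, 0),
                           resid = 2)
  y <- resp(s$phenotype, s$genotypes)
  cand <- prescreen_candidates(y, snp_P(s$genotypes), cfg_sc,
                               positions = s$genotypes$snps)
  expect_true(s$qts_ids[1] %in% cand$id)
  # candidates ordered by P
  expect_true(!is.unsorted(cand$p))
})

test_that("null pre-screen retention matches the binomial expectation", {
  set.seed(17)
  n_lines <- 100
  m <- 10000
  # independent null SNPs built directly (balanced-ish +/-1 codes)
  U <- matrix(sample(c(-1, 1), n_lines * m, replace = TRUE), n_lines, m)
  colnames(U) <- sprintf("s%05d", seq_len(m))
  P <- rbind(U, U)
  y <- rnorm(2 * n_lines)
  cand <- prescreen_candidates(y, P, scan_config(n_permutations = 50))
  ci <- qbinom(c(0.005, 0.995), m, 0.001)
  expect_gte(nrow(cand), ci[1])
  expect_lte(nrow(cand), ci[2])
})

test_that("critical F follows the order-statistic convention and is monotone in alpha", {
  s <- seeded_signal_panel(62, n_lines = 80, n_snps = 30, q = c(0, 0, 0))
  y <- resp(s$phenotype, s$genotypes)
  P <- snp_P(s$genotypes)
  cfg19 <- scan_config(n_permutations = 19, seed = 4)
  null19 <- permutation_critical_f(y, P, cfg19)
  expect_equal(null19$critical_F, max(null19$null_max))

  cfg <- scan_config(n_permutations = 100, seed = 4)
  null05 <- permutation_critical_f(y, P, cfg)
  cfg$alpha_ew <- 0.01
  null01 <- permutation_critical_f(y, P, cfg)
  expect_gte(null01$critical_F, null05$critical_F)
  expect_error(scan_config(n_permutations = 10), ">= 19")
})

test_that("experiment-wise P is add-one smoothed, floored, and never below nominal P", {
  s <- seeded_signal_panel(63, n_lines = 120, n_snps = 40, q = c(3, 0, 0))
  y <- resp(s$phenotype, s$genotypes)
  P <- snp_P(s$genotypes)
  cfg <- scan_config(n_permutations = 100, seed = 9)
  null <- permutation_critical_f(y, P, cfg)
  expect_equal(p_experimentwise(null, Inf), 1 / 101)
  expect_equal(p_experimentwise(null, -Inf), 1)
  cand <- prescreen_candidates(y, P, cfg, positions = s$genotypes$snps)
  sc <- scan_main_effects(y, P[, cand$id, drop = FALSE], null)
  expect_true(all(sc$p_ew >= sc$p_nominal - 1e-12))
})

test_that("experiment-wise P values are invariant to relabeling of lines", {
  s <- seeded_signal_panel(68, n_lines = 80, n_snps = 30, q = c(2, 0, 0))
  y <- resp(s$phenotype, s$genotypes)
  P <- snp_P(s$genotypes)
  cfg <- scan_config(n_permutations = 100, seed = 12)
  null1 <- permutation_critical_f(y, P, cfg)
  # relabel lines: apply one fixed permutation to lines of y AND P
  set.seed(5)
  idx <- sample.int(80)
  y2 <- y[c(idx, 80 + idx)]
  P2 <- P[c(idx, 80 + idx), ]
  null2 <- permutation_critical_f(y2, P2, cfg)
  f_obs <- max(startlenet:::fast_scan_stats(P, y, startlenet:::sex_contrast(80))$F_main)
  expect_equal(p_experimentwise(null1, f_obs), p_experimentwise(null2, f_obs))
})

test_that("an XOR phenotype is caught by the epistasis scan, not the main scan", {
  panel <- balanced_two_snp_panel(48)
  truth <- simulation_truth(mu = 20,
                            epistasis_effects = c("2L_1000_T:2L_2000_G" = 2))
  ph <- exact_phenotype(panel, truth)
  y <- resp(ph, panel)
  P <- snp_P(panel)
  cfg <- scan_config(n_permutations = 100, seed = 6)
  null <- permutation_critical_f(y, P, cfg)
  main <- scan_main_effects(y, P, null)
  expect_false(any(main$significant))
  epi <- scan_epistasis(y, P, cfg)
  qq <- epi$result[epi$result$type == "qq", ]
  expect_true(all(qq$significant))
  expect_equal(nrow(epi$result), 2 * choose(2, 2))  # qq + qqe for the one pair
})

test_that("the 2D scan covers k(k-1)/2 pairs and respects the pair budget", {
  s <- seeded_signal_panel(64, n_lines = 100, n_snps = 20, q = c(0, 0, 0))
  y <- resp(s$phenotype, s$genotypes)
  P <- snp_P(s$genotypes)[, 1:5]
  cfg <- scan_config(n_permutations = 50, seed = 2)
  epi <- scan_epistasis(y, P, cfg)
  expect_equal(nrow(epi$result), 2 * choose(5, 2))
  cfg$pair_budget <- 3L
  expect_warning(epi2 <- scan_epistasis(y, P, cfg), "budget")
  expect_lte(nrow(epi2$result) / 2, 3)
})

test_that("purely additive truth rarely yields false epistasis calls", {
  false_epi <- vapply(1:25, function(i) {
    s <- seeded_signal_panel(700 + i, n_lines = 100, n_snps = 30,
                             q = c(2, -2, 0))
    y <- resp(s$phenotype, s$genotypes)
    P <- snp_P(s$genotypes)[, s$qts_ids[1:2]]
    epi <- scan_epistasis(y, P, scan_config(n_permutations = 100, seed = i))
    any(epi$result$significant)
  }, logical(1))
  # alpha_EW = 0.05 per scan: expect false epistasis in <= 5% of runs + MC slack
  expect_lte(mean(false_epi), 0.05 + 2 * sqrt(0.05 * 0.95 / 25))
})

test_that("selection keeps a single overwhelming main effect and nothing else", {
  s <- seeded_signal_panel(65, n_lines = 150, n_snps = 40, q = c(4, 0, 0))
  y <- resp(s$phenotype, s$genotypes)
  P <- snp_P(s$genotypes)
  cfg <- scan_config(n_permutations = 100, seed = 3)
  cand <- prescreen_candidates(y, P, cfg, positions = s$genotypes$snps)
  null <- permutation_critical_f(y, P, cfg)
  candidates <- P[, cand$id, drop = FALSE]
  main <- scan_main_effects(y, candidates, null)
  epi <- scan_epistasis(y, candidates, cfg)
  sel <- select_model(y, candidates, main, epi, null,
                      positions = s$genotypes$snps)
  expect_identical(unique(sel$terms$source), s$qts_ids[1])
  expect_identical(sel$loci, s$qts_ids[1])
})

test_that("perfectly collinear significant SNPs resolve to the smaller genomic position", {
  cfg0 <- sim_config(n_lines = 120, n_snps = 20, seed = 19)
  g <- simulate_genotypes(cfg0)
  # duplicate SNP 5 at a larger position on the same chromosome
  dup <- g$calls[, 5]
  calls <- cbind(g$calls, dup)
  snp5 <- g$snps[5, ]
  dup_meta <- data.frame(id = paste0(snp5$chrom, "_19999999_A"),
                         chrom = snp5$chrom, pos = 19999999L,
                         major = "G", minor = "A")
  colnames(calls)[ncol(calls)] <- dup_meta$id
  g2 <- genotype_panel(calls, rbind(g$snps, dup_meta))
  truth <- simulation_truth(mu = 25,
                            qts_effects = stats::setNames(3, g$snps$id[5]))
  cfg <- sim_config(n_lines = 120, n_snps = 21, truth = truth, seed = 19)
  ph <- simulate_phenotype(g2, cfg)$phenotype
  y <- resp(ph, g2)
  P <- snp_P(g2)
  cfg_sc <- scan_config(n_permutations = 100, seed = 8)
  cand <- prescreen_candidates(y, P, cfg_sc, positions = g2$snps)
  null <- permutation_critical_f(y, P, cfg_sc)
  candidates <- P[, cand$id, drop = FALSE]
  main <- scan_main_effects(y, candidates, null)
  sel <- select_model(y, candidates, main, NULL, null, positions = g2$snps)
  expect_identical(sel$loci, g$snps$id[5])  # smaller position retained
})

test_that("the retained term set is invariant to candidate input order", {
  s <- seeded_signal_panel(66, n_lines = 150, n_snps = 30, q = c(2.5, -2, 0))
  y <- resp(s$phenotype, s$genotypes)
  P <- snp_P(s$genotypes)
  cfg <- scan_config(n_permutations = 100, seed = 10)
  cand <- prescreen_candidates(y, P, cfg, positions = s$genotypes$snps)
  null <- permutation_critical_f(y, P, cfg)
  run_sel <- function(ids) {
    candidates <- P[, ids, drop = FALSE]
    main <- scan_main_effects(y, candidates, null)
    epi <- scan_epistasis(y, candidates, cfg)
    sel <- select_model(y, candidates, main, epi, null,
                        positions = s$genotypes$snps)
    sel$terms[order(sel$terms$type, sel$terms$source), c("source", "type")]
  }
  a <- run_sel(cand$id)
  b <- run_sel(rev(cand$id))
  expect_equal(a$source, b$source)
  expect_equal(a$type, b$type)
})

test_that("an empty selection is a valid model", {
  s <- seeded_signal_panel(67, n_lines = 80, n_snps = 20, q = c(0, 0, 0))
  y <- resp(s$phenotype, s$genotypes)
  P <- snp_P(s$genotypes)
  null <- permutation_critical_f(y, P, scan_config(n_permutations = 50, seed = 1))
  main <- scan_main_effects(y, P, null)
  main$significant <- FALSE
  sel <- select_model(y, P, main, NULL, null)
  expect_identical(nrow(sel$terms), 0L)
  expect_identical(sel$loci, character(0))
})
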