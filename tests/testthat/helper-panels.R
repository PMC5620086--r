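# Fixtures built in code: tiny deterministic panels used across test files.

# A hand-crafted balanced two-SNP panel: SNP A splits lines in half, SNP B
# splits them orthogonally, so the 2x2 genotype table is perfectly balanced.
balanced_two_snp_panel <- function(n_lines = 40) {
  stopifnot(n_lines %% 4 == 0)
  q <- n_lines / 4
  a <- rep(c(0, 0, 2, 2), each = q)
  b <- rep(c(0, 2, 0, 2), each = q)
  calls <- cbind(a, b)
  rownames(calls) <- sprintf("line_%03d", seq_len(n_lines))
  colnames(calls) <- c("2L_1000_T", "2L_2000_G")
  genotype_panel(calls, data.frame(
    id = colnames(calls), chrom = "2L", pos = c(1000L, 2000L),
    major = "A", minor = c("T", "G"), stringsAsFactors = FALSE
  ))
}

# Noise-free phenotype built directly from a truth on a panel.
exact_phenotype <- function(panel, truth, replicates = 2) {
  cfg <- sim_config(
    n_lines = length(panel$line_ids), n_snps = nrow(panel$snps),
    truth = truth, residual_sd_pheno = 0, replicate_count = replicates,
    seed = 1
  )
  suppressWarnings(simulate_phenotype(panel, cfg)$phenotype)
}

# Small simulated panel with three additive QTS, used by scan/layer tests.
seeded_signal_panel <- function(seed, n_lines = 150, n_snps = 80,
                                n_transcripts = 20,
                                q = c(2, -2, 1.5), resid = 2) {
  base <- sim_config(n_lines = n_lines, n_snps = n_snps,
                     n_transcripts = n_transcripts, seed = seed)
  g <- simulate_genotypes(base)
  ids <- g$snps$id[round(seq(10, n_snps - 5, length.out = length(q)))]
  truth <- simulation_truth(
    mu = 25, qts_effects = stats::setNames(q, ids), sex_effect = 0.5,
    cis_trans_effects = data.frame(snp = ids[1], transcript = "T0003",
                                   effect = 2, stringsAsFactors = FALSE),
    tt_effects = data.frame(regulator = sprintf("T%04d", n_transcripts),
                            target = "T0003",
                            effect = 1, stringsAsFactors = FALSE)
  )
  cfg <- sim_config(n_lines = n_lines, n_snps = n_snps,
                    n_transcripts = n_transcripts, truth = truth,
                    residual_sd_pheno = resid, seed = seed)
  g <- simulate_genotypes(cfg)
  list(
    config = cfg, genotypes = g,
    expression = simulate_expression(g, cfg),
    phenotype = simulate_phenotype(g, cfg)$phenotype,
    truth = truth, qts_ids = ids
  )
}

# Independent brute-force least-squares oracle: plain normal equations.
normal_equations_oracle <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

# A small association record table exercising all layers.
example_records <- function() {
  data.frame(
    layer = c("QTS", "QTS", "QTT", "tQTT"),
    source = c("2L_1000_T", "2L_2000_G", "T0001", "T0002"),
    source2 = NA_character_,
    target = c("startle", "startle", "startle", "T0001"),
    effect = c(1.5, -0.8, 2.1, 0.9),
    effect_female = c(1.5, -0.8, 2.4, 0.9),
    effect_male = c(1.5, -0.8, 1.8, 0.9),
    effect_raw = c(1.5, -0.8, 1.0, 0.45),
    neg_log10_p_ew = c(3.3, 2.1, 3.3, 3.3),
    tier = c("ew_significant", "ew_significant", "ew_significant", "ew_significant"),
    h2 = c(0.2, 0.05, 0.3, 0.25),
    stringsAsFactors = FALSE
  )
}
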