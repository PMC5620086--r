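# Standing simulation experiments: end-to-end parameter recovery and
# family-wise error control. Used by the regression tests and the
# acceptance script so both run the exact same code path.

#' End-to-end recovery experiment on a synthetic panel
#'
#' Plants three additive QTS, two QTTs (transcripts carrying strong cis
#' effects of two of the QTS, which makes them phenotype-associated through
#' the shared locus) and two transcript-regulator (tQTT) edges on a
#' DGRP-like panel, runs the QTS, QTT and tQTT mapping layers, and checks
#' that every planted edge is recovered at the reporting tier with no false
#' edges. Effect sizes are one residual SD or more (additive effects 2 s at
#' residual SD 2 s; regulator effects 1.5 abundance units at expression
#' residual SD 1).
#'
#' @param seed RNG seed for panel simulation and permutations.
#' @param n_lines panel size (default 300).
#' @param n_snps,n_transcripts panel dimensions (defaults 100 and 30).
#' @param config a [scan_config()]; the default uses 2000 permutations (so
#'   the experiment-wise P floor clears the reporting tier) and a 4000
#'   iteration Gibbs chain.
#' @return list: `all_recovered` (logical), `false_edges` (count),
#'   `bias` (relative errors of the recovered QTS and tQTT effect
#'   estimates), `records` (the reported association records), `planted`
#'   (the planted edge keys).
#' @export
recovery_experiment <- function(seed, n_lines = 300, n_snps = 100,
                                n_transcripts = 30,
                                config = scan_config(
                                  n_permutations = 2000,
                                  gibbs = gibbs_config(iterations = 4000),
                                  seed = seed
                                )) {
  base <- sim_config(n_lines = n_lines, n_snps = n_snps,
                     n_transcripts = n_transcripts, seed = seed)
  g0 <- simulate_genotypes(base)
  # plant effects at common variants (minor allele in >= 25% of lines): the
  # +/-1 code then has variance near 1, so "effect = one residual SD" carries
  # its nominal meaning; at a minor allele carried by 4 lines the same
  # coefficient would contribute almost no phenotypic variance.
  common <- which(colSums(g0$calls == 2) >= 0.25 * n_lines)
  qts_ids <- g0$snps$id[common[round(seq(1, length(common), length.out = 3))]]
  qts_eff <- c(2, -2, 2)
  qtts <- c("T0003", "T0007")
  regulators <- c("T0011", "T0012")
  tt_eff <- c(1.5, -1.5)
  truth <- simulation_truth(
    mu = 25,
    qts_effects = stats::setNames(qts_eff, qts_ids),
    sex_effect = 0.5,
    cis_trans_effects = data.frame(
      snp = qts_ids[1:2], transcript = qtts, effect = c(2.5, 2.5),
      stringsAsFactors = FALSE
    ),
    tt_effects = data.frame(
      regulator = regulators, target = qtts, effect = tt_eff,
      stringsAsFactors = FALSE
    )
  )
  cfg <- sim_config(n_lines = n_lines, n_snps = n_snps,
                    n_transcripts = n_transcripts, truth = truth,
                    residual_sd_pheno = 2, residual_sd_expr = 1, seed = seed)
  g <- simulate_genotypes(cfg)
  e <- simulate_expression(g, cfg)
  ph <- simulate_phenotype(g, cfg)$phenotype

  sub_cfg <- function(off) { c2 <- config; c2$seed <- config$seed + off; c2 }
  qts_run <- map_layer("QTS", genotypes = g, phenotypes = ph,
                       config = sub_cfg(0L))
  qtt_run <- map_layer("QTT", expression = e, phenotypes = ph,
                       config = sub_cfg(100L))
  qtt_found <- unique(qtt_run$records$source[is.na(qtt_run$records$source2)])
  tqtt_targets <- union(qtt_found, qtts)
  tqtt_recs <- empty_records()
  for (k in seq_along(tqtt_targets)) {
    r <- map_layer("tQTT", expression = e, target = tqtt_targets[k],
                   config = sub_cfg(200L + k))
    tqtt_recs <- rbind(tqtt_recs, r$records)
  }
  records <- rbind(qts_run$records, qtt_run$records, tqtt_recs)
  reported <- records[records$neg_log10_p_ew >= config$tier_report, ,
                      drop = FALSE]

  edge_key <- function(layer, source, target) paste(layer, source, target)
  planted <- c(
    edge_key("QTS", qts_ids, "startle"),
    edge_key("QTT", qtts, "startle"),
    edge_key("tQTT", regulators, qtts)
  )
  found <- edge_key(reported$layer,
                    ifelse(is.na(reported$source2), reported$source,
                           pair_key(reported$source, reported$source2)),
                    reported$target)
  # a tQTT edge onto a planted QTT found under either of its detected runs
  false_edges <- sum(!(found %in% planted))
  all_recovered <- all(planted %in% found)

  bias <- numeric()
  for (i in seq_along(qts_ids)) {
    r <- reported[reported$layer == "QTS" & reported$source == qts_ids[i] &
                    is.na(reported$source2), , drop = FALSE]
    if (nrow(r)) bias[paste0("qts_", i)] <- (r$effect[1] - qts_eff[i]) / qts_eff[i]
  }
  for (i in seq_along(regulators)) {
    r <- reported[reported$layer == "tQTT" & reported$source == regulators[i] &
                    reported$target == qtts[i], , drop = FALSE]
    if (nrow(r)) bias[paste0("tqtt_", i)] <- (r$effect_raw[1] - tt_eff[i]) / tt_eff[i]
  }

  list(all_recovered = all_recovered, false_edges = as.integer(false_edges),
       bias = bias, records = reported, planted = planted)
}

#' Family-wise error experiment on null panels
#'
#' Simulates panels with pure-noise phenotypes (no genetic effects), runs the
#' two-step scan (pre-screen at nominal P < 0.001, then the
#' permutation-calibrated critical F at `alpha_ew`), and reports the fraction
#' of panels that declare at least one significant locus — the empirical
#' family-wise type-I error of the procedure.
#'
#' @param n_panels number of null panels (default 200).
#' @param n_lines,n_snps panel dimensions (defaults 100 and 200).
#' @param n_permutations permutations per panel (default 200).
#' @param alpha_ew experiment-wise alpha (default 0.05).
#' @param seed base seed; panel i uses `seed * 1000 + i`.
#' @return list: `fwer` (fraction of panels declaring any locus),
#'   `declared` (logical per panel), `n_panels`.
#' @export
null_fwer_experiment <- function(n_panels = 200, n_lines = 100, n_snps = 200,
                                 n_permutations = 200, alpha_ew = 0.05,
                                 seed = 1L) {
  declared <- logical(n_panels)
  for (i in seq_len(n_panels)) {
    pseed <- seed * 1000L + i
    cfg <- sim_config(n_lines = n_lines, n_snps = n_snps, n_transcripts = 0,
                      residual_sd_pheno = 1, seed = pseed)
    g <- simulate_genotypes(cfg)
    set.seed(pseed + 500000L)
    y <- stats::rnorm(2L * n_lines)   # pure Gaussian noise phenotype
    sc <- scan_config(n_permutations = n_permutations, alpha_ew = alpha_ew,
                      seed = pseed)
    pred <- snp_predictors(g)
    cand <- prescreen_candidates(y, pred$P, sc, positions = pred$positions)
    if (!nrow(cand)) next
    null <- permutation_critical_f(y, pred$P, sc)
    candidates <- pred$P[, cand$id, drop = FALSE]
    main <- scan_main_effects(y, candidates, null)
    hit <- any(main$significant)
    if (!hit && ncol(candidates) >= 2L) {
      epi <- scan_epistasis(y, candidates, sc)
      hit <- any(epi$result$significant)
    }
    declared[i] <- hit
  }
  list(fwer = mean(declared), declared = declared, n_panels = n_panels)
}
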