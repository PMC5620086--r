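#' Apply the study's SNP hygiene filters
#'
#' Removes SNPs whose minor allele is carried by fewer than
#' `min_minor_lines` lines, SNPs called in fewer than `min_called_lines`
#' lines (inbred panels here carry no missing data, so the called count is
#' the panel size unless a per-SNP `called_lines` metadata column is
#' supplied), and SNPs on excluded chromosomes (the very short chromosome 4
#' by default). Optionally restricts to autosomes.
#'
#' @param panel a [genotype_panel()].
#' @param min_minor_lines minimum lines carrying the minor allele (default 4).
#' @param min_called_lines minimum lines with a call (default 60).
#' @param exclude_chroms chromosomes to drop entirely (default "4").
#' @param autosomes_only drop X-linked SNPs too? Default FALSE.
#' @return list(panel = filtered panel, report = named removal counts per
#'   rule plus input/output totals).
#' @export
apply_snp_filters <- function(panel, min_minor_lines = 4, min_called_lines = 60,
                              exclude_chroms = "4", autosomes_only = FALSE) {
  stopifnot(inherits(panel, "genotype_panel"))
  n_in <- nrow(panel$snps)
  removed <- c(minor_lines = 0L, called_lines = 0L, excluded_chrom = 0L,
               non_autosomal = 0L)
  drop <- rep(FALSE, n_in)

  bad <- panel$snps$chrom %in% exclude_chroms & !drop
  removed[["excluded_chrom"]] <- sum(bad); drop <- drop | bad

  if (autosomes_only) {
    bad <- panel$snps$chrom %in% c("X", "Y") & !drop
    removed[["non_autosomal"]] <- sum(bad); drop <- drop | bad
  }

  called <- if ("called_lines" %in% names(panel$snps)) {
    panel$snps$called_lines
  } else {
    rep(length(panel$line_ids), n_in)
  }
  bad <- called < min_called_lines & !drop
  removed[["called_lines"]] <- sum(bad); drop <- drop | bad

  bad <- minor_line_count(panel) < min_minor_lines & !drop
  removed[["minor_lines"]] <- sum(bad); drop <- drop | bad

  if (all(drop)) stopf("all %d SNPs removed by the filters", n_in)
  keep <- which(!drop)
  out <- genotype_panel(panel$calls[, keep, drop = FALSE],
                        panel$snps[keep, , drop = FALSE])
  list(panel = out,
       report = c(removed, input = n_in, output = length(keep)))
}

# ---- predictor construction -------------------------------------------------

# SNP predictor matrix in canonical observation order (+/-1 codes).
snp_predictors <- function(panel) {
  u <- u_matrix(panel)
  P <- rbind(u, u)
  list(P = P, positions = panel$snps[, c("id", "chrom", "pos")],
       scales = stats::setNames(rep(1, ncol(P)), colnames(P)))
}

# Transcript predictor matrix, standardized per sex.
transcript_predictors <- function(expr, exclude = NULL) {
  ids <- setdiff(expr$transcript_ids, exclude)
  n <- length(expr$line_ids)
  P <- matrix(NA_real_, 2L * n, length(ids), dimnames = list(NULL, ids))
  scales <- stats::setNames(numeric(length(ids)), ids)
  for (tr in ids) {
    v <- transcript_obs(expr, tr)
    sds <- numeric(2L)
    for (b in 1:2) {
      idx <- seq_len(n) + (b - 1L) * n
      mu <- mean(v[idx]); sd <- stats::sd(v[idx])
      sds[b] <- sd
      v[idx] <- if (sd > 0) (v[idx] - mu) / sd else 0
    }
    P[, tr] <- v
    scales[tr] <- mean(sds)
  }
  list(P = P, positions = NULL, scales = scales)
}

# Build a qtx_design directly from selected scan terms (term-level model:
# a locus may carry a qe term without its main term, which design_spec's
# hierarchical surface cannot express).
design_from_terms <- function(terms, predictors, y, line_ids, scales,
                              response = "phenotype") {
  n <- length(line_ids)
  s <- sex_contrast(n)
  cols <- list(`(mu)` = rep(1, 2L * n), sex = s)
  tt <- data.frame(
    name = c("(mu)", "sex"), group = c("intercept", "sex"),
    id1 = NA_character_, id2 = NA_character_, scale = 1,
    stringsAsFactors = FALSE
  )
  grp <- c(main = "main", qq = "pair", qe = "qe", qqe = "qqe")
  for (r in seq_len(nrow(terms))) {
    g <- predictors[, terms$source[r]]
    sc <- scales[[terms$source[r]]]
    nm <- paste0(terms$type[r], ":", terms$source[r])
    if (!is.na(terms$source2[r])) {
      g <- g * predictors[, terms$source2[r]]
      sc <- sc * scales[[terms$source2[r]]]
      nm <- paste0(nm, ":", terms$source2[r])
    }
    if (terms$type[r] %in% c("qe", "qqe")) g <- g * s
    cols[[nm]] <- g
    tt[nrow(tt) + 1L, ] <- list(nm, grp[[terms$type[r]]], terms$source[r],
                                terms$source2[r], sc)
  }
  X <- do.call(cbind, cols)
  colnames(X) <- tt$name
  spec <- design_spec(response = response)
  structure(
    list(X = X, y = y, obs = obs_frame(line_ids), terms = tt, spec = spec,
         n_lines = n, line_ids = line_ids),
    class = "qtx_design"
  )
}

empty_records <- function() {
  data.frame(
    layer = character(), source = character(), source2 = character(),
    target = character(), effect = numeric(), effect_female = numeric(),
    effect_male = numeric(), effect_raw = numeric(),
    neg_log10_p_ew = numeric(), tier = character(), h2 = numeric(),
    stringsAsFactors = FALSE
  )
}

#' Run one association-mapping layer
#'
#' Executes the full two-step machinery for one of the four layers —
#' QTS (SNP -> phenotype), QTT (transcript -> phenotype), tQTS
#' (SNP -> transcript) and tQTT (transcript -> transcript) — on the given
#' panel data: pre-screen, permutation-calibrated critical F, 1D and 2D
#' scans, multi-locus model selection, Gibbs effect estimation and
#' heritability decomposition, emitting one association record per retained
#' source (locus or epistatic pair). For tQTT the target transcript is
#' excluded from its own predictor set.
#'
#' @param layer "QTS", "QTT", "tQTS" or "tQTT".
#' @param genotypes a [genotype_panel()] (QTS/tQTS layers).
#' @param expression an [expression_panel()] (QTT/tQTT layers and transcript
#'   responses).
#' @param phenotypes a [phenotype_table()] (QTS/QTT layers).
#' @param target the response transcript id (tQTS/tQTT layers).
#' @param config a [scan_config()].
#' @param trait name of the phenotype node/target (default "startle").
#' @return An object of class `layer_result`: list(records, fit, gibbs,
#'   heritability, selection, null, layer, target).
#' @export
map_layer <- function(layer = c("QTS", "QTT", "tQTS", "tQTT"),
                      genotypes = NULL, expression = NULL, phenotypes = NULL,
                      target = NULL, config = scan_config(),
                      trait = "startle") {
  layer <- match.arg(layer)
  snp_layer <- layer %in% c("QTS", "tQTS")
  pheno_layer <- layer %in% c("QTS", "QTT")

  if (snp_layer && is.null(genotypes)) stopf("%s layer needs genotypes", layer)
  if (!snp_layer && is.null(expression)) stopf("%s layer needs expression", layer)
  if (pheno_layer && is.null(phenotypes)) stopf("%s layer needs phenotypes", layer)
  if (!pheno_layer && is.null(target)) stopf("%s layer needs a target transcript", layer)

  line_ids <- if (!is.null(genotypes)) genotypes$line_ids else expression$line_ids
  if (!is.null(genotypes) && !is.null(expression) &&
      !setequal(genotypes$line_ids, expression$line_ids)) {
    stopf("genotype and expression panels disagree on line ids")
  }

  pred <- if (snp_layer) snp_predictors(genotypes)
          else transcript_predictors(expression,
                                     exclude = if (layer == "tQTT") target)
  y <- if (pheno_layer) pheno_means(phenotypes, line_ids)
       else transcript_obs(expression, target, line_ids)
  target_name <- if (pheno_layer) trait else target

  out <- structure(
    list(records = empty_records(), fit = NULL, gibbs = NULL,
         heritability = NULL, selection = NULL, null = NULL,
         layer = layer, target = target_name),
    class = "layer_result"
  )

  set.seed(config$seed)
  cand <- prescreen_candidates(y, pred$P, config, positions = pred$positions)
  if (!nrow(cand)) return(out)

  null <- permutation_critical_f(y, pred$P, config)
  out$null <- null
  candidates <- pred$P[, cand$id, drop = FALSE]
  main_scan <- scan_main_effects(y, candidates, null)
  epi_scan <- scan_epistasis(y, candidates, config)
  sel <- select_model(y, candidates, main_scan, epi_scan, null,
                      positions = pred$positions)
  out$selection <- sel
  if (!nrow(sel$terms)) return(out)

  design <- design_from_terms(sel$terms, pred$P, y, line_ids, pred$scales,
                              response = if (pheno_layer) "phenotype" else target)
  fit <- fit_qtx(design)
  gcfg <- config$gibbs
  gcfg$seed <- config$seed + 7L
  gibbs <- gibbs_estimate(design, gcfg)
  herit <- heritability(fit)
  out$fit <- fit
  out$gibbs <- gibbs
  out$heritability <- herit
  out$records <- build_records(layer, sel$terms, design, gibbs, herit,
                               target_name, config)
  out
}

#' @export
print.layer_result <- function(x, ...) {
  cat(sprintf("%s layer -> %s: %d association record(s)\n",
              x$layer, x$target, nrow(x$records)))
  if (nrow(x$records)) print(x$records, digits = 4, row.names = FALSE)
  invisible(x)
}

# One association record per retained source (locus or pair), aggregating its
# main and sex-interaction terms. Effects are Gibbs posterior means on the
# encoded (standardized) predictor scale; effect_raw converts back to the raw
# predictor scale for recovery checks.
build_records <- function(layer, terms, design, gibbs, herit, target, config) {
  gb <- gibbs_coefs(gibbs)
  h_term <- herit$per_term
  key <- ifelse(is.na(terms$source2), terms$source,
                pair_key(terms$source, terms$source2))
  recs <- lapply(unique(key), function(k) {
    rows <- terms[key == k, , drop = FALSE]
    is_pair <- !is.na(rows$source2[1L])
    main_type <- if (is_pair) c("qq") else c("main")
    sex_type <- if (is_pair) c("qqe") else c("qe")
    nm <- function(type, r) {
      paste0(type, ":", rows$source[1L],
             if (is_pair) paste0(":", rows$source2[1L]) else "")
    }
    coef_of <- function(type) {
      n <- nm(type)
      if (n %in% names(gb)) unname(gb[[n]]) else 0
    }
    main <- if (any(rows$type %in% main_type)) coef_of(main_type) else 0
    qe <- if (any(rows$type %in% sex_type)) coef_of(sex_type) else 0
    term_names <- paste0(rows$type, ":", rows$source,
                         ifelse(is.na(rows$source2), "",
                                paste0(":", rows$source2)))
    scale <- design$terms$scale[match(term_names[1L], design$terms$name)]
    p_ew <- min(rows$p_ew)
    nl <- -log10(p_ew)
    data.frame(
      layer = layer,
      source = rows$source[1L],
      source2 = if (is_pair) rows$source2[1L] else NA_character_,
      target = target,
      effect = main,
      effect_female = main + qe,
      effect_male = main - qe,
      effect_raw = main / scale,
      neg_log10_p_ew = nl,
      tier = if (nl >= config$tier_high) "ew_high" else "ew_significant",
      h2 = sum(h_term[term_names], na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, recs)
}

#' Run the complete four-layer study
#'
#' Orchestrates the full multi-omics pipeline on one panel: SNP filtering,
#' QTS mapping (SNP -> phenotype), QTT mapping (transcript -> phenotype),
#' then — for each significant QTT transcript — tQTS (SNP -> transcript) and
#' tQTT (transcript -> transcript) mapping. Association tables, a
#' per-layer heritability summary and a machine-readable run manifest are
#' returned, and written as TSV/YAML when `out_dir` is given. The pipeline
#' is deterministic under `config$seed`.
#'
#' @param genotypes a [genotype_panel()].
#' @param expression an [expression_panel()].
#' @param phenotypes a [phenotype_table()].
#' @param config a [scan_config()].
#' @param trait phenotype name (default "startle").
#' @param filters arguments forwarded to [apply_snp_filters()].
#' @param qtt_tier restrict t-layer targets to QTTs at this tier
#'   (NULL = all significant QTTs, the default).
#' @param out_dir optional output directory.
#' @return An object of class `study_result`: association tables per layer,
#'   combined table, heritability summary, filter report, layer results and
#'   manifest.
#' @export
run_full_study <- function(genotypes, expression, phenotypes,
                           config = scan_config(), trait = "startle",
                           filters = list(), qtt_tier = NULL,
                           out_dir = NULL) {
  stopifnot(inherits(genotypes, "genotype_panel"),
            inherits(expression, "expression_panel"),
            inherits(phenotypes, "phenotype_table"))
  if (!setequal(genotypes$line_ids, expression$line_ids)) {
    stopf("stage cross-validation: genotype and expression line ids differ")
  }
  if (length(bad <- setdiff(unique(phenotypes$line), genotypes$line_ids))) {
    stopf("stage cross-validation: phenotype line %s absent from genotypes", bad[1L])
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  flt <- stage("snp_filters",
               do.call(apply_snp_filters, c(list(genotypes), filters)))
  sub_cfg <- function(offset) {
    cfg <- config
    cfg$seed <- config$seed + offset
    cfg
  }

  qts <- stage("QTS", map_layer("QTS", genotypes = flt$panel,
                                phenotypes = phenotypes,
                                config = sub_cfg(0L), trait = trait))
  qtt <- stage("QTT", map_layer("QTT", expression = expression,
                                phenotypes = phenotypes,
                                config = sub_cfg(100L), trait = trait))

  qtt_transcripts <- unique(qtt$records$source[is.na(qtt$records$source2)])
  if (!is.null(qtt_tier) && length(qtt_transcripts)) {
    keep <- qtt$records$tier %in% qtt_tier & is.na(qtt$records$source2)
    qtt_transcripts <- unique(qtt$records$source[keep])
  }
  tqts_list <- list(); tqtt_list <- list()
  if (!length(qtt_transcripts)) {
    warnf("no significant QTTs; tQTS/tQTT layers are empty")
  } else {
    for (k in seq_along(qtt_transcripts)) {
      tr <- qtt_transcripts[k]
      tqts_list[[tr]] <- stage(paste0("tQTS:", tr),
        map_layer("tQTS", genotypes = flt$panel, expression = expression,
                  target = tr, config = sub_cfg(200L + k)))
      tqtt_list[[tr]] <- stage(paste0("tQTT:", tr),
        map_layer("tQTT", expression = expression, target = tr,
                  config = sub_cfg(300L + k)))
    }
  }

  bind_records <- function(results) {
    recs <- lapply(results, `[[`, "records")
    if (!length(recs)) return(empty_records())
    do.call(rbind, c(recs, list(empty_records())))
  }
  tables <- list(
    QTS = qts$records, QTT = qtt$records,
    tQTS = bind_records(tqts_list), tQTT = bind_records(tqtt_list)
  )

  herit_row <- function(res) {
    if (is.null(res$heritability)) {
      h <- list(h2_Q = 0, h2_QQ = 0, h2_QE = 0, h2_QQE = 0, h2_T = 0)
      r2 <- NA_real_
    } else {
      h <- res$heritability
      r2 <- suppressWarnings(predict_r2(res$fit)$r2)
    }
    data.frame(layer = res$layer, target = res$target,
               h2_Q = h$h2_Q, h2_QQ = h$h2_QQ, h2_QE = h$h2_QE,
               h2_QQE = h$h2_QQE, h2_T = h$h2_T, r2 = r2,
               stringsAsFactors = FALSE)
  }
  herit <- do.call(rbind, lapply(c(list(qts, qtt), tqts_list, tqtt_list),
                                 herit_row))
  rownames(herit) <- NULL

  manifest <- list(
    package = "startlenet",
    version = as.character(utils::packageVersion("startlenet")),
    seed = config$seed,
    n_permutations = config$n_permutations,
    prescreen_alpha = config$prescreen_alpha,
    alpha_ew = config$alpha_ew,
    gibbs_iterations = config$gibbs$iterations,
    trait = trait,
    n_lines = length(genotypes$line_ids),
    n_snps_input = unname(flt$report[["input"]]),
    n_snps_used = unname(flt$report[["output"]]),
    n_transcripts = length(expression$transcript_ids),
    qtt_targets = as.list(qtt_transcripts)
  )

  combined <- do.call(rbind, tables)
  rownames(combined) <- NULL
  out <- structure(
    list(tables = tables,
         combined = combined,
         heritability = herit, filter_report = flt$report,
         layers = c(list(QTS = qts, QTT = qtt),
                    list(tQTS = tqts_list, tQTT = tqtt_list)),
         manifest = manifest),
    class = "study_result"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (ly in names(tables)) {
      write_association_table(tables[[ly]],
                              file.path(out_dir, paste0(tolower(ly), ".tsv")))
    }
    hh <- herit
    hh$r2 <- ifelse(is.na(hh$r2), "NA", sprintf("%.6f", hh$r2))
    for (nm in c("h2_Q", "h2_QQ", "h2_QE", "h2_QQE", "h2_T")) {
      hh[[nm]] <- sprintf("%.6f", herit[[nm]])
    }
    utils::write.table(hh, file.path(out_dir, "heritability.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  out
}

#' @export
print.study_result <- function(x, ...) {
  cat("Four-layer association study\n")
  for (ly in names(x$tables)) {
    cat(sprintf("  %-5s: %d record(s)\n", ly, nrow(x$tables[[ly]])))
  }
  cat("heritability summary:\n")
  print(x$heritability, digits = 3, row.names = FALSE)
  invisible(x)
}
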