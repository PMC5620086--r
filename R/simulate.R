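#' Ground-truth effect set for a simulated panel
#'
#' Holds the parameters of the generating mixed linear model for the startle
#' phenotype (population mean, additive locus effects, epistatic pair effects,
#' sex effect, locus-by-sex and pair-by-sex interactions) together with the
#' regulatory truth of the expression layer (cis/trans SNP-on-transcript
#' effects and transcript-on-transcript effects).
#'
#' Sex-interaction effects use sum-to-zero coding: a single number per locus
#' (or pair) is the female-side effect, the male-side effect is its negative.
#' The phenotype for line k, sex h is
#' `mu + sum q_i u_ik + sum qq_ij u_ijk + e_h + sum qe_ih u_ik s_h +
#'  sum qqe_ijh u_ijk s_h + eps`, with `u` the +/-1 genotype code,
#' `u_ijk = u_ik u_jk`, and `s_h` the +1 female / -1 male contrast.
#'
#' @param mu population mean of the phenotype (seconds).
#' @param qts_effects named numeric, SNP id -> additive effect q_i.
#' @param epistasis_effects named numeric, "id1:id2" -> epistasis effect qq_ij.
#' @param sex_effect female-side sex main effect e_female (e_male = -e_female).
#' @param qe_effects named numeric, SNP id -> female-side locus-by-sex effect.
#' @param qqe_effects named numeric, "id1:id2" -> female-side pair-by-sex effect.
#' @param cis_trans_effects data.frame(snp, transcript, effect): SNP effects on
#'   transcript abundance (+/-1 coding of the SNP).
#' @param tt_effects data.frame(regulator, target, effect): directed
#'   transcript-on-transcript effects; must be acyclic, no self-regulation.
#' @param expr_sex_effects named numeric, transcript id -> female-side sex
#'   effect on abundance.
#' @return An object of class `simulation_truth`.
#' @export
simulation_truth <- function(mu = 20,
                             qts_effects = numeric(),
                             epistasis_effects = numeric(),
                             sex_effect = 0,
                             qe_effects = numeric(),
                             qqe_effects = numeric(),
                             cis_trans_effects = NULL,
                             tt_effects = NULL,
                             expr_sex_effects = numeric()) {
  df0 <- function(x, cols) {
    if (is.null(x)) {
      x <- as.data.frame(setNames(rep(list(character()), length(cols)), cols))
      x$effect <- numeric()
      return(x)
    }
    x <- as.data.frame(x, stringsAsFactors = FALSE)
    stopifnot(all(c(cols, "effect") %in% names(x)))
    x
  }
  cis <- df0(cis_trans_effects, c("snp", "transcript"))
  tt <- df0(tt_effects, c("regulator", "target"))
  if (nrow(tt) && any(tt$regulator == tt$target)) {
    stopf("self-regulation is not allowed in tt_effects (transcript %s)",
          tt$target[tt$regulator == tt$target][1L])
  }
  named_num <- function(x, what) {
    x <- unlist(x)
    if (length(x) && is.null(names(x))) stopf("%s must be named", what)
    if (!length(x)) x <- stats::setNames(numeric(), character())
    x
  }
  structure(
    list(
      mu = mu,
      qts_effects = named_num(qts_effects, "qts_effects"),
      epistasis_effects = named_num(epistasis_effects, "epistasis_effects"),
      sex_effect = sex_effect,
      qe_effects = named_num(qe_effects, "qe_effects"),
      qqe_effects = named_num(qqe_effects, "qqe_effects"),
      cis_trans_effects = cis,
      tt_effects = tt,
      expr_sex_effects = named_num(expr_sex_effects, "expr_sex_effects")
    ),
    class = "simulation_truth"
  )
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf(
    paste0("simulation_truth: mu = %g, %d QTS, %d epistatic pair(s), ",
           "sex effect %+g/%+g (f/m),\n  %d qe, %d qqe, %d cis/trans, %d tt edge(s)\n"),
    x$mu, length(x$qts_effects), length(x$epistasis_effects),
    x$sex_effect, -x$sex_effect, length(x$qe_effects), length(x$qqe_effects),
    nrow(x$cis_trans_effects), nrow(x$tt_effects)
  ))
  invisible(x)
}

#' Configuration of the synthetic inbred-panel generator
#'
#' Defaults emulate the structure of the DGRP startle study at reduced scale:
#' 156 fully inbred lines, homozygous biallelic SNPs with the minor allele in
#' at least 4 lines, sex-stratified expression, two phenotype replicates per
#' line and sex, phenotype measured in seconds of a 45 s assay.
#'
#' @param n_lines number of inbred lines.
#' @param n_snps number of SNPs.
#' @param n_transcripts number of transcripts.
#' @param min_minor_lines minimum lines carrying the minor allele (default 4).
#' @param chromosomes named integer of SNPs per chromosome arm, or character
#'   vector of labels (SNPs then split evenly).
#' @param ld_block_size SNPs per correlated LD block; 1 = independent SNPs.
#' @param ld_mutation_rate per-line flip probability when copying the block
#'   haplotype, controls within-block correlation.
#' @param truth a [simulation_truth()].
#' @param residual_sd_pheno residual SD of the phenotype (seconds).
#' @param residual_sd_expr residual SD of transcript abundance.
#' @param replicate_count phenotype replicates per line x sex (default 2).
#' @param bound_phenotype clip simulated phenotypes to the \[0, 45\] s assay
#'   range? Default FALSE so the generating model stays linear-Gaussian.
#' @param seed integer RNG seed; fixed seed gives byte-identical panels.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_lines = 156,
                       n_snps = 500,
                       n_transcripts = 100,
                       min_minor_lines = 4,
                       chromosomes = c("X", "2L", "2R", "3L", "3R"),
                       ld_block_size = 1,
                       ld_mutation_rate = 0.05,
                       truth = simulation_truth(),
                       residual_sd_pheno = 2,
                       residual_sd_expr = 1,
                       replicate_count = 2,
                       bound_phenotype = FALSE,
                       seed = 1L) {
  stopifnot(is_count(n_lines, 1), is_count(n_snps, 1), is_count(n_transcripts, 0),
            is_count(min_minor_lines, 1), is_count(ld_block_size, 1),
            is_count(replicate_count, 1))
  if (n_lines < 2 * min_minor_lines) {
    stopf("n_lines (%d) must be at least 2 * min_minor_lines (%d) so both alleles can reach the minimum line count",
          n_lines, 2 * min_minor_lines)
  }
  if (residual_sd_pheno < 0 || residual_sd_expr < 0) {
    stopf("residual SDs must be non-negative")
  }
  if (is.character(chromosomes)) {
    alloc <- rep(n_snps %/% length(chromosomes), length(chromosomes))
    alloc[seq_len(n_snps %% length(chromosomes))] <-
      alloc[seq_len(n_snps %% length(chromosomes))] + 1L
    chromosomes <- stats::setNames(alloc, chromosomes)
  }
  if (sum(chromosomes) != n_snps) {
    stopf("chromosome SNP allocation (%d) must sum to n_snps (%d)",
          sum(chromosomes), n_snps)
  }
  stopifnot(inherits(truth, "simulation_truth"))
  structure(
    list(
      n_lines = as.integer(n_lines), n_snps = as.integer(n_snps),
      n_transcripts = as.integer(n_transcripts),
      min_minor_lines = as.integer(min_minor_lines),
      chromosomes = chromosomes,
      ld_block_size = as.integer(ld_block_size),
      ld_mutation_rate = ld_mutation_rate,
      truth = truth,
      residual_sd_pheno = residual_sd_pheno,
      residual_sd_expr = residual_sd_expr,
      replicate_count = as.integer(replicate_count),
      bound_phenotype = isTRUE(bound_phenotype),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate homozygous inbred-line genotypes
#'
#' Draws fully homozygous biallelic SNP calls for an inbred panel. Within an
#' LD block the first SNP's minor-line set is copied to the others with a
#' per-line mutation probability, inducing a controllable block correlation;
#' with `ld_block_size = 1` SNPs are independent. Every SNP's minor allele is
#' guaranteed present in at least `min_minor_lines` lines (sites are repaired
#' after mutation if needed, mirroring the study's minor-allele filter).
#'
#' @param config a [sim_config()].
#' @return A [genotype_panel()].
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_lines
  line_ids <- sprintf("line_%03d", seq_len(n))
  bases <- c("A", "C", "G", "T")

  chrom <- rep(names(config$chromosomes), config$chromosomes)
  pos <- integer(config$n_snps)
  for (ch in names(config$chromosomes)) {
    k <- config$chromosomes[[ch]]
    pos[chrom == ch] <- sort(sample.int(20e6L, k))
  }
  alle <- t(vapply(seq_len(config$n_snps),
                   function(i) sample(bases, 2L), character(2L)))

  calls <- matrix(0, n, config$n_snps)
  max_minor <- floor(n / 2)
  i <- 1L
  while (i <= config$n_snps) {
    blk <- i:min(i + config$ld_block_size - 1L, config$n_snps)
    # block haplotype: which lines carry the minor allele
    m <- if (config$min_minor_lines >= max_minor) config$min_minor_lines else
      sample(config$min_minor_lines:max_minor, 1L)
    base_minor <- logical(n)
    base_minor[sample.int(n, m)] <- TRUE
    for (j in blk) {
      minor <- base_minor
      if (length(blk) > 1L) {
        flip <- stats::runif(n) < config$ld_mutation_rate
        minor <- xor(minor, flip)
      }
      # repair: minor allele must be the rarer one and present in >= min lines
      if (sum(minor) > n - sum(minor)) minor <- !minor
      short <- config$min_minor_lines - sum(minor)
      if (short > 0L) {
        minor[sample(which(!minor), short)] <- TRUE
      }
      calls[, j] <- ifelse(minor, 2, 0)
    }
    i <- max(blk) + 1L
  }

  snps <- data.frame(
    id = paste(chrom, pos, alle[, 2L], sep = "_"),
    chrom = chrom, pos = pos, major = alle[, 1L], minor = alle[, 2L],
    stringsAsFactors = FALSE
  )
  dimnames(calls) <- list(line_ids, snps$id)
  genotype_panel(calls, snps)
}

# Topological order of transcript-on-transcript truth; errors on cycles.
tt_topo_order <- function(tt, transcript_ids) {
  if (!nrow(tt)) return(transcript_ids)
  g <- igraph::graph_from_data_frame(
    tt[, c("regulator", "target")],
    vertices = data.frame(name = transcript_ids)
  )
  if (!igraph::is_dag(g)) {
    stopf("tt_effects must form a directed acyclic structure (cycle detected)")
  }
  names(igraph::topo_sort(g, mode = "out"))
}

#' Simulate sex-stratified transcript abundance
#'
#' Each transcript's abundance per line and sex is a baseline plus cis/trans
#' SNP effects (on the +/-1 genotype code), transcript-regulator effects
#' (evaluated in topological order over the acyclic regulatory truth), a
#' sex effect, and Gaussian noise.
#'
#' @param panel a [genotype_panel()].
#' @param config a [sim_config()]; its `truth` supplies the regulatory effects.
#' @return An [expression_panel()].
#' @export
simulate_expression <- function(panel, config) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  truth <- config$truth
  n <- length(panel$line_ids)
  tids <- sprintf("T%04d", seq_len(config$n_transcripts))

  refs <- unique(c(truth$cis_trans_effects$transcript,
                   truth$tt_effects$regulator, truth$tt_effects$target))
  if (length(bad <- setdiff(refs, tids))) {
    stopf("truth references unknown transcript(s): %s", paste(bad, collapse = ", "))
  }
  if (length(bad <- setdiff(truth$cis_trans_effects$snp, panel$snps$id))) {
    stopf("truth references unknown SNP(s): %s", paste(bad, collapse = ", "))
  }

  baseline <- stats::rnorm(config$n_transcripts, mean = 8, sd = 1.5)
  names(baseline) <- tids
  u <- u_matrix(panel)

  vals <- array(
    0, dim = c(n, config$n_transcripts, 2L),
    dimnames = list(panel$line_ids, tids, c("female", "male"))
  )
  ord <- tt_topo_order(truth$tt_effects, tids)
  sexes <- c(female = 1, male = -1)
  noise <- array(stats::rnorm(n * config$n_transcripts * 2L,
                              sd = config$residual_sd_expr),
                 dim = dim(vals))
  for (tr in ord) {
    g <- rep(baseline[[tr]], n)
    ct <- truth$cis_trans_effects[truth$cis_trans_effects$transcript == tr, ]
    for (r in seq_len(nrow(ct))) {
      g <- g + ct$effect[r] * u[, ct$snp[r]]
    }
    tt <- truth$tt_effects[truth$tt_effects$target == tr, ]
    ti <- match(tr, tids)
    se <- if (tr %in% names(truth$expr_sex_effects)) truth$expr_sex_effects[[tr]] else 0
    for (sx in names(sexes)) {
      v <- g + sexes[[sx]] * se
      for (r in seq_len(nrow(tt))) {
        v <- v + tt$effect[r] * vals[, tt$regulator[r], sx]
      }
      vals[, ti, sx] <- v + noise[, ti, match(sx, names(sexes))]
    }
  }
  expression_panel(vals)
}

# Line x sex genetic values implied by the truth (phenotype scale, no noise).
truth_genetic_values <- function(panel, truth) {
  u <- u_matrix(panel)
  n <- nrow(u)
  g <- matrix(truth$mu, n, 2L, dimnames = list(panel$line_ids, c("female", "male")))
  for (id in names(truth$qts_effects)) {
    g <- g + truth$qts_effects[[id]] * u[, id]
  }
  for (key in names(truth$epistasis_effects)) {
    p <- split_pair_key(key)[[1L]]
    g <- g + truth$epistasis_effects[[key]] * (u[, p[1L]] * u[, p[2L]])
  }
  s <- c(female = 1, male = -1)
  for (sx in colnames(g)) {
    g[, sx] <- g[, sx] + s[[sx]] * truth$sex_effect
    for (id in names(truth$qe_effects)) {
      g[, sx] <- g[, sx] + s[[sx]] * truth$qe_effects[[id]] * u[, id]
    }
    for (key in names(truth$qqe_effects)) {
      p <- split_pair_key(key)[[1L]]
      g[, sx] <- g[, sx] + s[[sx]] * truth$qqe_effects[[key]] * (u[, p[1L]] * u[, p[2L]])
    }
  }
  g
}

#' Simulate replicated startle phenotypes
#'
#' Builds line x sex genetic values exactly from the mixed linear model truth
#' (additive + epistatic + sex + sex-interaction terms) and adds independent
#' Gaussian residuals per replicate. Values are clipped to the \[0, 45\] s
#' assay range only when `config$bound_phenotype` is TRUE; otherwise a warning
#' is raised if the truth implies out-of-range means.
#'
#' @param panel a [genotype_panel()].
#' @param config a [sim_config()].
#' @return A list with elements `phenotype` (a [phenotype_table()]) and
#'   `truth` (the [simulation_truth()] used).
#' @export
simulate_phenotype <- function(panel, config) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(config, "sim_config"))
  truth <- config$truth
  loci <- unique(c(
    names(truth$qts_effects), names(truth$qe_effects),
    unlist(split_pair_key(names(truth$epistasis_effects))),
    unlist(split_pair_key(names(truth$qqe_effects)))
  ))
  if (length(bad <- setdiff(loci, panel$snps$id))) {
    stopf("truth references SNP(s) absent from the panel: %s",
          paste(bad, collapse = ", "))
  }
  set.seed(config$seed + 2L)
  g <- truth_genetic_values(panel, truth)
  if (any(g < 0 | g > 45)) {
    if (config$bound_phenotype) {
      warnf("truth implies line x sex means outside [0, 45] s; values will be clipped")
    } else {
      warnf("truth implies line x sex means outside [0, 45] s (phenotype left unbounded)")
    }
  }
  n <- length(panel$line_ids)
  r <- config$replicate_count
  rec <- expand.grid(
    line = panel$line_ids, sex = c("female", "male"),
    replicate = seq_len(r),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  mu <- g[cbind(match(rec$line, panel$line_ids), match(rec$sex, colnames(g)))]
  rec$value <- mu + stats::rnorm(nrow(rec), sd = config$residual_sd_pheno)
  if (config$bound_phenotype) rec$value <- pmin(pmax(rec$value, 0), 45)
  list(
    phenotype = phenotype_table(rec, check_bounds = config$bound_phenotype),
    truth = truth
  )
}

#' Write a complete synthetic panel to disk
#'
#' Simulates genotypes, expression and phenotype under `config` and writes
#' them as plain-text files (genotype TSV and VCF, expression TSV, phenotype
#' TSV, truth YAML) together with a manifest of MD5 checksums. All files
#' round-trip through the package's readers.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if absent).
#' @return Invisibly, the manifest data.frame (file, md5).
#' @export
make_panel <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory %s", out_dir)
  panel <- simulate_genotypes(config)
  expr <- simulate_expression(panel, config)
  ph <- simulate_phenotype(panel, config)

  paths <- file.path(out_dir, c(
    genotype_tsv = "genotypes.tsv", genotype_vcf = "genotypes.vcf",
    expression = "expression.tsv", phenotype = "phenotypes.tsv",
    truth = "truth.yaml"
  ))
  names(paths) <- c("genotype_tsv", "genotype_vcf", "expression", "phenotype", "truth")
  write_genotypes(panel, paths[["genotype_tsv"]], format = "tsv")
  write_genotypes(panel, paths[["genotype_vcf"]], format = "vcf")
  write_expression(expr, paths[["expression"]])
  write_phenotypes(ph$phenotype, paths[["phenotype"]])
  write_truth(ph$truth, paths[["truth"]])

  manifest <- data.frame(
    file = basename(paths),
    md5 = unname(tools::md5sum(paths)),
    stringsAsFactors = FALSE
  )
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
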