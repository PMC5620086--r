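#' Read a genotype panel from TSV or VCF
#'
#' Enforces the data-hygiene rules of inbred-panel genotypes at parse time:
#' no missing calls, every call homozygous, only biallelic sites. TSV input is
#' the minor-allele dosage matrix written by [write_genotypes()] (rows = SNP
#' id "chrom_pos_allele", columns = line ids, cells 0 or 2); since that format
#' does not carry the major allele it is read back as "N". VCF input must
#' restrict GT to 0/0 and 1/1 (REF = major allele, ALT = minor allele).
#'
#' @param path file path.
#' @param format "tsv" or "vcf".
#' @return A [genotype_panel()].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("genotype file not found: %s", path)
  if (format == "tsv") read_genotypes_tsv(path) else read_genotypes_vcf(path)
}

parse_snp_ids <- function(ids, path) {
  parts <- strsplit(ids, "_", fixed = TRUE)
  n <- lengths(parts)
  if (any(n < 3L)) {
    stopf("%s: SNP id '%s' is not of the form chrom_pos_allele",
          path, ids[which(n < 3L)[1L]])
  }
  # chromosome labels may themselves contain "_"; pos and allele are the last two
  data.frame(
    id = ids,
    chrom = vapply(parts, function(p) paste(p[seq_len(length(p) - 2L)], collapse = "_"),
                   character(1L)),
    pos = as.integer(vapply(parts, function(p) p[length(p) - 1L], character(1L))),
    minor = vapply(parts, function(p) p[length(p)], character(1L)),
    stringsAsFactors = FALSE
  )
}

read_genotypes_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1L] != "snp_id") {
    stopf("%s: first column of a genotype TSV must be 'snp_id'", path)
  }
  ids <- tab[[1L]]
  calls <- as.matrix(tab[, -1L, drop = FALSE])
  if (anyNA(calls)) {
    bad <- which(is.na(calls), arr.ind = TRUE)[1L, ]
    stopf("%s: missing call for SNP %s, line %s", path, ids[bad[1L]],
          colnames(calls)[bad[2L]])
  }
  if (!all(calls %in% c(0, 2))) {
    bad <- which(!(calls %in% c(0, 2)), arr.ind = TRUE)[1L, ]
    stopf("%s: call '%s' for SNP %s, line %s is not a homozygous dosage (0 or 2)",
          path, calls[bad[1L], bad[2L]], ids[bad[1L]], colnames(calls)[bad[2L]])
  }
  meta <- parse_snp_ids(ids, path)
  meta$major <- "N"
  calls <- t(calls)
  colnames(calls) <- ids
  genotype_panel(calls, meta[, c("id", "chrom", "pos", "major", "minor")])
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- t(fx)   # single-variant files come back as a vector
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    stopf("%s: multi-allelic site at %s:%s (only biallelic SNPs are supported)",
          path, fix$CHROM[grepl(",", fix$ALT)][1L],
          fix$POS[grepl(",", fix$ALT)][1L])
  }
  gt_norm <- gsub("|", "/", gt, fixed = TRUE)
  miss <- is.na(gt_norm) | gt_norm %in% c("./.", ".")
  if (any(miss)) {
    bad <- which(miss, arr.ind = TRUE)[1L, ]
    stopf("%s: missing genotype (no missing data allowed) at %s:%s in line %s",
          path, fix$CHROM[bad[1L]], fix$POS[bad[1L]], colnames(gt)[bad[2L]])
  }
  het <- !(gt_norm %in% c("0/0", "1/1"))
  if (any(het)) {
    bad <- which(matrix(het, nrow(gt)), arr.ind = TRUE)[1L, ]
    stopf("%s: heterozygous call '%s' (all calls must be homozygous) at %s:%s in line %s",
          path, gt[bad[1L], bad[2L]], fix$CHROM[bad[1L]], fix$POS[bad[1L]],
          colnames(gt)[bad[2L]])
  }
  calls <- ifelse(matrix(gt_norm == "1/1", nrow(gt)), 2, 0)
  snps <- data.frame(
    id = paste(fix$CHROM, fix$POS, fix$ALT, sep = "_"),
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    major = fix$REF, minor = fix$ALT, stringsAsFactors = FALSE
  )
  calls <- t(calls)
  dimnames(calls) <- list(colnames(gt), snps$id)
  genotype_panel(calls, snps)
}

#' Write a genotype panel to TSV or VCF
#'
#' @param panel a [genotype_panel()].
#' @param path output file.
#' @param format "tsv" (dosage matrix) or "vcf" (plain-text VCF, GT restricted
#'   to 0/0 and 1/1).
#' @return Invisibly, `path`.
#' @export
write_genotypes <- function(panel, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  stopifnot(inherits(panel, "genotype_panel"))
  if (format == "tsv") {
    tab <- data.frame(snp_id = panel$snps$id,
                      t(panel$calls), check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      "##fileformat=VCFv4.2",
      "##source=startlenet",
      '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", panel$line_ids), collapse = "\t")
    ), con)
    gt <- ifelse(t(panel$calls) == 2, "1/1", "0/0")
    body <- paste(
      panel$snps$chrom, panel$snps$pos, panel$snps$id, panel$snps$major,
      panel$snps$minor, ".", "PASS", ".", "GT",
      apply(gt, 1L, paste, collapse = "\t"),
      sep = "\t"
    )
    writeLines(body, con)
  }
  invisible(path)
}

#' Read/write a sex-stratified expression panel (TSV)
#'
#' Rows are transcripts, columns are `line:sex` (e.g. `line_001:female`);
#' both sex slices must be present for every line.
#'
#' @param path file path.
#' @param line_ids optional reference line-id set; lines in the expression
#'   file missing from it raise an error.
#' @return [read_expression()]: an [expression_panel()].
#' @export
read_expression <- function(path, line_ids = NULL) {
  if (!file.exists(path)) stopf("expression file not found: %s", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1L] != "transcript_id") {
    stopf("%s: first column of an expression TSV must be 'transcript_id'", path)
  }
  tids <- tab[[1L]]
  m <- as.matrix(tab[, -1L, drop = FALSE])
  cols <- strsplit(colnames(m), ":", fixed = TRUE)
  if (any(lengths(cols) != 2L)) {
    stopf("%s: expression column '%s' is not of the form line:sex", path,
          colnames(m)[which(lengths(cols) != 2L)[1L]])
  }
  cl <- vapply(cols, `[`, character(1L), 1L)
  cs <- vapply(cols, `[`, character(1L), 2L)
  if (!all(cs %in% c("female", "male"))) {
    stopf("%s: unknown sex label '%s'", path, cs[!(cs %in% c("female", "male"))][1L])
  }
  lines <- unique(cl)
  for (ln in lines) {
    have <- cs[cl == ln]
    if (!setequal(have, c("female", "male"))) {
      stopf("%s: line %s is missing its %s expression slice", path, ln,
            setdiff(c("female", "male"), have))
    }
  }
  if (!is.null(line_ids) && length(bad <- setdiff(lines, line_ids))) {
    stopf("%s: line %s present in expression but absent from the reference line set",
          path, bad[1L])
  }
  vals <- array(
    NA_real_, dim = c(length(lines), length(tids), 2L),
    dimnames = list(lines, tids, c("female", "male"))
  )
  for (j in seq_along(cl)) vals[cl[j], , cs[j]] <- m[, j]
  expression_panel(vals)
}

#' @rdname read_expression
#' @param expr an [expression_panel()].
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "expression_panel"))
  cols <- as.vector(outer(expr$line_ids, c("female", "male"), paste, sep = ":"))
  m <- cbind(t(expr$values[, , "female", drop = FALSE][, , 1L]),
             t(expr$values[, , "male", drop = FALSE][, , 1L]))
  colnames(m) <- cols
  tab <- data.frame(transcript_id = expr$transcript_ids, m,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a phenotype table (TSV)
#'
#' Columns: `line`, `sex`, `replicate`, `value_seconds`. The assay bound
#' (values in \[0, 45\] s) is checked on read by default; disable for
#' unbounded synthetic phenotypes.
#'
#' @param path file path.
#' @param check_bounds enforce the \[0, 45\] s assay bound (default TRUE).
#' @param line_ids optional reference line-id set to cross-check against.
#' @return [read_phenotypes()]: a [phenotype_table()].
#' @export
read_phenotypes <- function(path, check_bounds = TRUE, line_ids = NULL) {
  if (!file.exists(path)) stopf("phenotype file not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("line", "sex", "replicate", "value_seconds")
  if (!all(need %in% names(tab))) {
    stopf("%s: phenotype TSV needs columns %s", path, paste(need, collapse = ", "))
  }
  if (!is.null(line_ids) && length(bad <- setdiff(unique(tab$line), line_ids))) {
    stopf("%s: line %s present in phenotype but absent from the reference line set",
          path, bad[1L])
  }
  rec <- data.frame(line = as.character(tab$line), sex = tab$sex,
                    replicate = tab$replicate, value = tab$value_seconds,
                    stringsAsFactors = FALSE)
  tryCatch(
    phenotype_table(rec, check_bounds = check_bounds),
    error = function(e) stopf("%s: %s", path, conditionMessage(e))
  )
}

#' @rdname read_phenotypes
#' @param pheno a [phenotype_table()].
#' @export
write_phenotypes <- function(pheno, path) {
  stopifnot(inherits(pheno, "phenotype_table"))
  tab <- data.frame(line = pheno$line, sex = pheno$sex,
                    replicate = pheno$replicate, value_seconds = pheno$value)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Truth serialization (YAML), mirroring simulation_truth.
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "simulation_truth"))
  as_map <- function(x) if (length(x)) as.list(x) else NULL
  as_rows <- function(df) if (nrow(df)) lapply(seq_len(nrow(df)), function(i) as.list(df[i, ])) else NULL
  obj <- list(
    mu = truth$mu,
    qts_effects = as_map(truth$qts_effects),
    epistasis_effects = as_map(truth$epistasis_effects),
    sex_effect = truth$sex_effect,
    qe_effects = as_map(truth$qe_effects),
    qqe_effects = as_map(truth$qqe_effects),
    cis_trans_effects = as_rows(truth$cis_trans_effects),
    tt_effects = as_rows(truth$tt_effects),
    expr_sex_effects = as_map(truth$expr_sex_effects)
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

read_truth <- function(path) {
  obj <- yaml::read_yaml(path)
  as_vec <- function(x) if (is.null(x)) numeric() else unlist(x)
  as_df <- function(x) if (is.null(x)) NULL else do.call(rbind, lapply(x, as.data.frame))
  simulation_truth(
    mu = obj$mu,
    qts_effects = as_vec(obj$qts_effects),
    epistasis_effects = as_vec(obj$epistasis_effects),
    sex_effect = obj$sex_effect %||% 0,
    qe_effects = as_vec(obj$qe_effects),
    qqe_effects = as_vec(obj$qqe_effects),
    cis_trans_effects = as_df(obj$cis_trans_effects),
    tt_effects = as_df(obj$tt_effects),
    expr_sex_effects = as_vec(obj$expr_sex_effects)
  )
}

# Canonical layer ordering for association tables.
layer_levels <- c("QTS", "QTT", "tQTS", "tQTT")

#' Write/read an association table (TSV)
#'
#' One row per retained association record across the four mapping layers,
#' in the layout of the study's supplementary tables: layer, source (one or
#' two ids for epistatic pairs), target, overall and per-sex effect
#' estimates, -log10 experiment-wise P (2 decimals), significance tier and
#' heritability contribution. Rows are ordered by layer, then source id,
#' then target, so output is deterministic.
#'
#' @param assocs association record data.frame (see [map_layer()]).
#' @param path file path.
#' @return Invisibly, `path`.
#' @export
write_association_table <- function(assocs, path) {
  assocs <- as.data.frame(assocs, stringsAsFactors = FALSE)
  cols <- c("layer", "source", "source2", "target", "effect",
            "effect_female", "effect_male", "neg_log10_p_ew", "tier", "h2")
  if (!nrow(assocs)) {
    assocs <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
  }
  if (!all(cols %in% names(assocs))) {
    stopf("association table needs columns %s", paste(cols, collapse = ", "))
  }
  assocs <- assocs[, cols, drop = FALSE]
  if (nrow(assocs)) {
    ord <- order(match(assocs$layer, layer_levels), assocs$source,
                 assocs$target, method = "radix")
    assocs <- assocs[ord, , drop = FALSE]
    assocs$neg_log10_p_ew <- sprintf("%.2f", assocs$neg_log10_p_ew)
    for (nm in c("effect", "effect_female", "effect_male", "h2")) {
      assocs[[nm]] <- sprintf("%.6g", assocs[[nm]])
    }
  }
  utils::write.table(assocs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_association_table
#' @export
read_association_table <- function(path) {
  if (!file.exists(path)) stopf("association file not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  num <- c("effect", "effect_female", "effect_male", "neg_log10_p_ew", "h2")
  for (nm in num) tab[[nm]] <- as.numeric(tab[[nm]])
  for (nm in c("layer", "source", "source2", "target", "tier")) {
    tab[[nm]] <- as.character(tab[[nm]])
  }
  tab$source2[is.na(tab$source2) | tab$source2 == ""] <- NA_character_
  tab
}
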