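#' Genotype panel of homozygous inbred lines
#'
#' Container for biallelic SNP calls on a panel of fully inbred lines, as in
#' the Drosophila Genetic Reference Panel: every call is homozygous, there is
#' no missing data, and each SNP carries chromosome, 1-based position and the
#' two alleles. Calls are stored as minor-allele dosage, so each cell is 0
#' (major-allele homozygote) or 2 (minor-allele homozygote).
#'
#' @param calls integer/numeric matrix, lines x SNPs, values in \{0, 2\};
#'   rownames are line ids, colnames SNP ids.
#' @param snps data.frame with columns `id`, `chrom`, `pos` (1-based bp),
#'   `major`, `minor`; one row per column of `calls`, same order.
#' @return An object of class `genotype_panel` with elements `calls`, `snps`
#'   and `line_ids`. SNPs are stored sorted by chromosome then position.
#' @export
genotype_panel <- function(calls, snps) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "double"
  if (is.null(rownames(calls)) || is.null(colnames(calls))) {
    stopf("genotype calls must carry line ids (rownames) and SNP ids (colnames)")
  }
  if (anyNA(calls)) {
    bad <- which(is.na(calls), arr.ind = TRUE)[1L, ]
    stopf("missing genotype call for SNP %s in line %s",
          colnames(calls)[bad[2L]], rownames(calls)[bad[1L]])
  }
  if (!all(calls %in% c(0, 2))) {
    bad <- which(!(calls %in% c(0, 2)), arr.ind = TRUE)[1L, ]
    stopf(
      "non-homozygous or invalid dosage %s for SNP %s in line %s (calls must be 0 or 2)",
      calls[bad[1L], bad[2L]], colnames(calls)[bad[2L]], rownames(calls)[bad[1L]]
    )
  }
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "pos", "major", "minor")
  if (!all(need %in% names(snps))) {
    stopf("snp table must have columns: %s", paste(need, collapse = ", "))
  }
  if (nrow(snps) != ncol(calls) || !identical(as.character(snps$id), colnames(calls))) {
    stopf("snp table rows must match call matrix columns (same ids, same order)")
  }
  if (any(snps$major == snps$minor)) {
    stopf("SNP %s has identical major and minor allele",
          snps$id[which(snps$major == snps$minor)[1L]])
  }
  ord <- order(snps$chrom, snps$pos, snps$id, method = "radix")
  snps <- snps[ord, , drop = FALSE]
  rownames(snps) <- NULL
  calls <- calls[, ord, drop = FALSE]
  # positions strictly increasing within chromosome
  for (ch in unique(snps$chrom)) {
    p <- snps$pos[snps$chrom == ch]
    if (anyDuplicated(p)) {
      stopf("duplicate position %s on chromosome %s", p[duplicated(p)][1L], ch)
    }
  }
  structure(
    list(calls = calls, snps = snps, line_ids = rownames(calls)),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf(
    "genotype_panel: %d inbred lines x %d SNPs on %s\n",
    length(x$line_ids), nrow(x$snps),
    paste(unique(x$snps$chrom), collapse = ", ")
  ))
  maf <- minor_line_count(x)
  cat(sprintf("  minor-allele line count: min %d, median %s\n",
              min(maf), format(stats::median(maf))))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$calls)

# Number of lines carrying the minor allele, per SNP.
minor_line_count <- function(panel) colSums(panel$calls == 2)

# +/-1 genotype coding: +1 major-allele homozygote, -1 minor-allele homozygote.
u_matrix <- function(panel) {
  u <- 1 - panel$calls
  storage.mode(u) <- "double"
  u
}

#' Sex-stratified expression panel
#'
#' Transcript abundance for each line, measured separately in females and
#' males (as for the sex-stratified DGRP expression arrays).
#'
#' @param values numeric array, lines x transcripts x sex, with
#'   `dimnames = list(line_ids, transcript_ids, c("female", "male"))`.
#' @return An object of class `expression_panel`.
#' @export
expression_panel <- function(values) {
  if (length(dim(values)) != 3L || dim(values)[3L] != 2L) {
    stopf("expression values must be a lines x transcripts x 2 (sex) array")
  }
  dn <- dimnames(values)
  if (is.null(dn) || any(vapply(dn[1:2], is.null, logical(1)))) {
    stopf("expression array must carry line and transcript dimnames")
  }
  if (is.null(dn[[3L]])) dimnames(values)[[3L]] <- c("female", "male")
  if (!setequal(dimnames(values)[[3L]], c("female", "male"))) {
    stopf("sex slices must be named 'female' and 'male'; missing sex slice")
  }
  values <- values[, , c("female", "male"), drop = FALSE]
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stopf("non-finite expression value for transcript %s, line %s",
          dimnames(values)[[2L]][bad[2L]], dimnames(values)[[1L]][bad[1L]])
  }
  structure(
    list(
      values = values,
      line_ids = dimnames(values)[[1L]],
      transcript_ids = dimnames(values)[[2L]]
    ),
    class = "expression_panel"
  )
}

#' @export
print.expression_panel <- function(x, ...) {
  cat(sprintf(
    "expression_panel: %d lines x %d transcripts x 2 sexes\n",
    length(x$line_ids), length(x$transcript_ids)
  ))
  invisible(x)
}

#' Phenotype table of startle scores
#'
#' Replicated startle measurements (seconds of activity in the 45 s window
#' after a mechanical disturbance) per line and sex.
#'
#' @param records data.frame with columns `line`, `sex` ("female"/"male"),
#'   `replicate` (integer), `value` (seconds).
#' @param check_bounds enforce the assay bound value in \[0, 45\]? Default
#'   TRUE; turn off for unbounded synthetic phenotypes.
#' @return An object of class `phenotype_table` (a data.frame).
#' @export
phenotype_table <- function(records, check_bounds = TRUE) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("line", "sex", "replicate", "value")
  if (!all(need %in% names(records))) {
    stopf("phenotype records need columns: %s", paste(need, collapse = ", "))
  }
  if (!all(records$sex %in% c("female", "male"))) {
    stopf("phenotype sex must be 'female' or 'male' (record %d)",
          which(!(records$sex %in% c("female", "male")))[1L])
  }
  if (anyNA(records$value)) {
    stopf("missing phenotype value at record %d", which(is.na(records$value))[1L])
  }
  if (check_bounds && any(records$value < 0 | records$value > 45)) {
    bad <- which(records$value < 0 | records$value > 45)[1L]
    stopf("phenotype value %.3f outside [0, 45] s (line %s, sex %s, replicate %s)",
          records$value[bad], records$line[bad], records$sex[bad],
          records$replicate[bad])
  }
  # replicate indices complete per line x sex
  reps <- split(records$replicate, paste(records$line, records$sex))
  nrep <- lengths(reps)
  if (length(unique(nrep)) > 1L ||
      !all(vapply(reps, function(r) setequal(r, seq_along(r)), logical(1)))) {
    stopf("replicate indices must be complete (1..r) for every line x sex")
  }
  class(records) <- c("phenotype_table", "data.frame")
  records
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf(
    "phenotype_table: %d records, %d lines, %d replicate(s)/line/sex, range [%.2f, %.2f] s\n",
    nrow(x), length(unique(x$line)), max(x$replicate), min(x$value), max(x$value)
  ))
  invisible(x)
}

# Line x sex mean response in canonical observation order (females then males,
# lines in `line_ids` order).
pheno_means <- function(pheno, line_ids) {
  key <- paste(pheno$line, pheno$sex, sep = "\r")
  m <- tapply(pheno$value, key, mean)
  want <- paste(rep(line_ids, 2L), rep(c("female", "male"), each = length(line_ids)),
                sep = "\r")
  if (!all(want %in% names(m))) {
    miss <- strsplit(want[!(want %in% names(m))][1L], "\r")[[1L]]
    stopf("phenotype is missing line %s, sex %s", miss[1L], miss[2L])
  }
  as.numeric(m[want])
}

# One transcript's values in canonical observation order.
transcript_obs <- function(expr, transcript, line_ids = expr$line_ids) {
  v <- expr$values[line_ids, transcript, , drop = FALSE]
  c(v[, 1L, "female"], v[, 1L, "male"])
}
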