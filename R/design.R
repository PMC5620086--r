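#' Term structure of the mixed linear association model
#'
#' Declares which predictors enter the model for one response: main loci
#' (SNPs or transcripts), epistatic pairs, the sex main effect, and which
#' loci/pairs additionally carry sex-interaction (qe/qqe) terms.
#'
#' @param loci character vector of predictor ids (SNP or transcript ids).
#' @param pairs epistatic pairs: a 2-column matrix/data.frame of ids, or a
#'   character vector of "id1:id2" keys. Self-pairs are rejected.
#' @param include_sex include the sex main effect (default TRUE).
#' @param qe_loci loci carrying a locus-by-sex interaction term; TRUE means
#'   all of `loci`, FALSE/NULL none, or a character subset.
#' @param qqe_pairs pairs carrying a pair-by-sex interaction; TRUE/FALSE or a
#'   character vector of "id1:id2" keys.
#' @param response `"phenotype"` or a transcript id to model transcript
#'   abundance as the response.
#' @param observation_unit `"means"` (line x sex means; the model has no
#'   replicate term) or `"replicates"`.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(loci = character(),
                        pairs = NULL,
                        include_sex = TRUE,
                        qe_loci = FALSE,
                        qqe_pairs = FALSE,
                        response = "phenotype",
                        observation_unit = c("means", "replicates")) {
  observation_unit <- match.arg(observation_unit)
  loci <- as.character(loci)
  if (anyDuplicated(loci)) stopf("duplicate locus id in design: %s",
                                 loci[duplicated(loci)][1L])
  if (is.null(pairs)) {
    pairs <- matrix(character(), ncol = 2L)
  } else if (is.character(pairs)) {
    pairs <- do.call(rbind, split_pair_key(pairs))
  } else {
    pairs <- as.matrix(pairs)
  }
  if (ncol(pairs) != 2L && length(pairs)) stopf("pairs must have two ids per row")
  if (nrow(pairs)) {
    if (any(pairs[, 1L] == pairs[, 2L])) stopf("self-pairs are not allowed")
    if (length(bad <- setdiff(as.vector(pairs), loci))) {
      stopf("pair member(s) not in loci: %s", paste(bad, collapse = ", "))
    }
  }
  norm_subset <- function(x, universe, what) {
    if (isTRUE(x)) return(universe)
    if (is.null(x) || isFALSE(x)) return(character())
    x <- as.character(x)
    if (length(bad <- setdiff(x, universe))) {
      stopf("%s not among declared %s: %s", what, what, paste(bad, collapse = ", "))
    }
    x
  }
  pair_keys <- if (nrow(pairs)) pair_key(pairs[, 1L], pairs[, 2L]) else character()
  structure(
    list(
      loci = loci, pairs = pairs, pair_keys = pair_keys,
      include_sex = isTRUE(include_sex),
      qe_loci = norm_subset(qe_loci, loci, "loci"),
      qqe_pairs = norm_subset(qqe_pairs, pair_keys, "pairs"),
      response = response,
      observation_unit = observation_unit
    ),
    class = "design_spec"
  )
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf(
    "design_spec: response %s | %d main locus/loci, %d pair(s), sex %s, %d qe, %d qqe (%s)\n",
    x$response, length(x$loci), nrow(x$pairs),
    if (x$include_sex) "yes" else "no",
    length(x$qe_loci), length(x$qqe_pairs), x$observation_unit
  ))
  invisible(x)
}

# Resolve one predictor id to its observation-order column.
# SNPs: +/-1 code, identical in both sex blocks, scale 1.
# Transcripts: standardized to mean 0, SD 1 within each sex; `scale` is the
# factor that converts a coefficient on the standardized column back to the
# raw-abundance scale (raw = coef / scale is wrong; raw_effect = coef / sd).
resolve_predictor <- function(id, genotypes, expression, line_ids) {
  if (!is.null(genotypes) && id %in% genotypes$snps$id) {
    u <- u_matrix(genotypes)[line_ids, id]
    return(list(x = c(u, u), scale = 1, kind = "snp"))
  }
  if (!is.null(expression) && id %in% expression$transcript_ids) {
    v <- transcript_obs(expression, id, line_ids)
    n <- length(line_ids)
    z <- v
    sds <- numeric(2L)
    for (b in 1:2) {
      idx <- seq_len(n) + (b - 1L) * n
      mu <- mean(v[idx]); sd <- stats::sd(v[idx])
      sds[b] <- sd
      z[idx] <- if (sd > 0) (v[idx] - mu) / sd else 0
    }
    return(list(x = z, scale = mean(sds), kind = "transcript"))
  }
  stopf("unknown predictor id: %s", id)
}

#' Encode the design matrix and response for the association model
#'
#' Builds the fixed-effect design of the mixed linear model in a fixed column
#' order: intercept, sex contrast (+1 female, -1 male), main locus codes
#' (SNPs +/-1; transcripts standardized per sex), epistasis columns
#' (elementwise products), then qe (main code x sex contrast) and qqe
#' (pair code x sex contrast) columns. The response is the phenotype
#' (line x sex means by default, or replicate-level) or a transcript's
#' abundance.
#'
#' @param spec a [design_spec()].
#' @param genotypes a [genotype_panel()] (or NULL if all predictors are
#'   transcripts).
#' @param expression an [expression_panel()] (or NULL).
#' @param phenotypes a [phenotype_table()]; required when
#'   `spec$response == "phenotype"`.
#' @return An object of class `qtx_design`: list with the model matrix `X`,
#'   response `y`, observation frame `obs`, and a `terms` table (column name,
#'   group, ids, raw-scale conversion factor).
#' @export
encode_design <- function(spec, genotypes = NULL, expression = NULL,
                          phenotypes = NULL) {
  stopifnot(inherits(spec, "design_spec"))
  line_ids <- if (!is.null(genotypes)) genotypes$line_ids else expression$line_ids
  if (is.null(line_ids)) stopf("need a genotype or expression panel to define the line set")
  if (!is.null(genotypes) && !is.null(expression) &&
      !setequal(genotypes$line_ids, expression$line_ids)) {
    stopf("genotype and expression panels disagree on line ids")
  }
  n <- length(line_ids)
  obs <- obs_frame(line_ids)
  s <- sex_contrast(n)

  # response
  if (identical(spec$response, "phenotype")) {
    if (is.null(phenotypes)) stopf("phenotype table required for phenotype response")
    if (spec$observation_unit == "means") {
      y <- pheno_means(phenotypes, line_ids)
    } else {
      key <- order(match(phenotypes$line, line_ids) +
                     n * (phenotypes$sex == "male"),
                   phenotypes$replicate, method = "radix")
      ph <- phenotypes[key, ]
      obs <- data.frame(line = ph$line, sex = ph$sex, replicate = ph$replicate,
                        stringsAsFactors = FALSE)
      y <- ph$value
      s <- ifelse(ph$sex == "female", 1, -1)
    }
  } else {
    if (is.null(expression)) stopf("expression panel required for transcript response")
    if (!(spec$response %in% expression$transcript_ids)) {
      stopf("unknown response transcript: %s", spec$response)
    }
    y <- transcript_obs(expression, spec$response, line_ids)
  }

  cols <- list(`(mu)` = rep(1, length(y)))
  terms <- data.frame(
    name = "(mu)", group = "intercept",
    id1 = NA_character_, id2 = NA_character_, scale = 1,
    stringsAsFactors = FALSE
  )
  add_term <- function(name, group, x, id1 = NA, id2 = NA, scale = 1) {
    cols[[name]] <<- x
    terms[nrow(terms) + 1L, ] <<- list(name, group, id1, id2, scale)
  }
  if (spec$include_sex) add_term("sex", "sex", s)

  main_cols <- list()
  dropped <- character()
  if (spec$observation_unit == "replicates" && !identical(spec$response, "phenotype")) {
    stopf("replicate-level observation unit applies to the phenotype response only")
  }
  expand_obs <- function(x) {
    if (spec$observation_unit == "means" || !identical(spec$response, "phenotype")) return(x)
    # replicate-level: repeat the line x sex value for each replicate row
    x[match(paste(obs$line, obs$sex), paste(obs_frame(line_ids)$line,
                                            obs_frame(line_ids)$sex))]
  }
  for (id in spec$loci) {
    p <- resolve_predictor(id, genotypes, expression, line_ids)
    x <- expand_obs(p$x)
    if (stats::var(x) == 0) {
      warnf("predictor %s has zero variance and is excluded from the design", id)
      dropped <- c(dropped, id)
      next
    }
    main_cols[[id]] <- x
    add_term(paste0("q:", id), "main", x, id1 = id, scale = p$scale)
  }
  for (r in seq_len(nrow(spec$pairs))) {
    i <- spec$pairs[r, 1L]; j <- spec$pairs[r, 2L]
    if (i %in% dropped || j %in% dropped) next
    x <- main_cols[[i]] * main_cols[[j]]
    if (stats::var(x) == 0) {
      warnf("epistasis column %s has zero variance and is excluded", pair_key(i, j))
      next
    }
    add_term(paste0("qq:", pair_key(i, j)), "pair", x, id1 = i, id2 = j)
  }
  for (id in setdiff(spec$qe_loci, dropped)) {
    add_term(paste0("qe:", id), "qe", main_cols[[id]] * expand_obs(s0 <- sex_contrast(n)),
             id1 = id, scale = terms$scale[terms$id1 %in% id & terms$group == "main"][1L])
  }
  for (key in spec$qqe_pairs) {
    p <- split_pair_key(key)[[1L]]
    if (any(p %in% dropped)) next
    x <- main_cols[[p[1L]]] * main_cols[[p[2L]]] * expand_obs(sex_contrast(n))
    add_term(paste0("qqe:", key), "qqe", x, id1 = p[1L], id2 = p[2L])
  }

  X <- do.call(cbind, cols)
  colnames(X) <- terms$name
  structure(
    list(X = X, y = y, obs = obs, terms = terms, spec = spec,
         n_lines = n, line_ids = line_ids),
    class = "qtx_design"
  )
}

#' @export
print.qtx_design <- function(x, ...) {
  cat(sprintf("qtx_design: %d observations x %d terms (%s)\n",
              nrow(x$X), ncol(x$X),
              paste(unique(x$terms$group), collapse = ", ")))
  invisible(x)
}
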