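#' Scan configuration
#'
#' Parameters of the two-step detection machinery: nominal pre-screen
#' threshold, permutation count and experiment-wise alpha for the critical F,
#' significance-tier thresholds on -log10 experiment-wise P, and the budget
#' on epistatic candidate pairs.
#'
#' @param prescreen_alpha nominal P threshold of the single-locus pre-screen
#'   (default 0.001, the study's candidate filter).
#' @param n_permutations permutations for the critical F (default 2000;
#'   reducible for desk-scale runs, minimum 19).
#' @param alpha_ew experiment-wise type-I error (default 0.05).
#' @param tier_high -log10 P_EW at/above which a record is tier
#'   "ew_high" (default 5).
#' @param tier_report secondary reporting tier (default 3).
#' @param pair_budget maximum candidate pairs in the 2D scan (default 100).
#' @param gibbs a [gibbs_config()] used for effect estimation downstream.
#' @param seed RNG seed for the permutations.
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(prescreen_alpha = 0.001, n_permutations = 2000,
                        alpha_ew = 0.05, tier_high = 5, tier_report = 3,
                        pair_budget = 100, gibbs = gibbs_config(), seed = 1L) {
  if (!(prescreen_alpha > 0 && prescreen_alpha < 1)) {
    stopf("prescreen_alpha must be in (0, 1)")
  }
  if (!is_count(n_permutations, 19)) {
    stopf("n_permutations must be an integer >= 19 (cannot resolve alpha = 0.05 below that)")
  }
  stopifnot(alpha_ew > 0, alpha_ew < 1, is_count(pair_budget, 1))
  structure(
    list(prescreen_alpha = prescreen_alpha,
         n_permutations = as.integer(n_permutations),
         alpha_ew = alpha_ew, tier_high = tier_high, tier_report = tier_report,
         pair_budget = as.integer(pair_budget), gibbs = gibbs,
         seed = as.integer(seed)),
    class = "scan_config"
  )
}

# ---- fast marginal single-locus statistics ---------------------------------
#
# Model per predictor: y ~ 1 + sex + g + g*sex on line x sex observations.
# Predictor columns are required to be (a) constant within line (SNP +/-1
# codes, centered here) or (b) standardized to mean 0 within each sex block
# (transcripts). In both cases {1, s, g, g*s} are mutually orthogonal after
# centering g, so sums of squares per term reduce to projections, vectorized
# over predictors and over many response vectors at once (permutations).
#
# P: 2n x m predictor matrix (canonical obs order), Y: 2n x r responses.
# Returns per-term F (main, qe) and the joint 2-df locus F, each m x r.
fast_scan_stats <- function(P, Y, s) {
  Y <- as.matrix(Y)
  n2 <- nrow(Y)
  Pc <- sweep(P, 2L, colMeans(P))
  d <- colSums(Pc^2)
  ok <- d > 0
  Yt <- sweep(Y, 2L, colMeans(Y))
  Yt <- Yt - (s %o% drop(crossprod(s, Yt) / n2))
  A <- crossprod(Pc, Yt)              # m x r projections on g
  B <- crossprod(Pc, Yt * s)          # projections on g*s (= crossprod(Pc*s, Yt))
  dsafe <- ifelse(ok, d, 1)
  SSg <- A^2 / dsafe
  SSge <- B^2 / dsafe
  TSS <- rep(colSums(Yt^2), each = nrow(A))
  dim(TSS) <- dim(SSg)
  df <- n2 - 4L
  RSS <- pmax(TSS - SSg - SSge, 0)
  denom <- pmax(RSS / df, .Machine$double.eps)
  F_main <- SSg / denom
  F_qe <- SSge / denom
  F_joint <- ((SSg + SSge) / 2) / denom
  if (any(!ok)) {
    F_main[!ok, ] <- 0
    F_qe[!ok, ] <- 0
    F_joint[!ok, ] <- 0
  }
  list(F_main = F_main, F_qe = F_qe, F_joint = F_joint, df = df)
}

# Line-level permutations of a canonical-order response: both sex slices of a
# line move together, preserving each line's female/male pairing.
permuted_responses <- function(y, n_lines, n_perm) {
  out <- matrix(NA_real_, 2L * n_lines, n_perm)
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n_lines)
    out[, b] <- y[c(idx, n_lines + idx)]
  }
  out
}

#' Pre-screen candidate predictors
#'
#' First step of the two-step strategy: each predictor is tested in its own
#' single-locus model (main effect + sex + locus-by-sex interaction) and
#' retained when the joint 2-df locus F has nominal P below
#' `config$prescreen_alpha`. Ordering of the retained set is by P, ties by
#' genomic position (or id).
#'
#' @param y response in canonical observation order (females then males).
#' @param predictors 2n x m matrix of encoded predictor columns.
#' @param config a [scan_config()].
#' @param positions optional data.frame(chrom, pos) aligned with predictors
#'   for positional tie-breaking.
#' @return data.frame(id, F, p) of retained candidates.
#' @export
prescreen_candidates <- function(y, predictors, config = scan_config(),
                                 positions = NULL) {
  st <- fast_scan_stats(predictors, y, sex_contrast(length(y) / 2L))
  Fj <- drop(st$F_joint)
  p <- stats::pf(Fj, 2, st$df, lower.tail = FALSE)
  keep <- which(p < config$prescreen_alpha)
  if (is.null(positions)) {
    posord <- seq_len(ncol(predictors))
  } else {
    posord <- order(positions$chrom, positions$pos, method = "radix")
    posord <- match(seq_len(ncol(predictors)), posord)
  }
  keep <- keep[order(p[keep], posord[keep])]
  data.frame(id = colnames(predictors)[keep], F = Fj[keep], p = p[keep],
             stringsAsFactors = FALSE)
}

#' Permutation-calibrated critical F
#'
#' For each permutation, line labels of the response are shuffled jointly
#' across both sex slices, the per-term F statistics (main and locus-by-sex)
#' of every supplied predictor are recomputed, and their maximum recorded.
#' The critical F at `alpha_ew` is the `ceiling((1 - alpha_ew) * n_perm)`-th
#' order statistic of the null maxima; experiment-wise P of an observed F
#' uses add-one smoothing, `(1 + #{null maxima >= F}) / (n_perm + 1)`.
#'
#' The null is built over the full predictor set supplied, so thresholds
#' calibrated here control the family-wise error of the whole scan.
#'
#' @inheritParams prescreen_candidates
#' @return An object of class `perm_null` with `critical_F`, the vector of
#'   `null_max`, and the calibration settings.
#' @export
permutation_critical_f <- function(y, predictors, config = scan_config()) {
  n_lines <- length(y) / 2L
  set.seed(config$seed)
  Y <- permuted_responses(y, n_lines, config$n_permutations)
  st <- fast_scan_stats(predictors, Y, sex_contrast(n_lines))
  null_max <- apply(pmax(st$F_main, st$F_qe), 2L, max)
  perm_null(null_max, config)
}

perm_null <- function(null_max, config) {
  k <- ceiling((1 - config$alpha_ew) * length(null_max))
  structure(
    list(critical_F = sort(null_max)[k], null_max = null_max,
         n_perm = length(null_max), alpha_ew = config$alpha_ew),
    class = "perm_null"
  )
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf("perm_null: critical F = %.3f at alpha_EW = %g (%d permutations)\n",
              x$critical_F, x$alpha_ew, x$n_perm))
  invisible(x)
}

#' Experiment-wise P value from a permutation null
#'
#' @param null a `perm_null`.
#' @param f observed F statistic(s).
#' @return experiment-wise P value(s), floored at `1 / (n_perm + 1)`.
#' @export
p_experimentwise <- function(null, f) {
  vapply(f, function(fi) (1 + sum(null$null_max >= fi)) / (null$n_perm + 1),
         numeric(1L))
}

#' One-dimensional scan of candidate main and sex-interaction effects
#'
#' Tests each candidate's main (q) and locus-by-sex (qe) term with the same
#' marginal single-locus statistic that the permutation null recomputes, and
#' attaches experiment-wise P values. Terms with F above the critical F are
#' flagged significant.
#'
#' @param y response (canonical observation order).
#' @param candidates 2n x k matrix of candidate predictor columns.
#' @param null a `perm_null` from [permutation_critical_f()].
#' @return A `scan_result` data.frame: source, term type, F, nominal P,
#'   experiment-wise P, significance flag.
#' @export
scan_main_effects <- function(y, candidates, null) {
  if (!ncol(candidates)) return(empty_scan_result(null))
  st <- fast_scan_stats(candidates, y, sex_contrast(length(y) / 2L))
  res <- data.frame(
    source = rep(colnames(candidates), 2L),
    source2 = NA_character_,
    type = rep(c("main", "qe"), each = ncol(candidates)),
    F = c(drop(st$F_main), drop(st$F_qe)),
    stringsAsFactors = FALSE
  )
  res$p_nominal <- stats::pf(res$F, 1, st$df, lower.tail = FALSE)
  res$p_ew <- p_experimentwise(null, res$F)
  res$significant <- res$F > null$critical_F
  structure(res, class = c("scan_result", "data.frame"), critical_F = null$critical_F)
}

empty_scan_result <- function(null = NULL) {
  structure(
    data.frame(source = character(), source2 = character(), type = character(),
               F = numeric(), p_nominal = numeric(), p_ew = numeric(),
               significant = logical(), stringsAsFactors = FALSE),
    class = c("scan_result", "data.frame"),
    critical_F = if (is.null(null)) NA_real_ else null$critical_F
  )
}

# Per-term (type III) F statistics for the last columns of a fixed design,
# vectorized over many responses. X must be full rank.
joint_term_F <- function(X, Y, term_cols = seq_len(ncol(X))) {
  Y <- as.matrix(Y)
  qx <- qr(X)
  beta <- qr.coef(qx, Y)
  RSS <- colSums(qr.resid(qx, Y)^2)
  df <- nrow(X) - ncol(X)
  xtx_inv_diag <- diag(chol2inv(qr.R(qx)))
  Fm <- matrix(NA_real_, length(term_cols), ncol(Y))
  for (i in seq_along(term_cols)) {
    j <- term_cols[i]
    Fm[i, ] <- beta[j, ]^2 / (xtx_inv_diag[j] * RSS / df)
  }
  list(F = Fm, df = df)
}

#' Two-dimensional epistasis scan over candidate pairs
#'
#' Every unordered pair of candidates (up to `config$pair_budget`; beyond
#' that, candidates are truncated by marginal significance with a warning)
#' is tested in the two-locus model (both mains, both qe terms, the
#' epistasis product and its sex interaction); the qq and qqe terms get
#' per-term F statistics. A dedicated permutation null of the max pair-term
#' statistic calibrates the pair critical F and experiment-wise P values.
#'
#' @param y response (canonical observation order).
#' @param candidates 2n x k matrix of candidate predictor columns.
#' @param config a [scan_config()].
#' @return list(result = `scan_result` for qq/qqe terms, null = `perm_null`).
#' @export
scan_epistasis <- function(y, candidates, config = scan_config()) {
  k <- ncol(candidates)
  if (k < 2L) {
    return(list(result = empty_scan_result(), null = NULL))
  }
  if (choose(k, 2L) > config$pair_budget) {
    k_max <- floor((1 + sqrt(1 + 8 * config$pair_budget)) / 2)
    warnf("pair budget %d exceeded (%d candidates); truncating to the %d strongest candidates",
          config$pair_budget, k, k_max)
    candidates <- candidates[, seq_len(k_max), drop = FALSE]
    k <- k_max
  }
  n_lines <- length(y) / 2L
  s <- sex_contrast(n_lines)
  set.seed(config$seed + 1L)
  Y <- cbind(y, permuted_responses(y, n_lines, config$n_permutations))

  pairs <- utils::combn(k, 2L)
  rows <- list()
  null_max <- rep(0, config$n_permutations)
  df <- NA_integer_
  for (c2 in seq_len(ncol(pairs))) {
    i <- pairs[1L, c2]; j <- pairs[2L, c2]
    gi <- candidates[, i]; gj <- candidates[, j]
    gij <- gi * gj
    X <- cbind(1, s, gi, gj, gi * s, gj * s, gij, gij * s)
    if (qr(X)$rank < ncol(X)) next   # collinear pair (e.g. LD = 1); untestable
    ft <- joint_term_F(X, Y, term_cols = 7:8)
    df <- ft$df
    null_max <- pmax(null_max, apply(ft$F[, -1L, drop = FALSE], 2L, max))
    rows[[length(rows) + 1L]] <- data.frame(
      source = colnames(candidates)[i], source2 = colnames(candidates)[j],
      type = c("qq", "qqe"), F = ft$F[, 1L], stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) return(list(result = empty_scan_result(), null = NULL))
  null <- perm_null(null_max, config)
  res <- do.call(rbind, rows)
  res$p_nominal <- stats::pf(res$F, 1, df, lower.tail = FALSE)
  res$p_ew <- p_experimentwise(null, res$F)
  res$significant <- res$F > null$critical_F
  list(
    result = structure(res, class = c("scan_result", "data.frame"),
                       critical_F = null$critical_F),
    null = null
  )
}

#' Final multi-locus model selection
#'
#' Forward inclusion of all terms passing their critical F (main/qe terms
#' before epistatic terms), with perfectly collinear survivors resolved by
#' keeping the smaller genomic position (or lexicographically smaller id);
#' then backward elimination that refits the joint model and drops the
#' weakest term until every retained term stays experiment-wise significant.
#' An empty selection is a valid model (intercept + sex).
#'
#' @param y response (canonical observation order).
#' @param candidates 2n x k candidate predictor matrix.
#' @param main_scan `scan_result` from [scan_main_effects()].
#' @param epi_scan result list from [scan_epistasis()] (or NULL).
#' @param main_null `perm_null` used for the main scan.
#' @param positions optional data.frame(id, chrom, pos) for positional
#'   tie-breaking; defaults to lexicographic ids.
#' @return list with `terms` (data.frame of retained terms: source, source2,
#'   type, F, p_ew), `loci`, `pairs` — ready to build a [design_spec()].
#' @export
select_model <- function(y, candidates, main_scan, epi_scan = NULL,
                         main_null, positions = NULL) {
  pos_rank <- function(ids) {
    if (is.null(positions)) return(rank(ids, ties.method = "first"))
    m <- match(ids, positions$id)
    order(order(positions$chrom[m], positions$pos[m], ids, method = "radix"))
  }
  sig_main <- main_scan[main_scan$significant, , drop = FALSE]
  epi_res <- if (!is.null(epi_scan)) epi_scan$result else empty_scan_result()
  sig_pair <- epi_res[epi_res$significant, , drop = FALSE]
  terms <- rbind(sig_main, sig_pair)
  if (!nrow(terms)) {
    return(list(terms = terms, loci = character(), pairs = character()))
  }

  # drop perfectly collinear duplicate loci, keeping the smaller position
  loci <- unique(c(terms$source, terms$source2))
  loci <- loci[!is.na(loci)]
  loci <- loci[order(pos_rank(loci))]
  dropped <- character()
  if (length(loci) > 1L) {
    M <- candidates[, loci, drop = FALSE]
    cm <- suppressWarnings(stats::cor(M))
    for (a in seq_len(length(loci) - 1L)) {
      for (b in seq((a + 1L), length(loci))) {
        if (!is.na(cm[a, b]) && abs(abs(cm[a, b]) - 1) < 1e-12) {
          dropped <- c(dropped, loci[b])
        }
      }
    }
    dropped <- unique(dropped)
  }
  keep_term <- !(terms$source %in% dropped) &
    (is.na(terms$source2) | !(terms$source2 %in% dropped))
  terms <- terms[keep_term, , drop = FALSE]
  if (!nrow(terms)) {
    return(list(terms = terms, loci = character(), pairs = character()))
  }

  crit_for <- function(type) {
    if (type %in% c("main", "qe")) main_null$critical_F
    else attr(epi_res, "critical_F")
  }
  null_for <- function(type) {
    if (type %in% c("main", "qe")) main_null else epi_scan$null
  }

  # canonical term order: mains before pairs, then by position/id
  ord <- order(match(terms$type, c("main", "qe", "qq", "qqe")),
               pos_rank(terms$source), method = "radix")
  terms <- terms[ord, , drop = FALSE]

  build_X <- function(terms) {
    n2 <- nrow(candidates)
    s <- sex_contrast(n2 / 2L)
    cols <- list(rep(1, n2), s)
    nms <- c("(mu)", "sex")
    for (r in seq_len(nrow(terms))) {
      g <- candidates[, terms$source[r]]
      if (!is.na(terms$source2[r])) g <- g * candidates[, terms$source2[r]]
      if (terms$type[r] %in% c("qe", "qqe")) g <- g * s
      cols[[length(cols) + 1L]] <- g
      nms <- c(nms, paste0(terms$type[r], ":", terms$source[r],
                           ifelse(is.na(terms$source2[r]), "",
                                  paste0(":", terms$source2[r]))))
    }
    X <- do.call(cbind, cols)
    colnames(X) <- nms
    X
  }

  repeat {
    if (!nrow(terms)) break
    X <- build_X(terms)
    # resolve residual rank deficiency by dropping later (larger-position) terms
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      aliased <- setdiff(qx$pivot[(qx$rank + 1L):ncol(X)], 1:2) - 2L
      terms <- terms[-aliased[1L], , drop = FALSE]
      next
    }
    ft <- joint_term_F(X, y, term_cols = 2L + seq_len(nrow(terms)))
    Fj <- drop(ft$F)
    crit <- vapply(terms$type, crit_for, numeric(1L))
    fail <- which(Fj <= crit)
    if (!length(fail)) {
      terms$F <- Fj
      terms$p_nominal <- stats::pf(Fj, 1, ft$df, lower.tail = FALSE)
      terms$p_ew <- vapply(seq_len(nrow(terms)), function(r)
        p_experimentwise(null_for(terms$type[r]), Fj[r]), numeric(1L))
      break
    }
    weakest <- fail[which.min(Fj[fail] / crit[fail])]
    terms <- terms[-weakest, , drop = FALSE]
  }

  loci <- unique(stats::na.omit(c(terms$source, terms$source2)))
  pk <- unique(terms$source2[!is.na(terms$source2)])
  pairs <- unique(terms[!is.na(terms$source2), c("source", "source2"), drop = FALSE])
  list(
    terms = terms,
    loci = loci,
    pairs = if (nrow(pairs)) pair_key(pairs$source, pairs$source2) else character()
  )
}
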