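#' Fit the fixed-effect association model
#'
#' Least-squares fit of the encoded mixed linear model, with per-term F
#' statistics (squared t statistics on 1 numerator df) and nominal P values.
#' Detection elsewhere in the package is driven by these frequentist tests;
#' reported effect sizes may instead come from [gibbs_estimate()].
#'
#' @param design a `qtx_design` from [encode_design()].
#' @return An object of class `qtx_fit` with coefficients, standard errors,
#'   per-term F and P, residual variance and the design.
#' @export
fit_qtx <- function(design) {
  stopifnot(inherits(design, "qtx_design"))
  X <- design$X
  y <- design$y
  if (nrow(X) < ncol(X) + 2L) {
    stopf("need at least %d observations to fit %d parameters (+2)",
          ncol(X) + 2L, ncol(X))
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stopf("design is rank deficient; aliased column(s): %s",
          paste(aliased, collapse = ", "))
  }
  beta <- qr.coef(qx, y)
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  df_res <- nrow(X) - ncol(X)
  rss <- sum(resid^2)
  sigma2 <- rss / df_res
  # LINPACK qr() does not pivot for full-rank X, so R is in column order
  xtx_inv <- chol2inv(qr.R(qx))
  se <- sqrt(diag(xtx_inv) * sigma2)
  Fstat <- (beta / se)^2
  p <- stats::pf(Fstat, 1, df_res, lower.tail = FALSE)
  structure(
    list(
      coefficients = beta, se = se, F = Fstat, p = p,
      df_residual = df_res, sigma2 = sigma2,
      fitted = fitted, residuals = resid,
      xtx_inv = xtx_inv, design = design
    ),
    class = "qtx_fit"
  )
}

#' @export
print.qtx_fit <- function(x, ...) {
  cat(sprintf("qtx_fit: %d observations, %d terms, residual SD %.4g (df = %d)\n",
              length(x$residuals), length(x$coefficients),
              sqrt(x$sigma2), x$df_residual))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.qtx_fit <- function(object, ...) {
  tab <- data.frame(
    term = names(object$coefficients),
    group = object$design$terms$group,
    estimate = unname(object$coefficients),
    se = unname(object$se),
    F = unname(object$F),
    neg_log10_p = -log10(unname(object$p)),
    stringsAsFactors = FALSE
  )
  h <- tryCatch(heritability(object), error = function(e) NULL)
  out <- list(terms = tab, sigma2 = object$sigma2,
              df_residual = object$df_residual, heritability = h,
              r2 = tryCatch(predict_r2(object)$r2, error = function(e) NA_real_))
  class(out) <- "summary.qtx_fit"
  out
}

#' @export
print.summary.qtx_fit <- function(x, ...) {
  cat("Mixed linear association model (fixed-effect fit)\n\n")
  print(x$terms, digits = 4, row.names = FALSE)
  cat(sprintf("\nResidual variance: %.4g on %d df\n", x$sigma2, x$df_residual))
  if (!is.null(x$heritability)) {
    h <- x$heritability
    cat(sprintf("Heritability: h2_Q = %.3f, h2_QQ = %.3f, h2_QE = %.3f, h2_QQE = %.3f, h2_T = %.3f\n",
                h$h2_Q, h$h2_QQ, h$h2_QE, h$h2_QQE, h$h2_T))
  }
  if (is.finite(x$r2)) cat(sprintf("R2 (predicted genotypic values vs response): %.3f\n", x$r2))
  invisible(x)
}

#' @export
coef.qtx_fit <- function(object, ...) object$coefficients

#' @export
residuals.qtx_fit <- function(object, ...) object$residuals

#' @export
fitted.qtx_fit <- function(object, ...) object$fitted

#' Predicted genotypic values
#'
#' The model's total predicted genotypic effect per observation: the sum of
#' all genetic terms (main, epistasis, qe, qqe), excluding the intercept, the
#' sex main effect and the residual.
#'
#' @param object a `qtx_fit`.
#' @param type `"genotypic"` (default) or `"response"` (full fitted values).
#' @param ... unused.
#' @export
predict.qtx_fit <- function(object, type = c("genotypic", "response"), ...) {
  type <- match.arg(type)
  if (type == "response") return(object$fitted)
  genetic_values(object)
}

#' @export
simulate.qtx_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$fitted)
  out <- as.data.frame(
    matrix(object$fitted + stats::rnorm(n * nsim, sd = sqrt(object$sigma2)),
           n, nsim)
  )
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

genetic_groups <- c("main", "pair", "qe", "qqe")

# Per-observation contribution of a set of term groups.
group_contribution <- function(fit, groups, coefs = fit$coefficients) {
  keep <- fit$design$terms$group %in% groups
  if (!any(keep)) return(rep(0, nrow(fit$design$X)))
  drop(fit$design$X[, keep, drop = FALSE] %*% coefs[keep])
}

genetic_values <- function(fit, coefs = fit$coefficients) {
  group_contribution(fit, genetic_groups, coefs)
}

#' Variance components of the fitted model
#'
#' Partitions phenotypic variance into main-effect, epistatic, sex-interaction
#' and residual components: `V_Q` is the population (divide-by-n) variance
#' over observations of the summed main-effect contributions, `V_QQ` of the
#' epistasis contributions, `V_QE`/`V_QQE` of the sex-interaction
#' contributions; `V_eps` is the mean squared residual, and the phenotypic
#' variance `V_P` is their sum. Per-term contributions (the variance of each
#' term's own fitted contribution) are attached for per-locus heritability.
#'
#' @param object a `qtx_fit`, or (for `qtx_varcomp()`) explicit components.
#' @param coefs optional coefficient vector to use instead of the
#'   least-squares estimates (e.g. Gibbs posterior means).
#' @param ... unused.
#' @return An object of class `qtx_varcomp`.
#' @export
variance_components <- function(object, coefs = NULL, ...) {
  UseMethod("variance_components")
}

#' @export
variance_components.qtx_fit <- function(object, coefs = NULL, ...) {
  b <- coefs %||% object$coefficients
  terms <- object$design$terms
  comp <- vapply(
    c(V_Q = "main", V_QQ = "pair", V_QE = "qe", V_QQE = "qqe"),
    function(g) popvar(group_contribution(object, g, b)),
    numeric(1L)
  )
  if (is.null(coefs)) {
    v_eps <- mean(object$residuals^2)
  } else {
    v_eps <- mean((object$design$y - drop(object$design$X %*% b))^2)
  }
  per_term <- vapply(seq_len(nrow(terms)), function(i) {
    if (!(terms$group[i] %in% genetic_groups)) return(NA_real_)
    popvar(object$design$X[, i] * b[i])
  }, numeric(1L))
  names(per_term) <- terms$name
  vc <- qtx_varcomp(V_Q = comp[["V_Q"]], V_QQ = comp[["V_QQ"]],
                    V_QE = comp[["V_QE"]], V_QQE = comp[["V_QQE"]],
                    V_eps = v_eps)
  vc$per_term <- per_term[!is.na(per_term)]
  vc
}

#' @rdname variance_components
#' @param V_Q,V_QQ,V_QE,V_QQE,V_eps explicit variance components (used to
#'   push externally obtained components through the same heritability
#'   decomposition code path).
#' @export
qtx_varcomp <- function(V_Q = 0, V_QQ = 0, V_QE = 0, V_QQE = 0, V_eps = 0) {
  comp <- c(V_Q = V_Q, V_QQ = V_QQ, V_QE = V_QE, V_QQE = V_QQE, V_eps = V_eps)
  if (any(comp < 0)) stopf("variance components must be non-negative")
  structure(
    list(V_Q = V_Q, V_QQ = V_QQ, V_QE = V_QE, V_QQE = V_QQE, V_eps = V_eps,
         V_P = sum(comp), per_term = NULL),
    class = "qtx_varcomp"
  )
}

#' @export
print.qtx_varcomp <- function(x, ...) {
  cat(sprintf(
    "variance components: V_Q = %.4g, V_QQ = %.4g, V_QE = %.4g, V_QQE = %.4g, V_eps = %.4g; V_P = %.4g\n",
    x$V_Q, x$V_QQ, x$V_QE, x$V_QQE, x$V_eps, x$V_P
  ))
  invisible(x)
}

#' Heritability decomposition
#'
#' Relative contribution of each genetic variance component to phenotypic
#' variance: `h2_Q = V_Q / V_P` and analogously for the epistatic and
#' sex-interaction components; total heritability is their sum,
#' `h2_T = h2_Q + h2_QQ + h2_QE + h2_QQE`. For a fitted model, per-term
#' heritabilities (each term's own contribution variance over `V_P`) are
#' attached.
#'
#' @param object a `qtx_fit` or `qtx_varcomp`.
#' @param ... passed on.
#' @return An object of class `qtx_heritability` (a list of h2 values).
#' @export
heritability <- function(object, ...) UseMethod("heritability")

#' @export
heritability.qtx_fit <- function(object, coefs = NULL, ...) {
  heritability(variance_components(object, coefs = coefs))
}

#' @export
heritability.qtx_varcomp <- function(object, ...) {
  if (object$V_P <= 0) stopf("phenotypic variance is zero; heritability undefined")
  h <- list(
    h2_Q = object$V_Q / object$V_P,
    h2_QQ = object$V_QQ / object$V_P,
    h2_QE = object$V_QE / object$V_P,
    h2_QQE = object$V_QQE / object$V_P
  )
  h$h2_T <- h$h2_Q + h$h2_QQ + h$h2_QE + h$h2_QQE
  if (!is.null(object$per_term)) {
    h$per_term <- object$per_term / object$V_P
  }
  h$components <- object
  class(h) <- "qtx_heritability"
  h
}

#' @export
print.qtx_heritability <- function(x, ...) {
  cat(sprintf(
    "heritability: h2_Q = %.3f, h2_QQ = %.3f, h2_QE = %.3f, h2_QQE = %.3f; h2_T = %.3f\n",
    x$h2_Q, x$h2_QQ, x$h2_QE, x$h2_QQE, x$h2_T
  ))
  invisible(x)
}

#' Determination coefficient of predicted genotypic values
#'
#' Squared Pearson correlation between the model's total predicted genotypic
#' effects (all genetic terms, residual excluded) and the observed response.
#'
#' @param fit a `qtx_fit`.
#' @param coefs optional coefficients (e.g. Gibbs posterior means).
#' @return list(genetic_values, r2).
#' @export
predict_r2 <- function(fit, coefs = NULL) {
  stopifnot(inherits(fit, "qtx_fit"))
  g <- genetic_values(fit, coefs %||% fit$coefficients)
  if (stats::var(g) == 0) {
    warnf("predicted genotypic values are constant; R2 reported as 0")
    return(list(genetic_values = g, r2 = 0))
  }
  list(genetic_values = g, r2 = stats::cor(g, fit$design$y)^2)
}
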