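# The fixed four-gene qPCR score and the platform-specific logistic refit.
#
# The published qPCR-platform score is a logistic model over delta-Ct values
# of MCM2, PROS1 (up-regulated modules) and CD22, TMEM66 (down-regulated
# modules):
#   s = -27.28 - 3.43*MCM2 - 0.68*PROS1 + 3.06*CD22 + 3.49*TMEM66
#   score = exp(s) / (1 + exp(s)),  high risk iff score >= 0.5.
# Delta-Ct is inversely related to transcript abundance, so the signs are
# flipped relative to the expression-scale directions.

FOUR_GENE_INTERCEPT <- -27.28
FOUR_GENE_WEIGHTS <- c(MCM2 = -3.43, PROS1 = -0.68, CD22 = 3.06, TMEM66 = 3.49)

#' The fixed four-gene qPCR score
#'
#' @param mcm2,pros1,cd22,tmem66 delta-Ct values (vectors recycle together).
#' @return score(s) in (0, 1); high risk iff score >= 0.5.
#' @examples
#' four_gene_score(-27.28 / 3.43, 0, 0, 0)  # linear predictor 0 -> 0.5
#' @export
four_gene_score <- function(mcm2, pros1, cd22, tmem66) {
  vals <- cbind(mcm2, pros1, cd22, tmem66)
  if (any(!is.finite(vals))) stopf("delta-Ct inputs must be finite")
  s <- FOUR_GENE_INTERCEPT +
    FOUR_GENE_WEIGHTS[["MCM2"]] * vals[, 1L] +
    FOUR_GENE_WEIGHTS[["PROS1"]] * vals[, 2L] +
    FOUR_GENE_WEIGHTS[["CD22"]] * vals[, 3L] +
    FOUR_GENE_WEIGHTS[["TMEM66"]] * vals[, 4L]
  logistic(unname(s))
}

#' The four-gene score as a platform-logistic model object
#' @return a `platform_logistic` with the published intercept, weights,
#'   cutoff 0.5 and qPCR delta-Ct platform tag.
#' @export
four_gene_model <- function() {
  structure(list(intercept = FOUR_GENE_INTERCEPT,
                 coefficients = FOUR_GENE_WEIGHTS,
                 se = NULL, cutoff = 0.5, platform = "qpcr_deltact",
                 converged = TRUE, ridged = FALSE),
            class = "platform_logistic")
}

#' @export
predict.platform_logistic <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "expr_matrix")) as.matrix(newdata) else newdata
  gn <- names(object$coefficients)
  miss <- setdiff(gn, rownames(x))
  if (length(miss)) stopf("missing gene row(s): %s", paste(miss, collapse = ", "))
  s <- object$intercept + drop(crossprod(x[gn, , drop = FALSE],
                                         object$coefficients))
  out <- logistic(s)
  names(out) <- colnames(x)
  out
}

#' @export
coef.platform_logistic <- function(object, ...)
  c("(Intercept)" = object$intercept, object$coefficients)

#' @export
print.platform_logistic <- function(x, ...) {
  cat("platform_logistic [", x$platform, "], cutoff ", x$cutoff, "\n", sep = "")
  print(coef(x))
  if (x$ridged) cat("  (ridge-stabilized fit)\n")
  invisible(x)
}

#' Refit the gene score for a new platform by extreme-group logistic regression
#'
#' Emulates the published qPCR re-optimization: patients with an observed
#' death before `t_low` months form the high-risk extreme, patients surviving
#' (event or censoring time) beyond `t_high` months the low-risk extreme;
#' everyone else is excluded.  A logistic model of the gene values is fitted
#' by Newton-Raphson maximum likelihood; if the fit does not converge or the
#' groups are perfectly separated, a small ridge penalty (1e-4) is applied
#' with a warning rather than returning divergent coefficients.
#'
#' @param expr [expr_matrix()] on the target platform (e.g. delta-Ct).
#' @param pheno [phenotype_table()] with `survival_time` and `event`.
#' @param genes model genes (rows of `expr`).
#' @param t_low,t_high extreme-group boundaries in months (default 12 / 24).
#' @param max_iter,tol Newton iteration controls.
#' @return a `platform_logistic` with fitted `intercept`, `coefficients`,
#'   standard errors `se`, and `cutoff = 0.5`.
#' @export
fit_platform_logistic <- function(expr, pheno, genes, t_low = 12, t_high = 24,
                                  max_iter = 100L, tol = 1e-8) {
  if (t_low > t_high) stopf("t_low must be <= t_high")
  ord <- match(samples(expr), pheno$sample_id)
  if (anyNA(ord)) stopf("samples missing from the phenotype table")
  times <- pheno$survival_time[ord]; events <- pheno$event[ord]
  high <- events == 1 & times < t_low
  low <- times > t_high
  keep <- which(high | low)
  if (!any(high) || !any(low))
    stopf("an extreme group is empty (deaths < %g months: %d; survivors > %g months: %d)",
          t_low, sum(high), t_high, sum(low))
  x <- t(as.matrix(expr)[genes, keep, drop = FALSE])
  y <- as.numeric(high[keep])
  X <- cbind(`(Intercept)` = 1, x)
  fit <- newton_logistic(X, y, max_iter = max_iter, tol = tol, ridge = 0)
  if (!fit$converged || max(abs(fit$beta)) > 30) {
    warnf("logistic fit unstable (separation suspected): refitting with ridge 1e-4")
    fit <- newton_logistic(X, y, max_iter = max_iter, tol = tol, ridge = 1e-4)
    fit$ridged <- TRUE
  }
  beta <- drop(fit$beta)
  names(beta) <- colnames(X)
  structure(list(intercept = beta[[1L]], coefficients = beta[-1L],
                 se = fit$se, cutoff = 0.5, platform = expr$platform,
                 converged = fit$converged, ridged = isTRUE(fit$ridged),
                 n = length(y), n_high = sum(y)),
            class = "platform_logistic")
}

# Newton-Raphson (IRLS) for logistic MLE with optional ridge penalty on all
# coefficients including the intercept (penalty only used as a separation
# fallback)
newton_logistic <- function(X, y, max_iter = 100L, tol = 1e-8, ridge = 0) {
  p <- ncol(X)
  beta <- rep(0, p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- logistic(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    H <- crossprod(X, X * w) + diag(ridge, p)
    g <- crossprod(X, y - mu) - ridge * beta
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  mu <- logistic(eta)
  H <- crossprod(X, X * pmax(mu * (1 - mu), 1e-12)) + diag(ridge, p)
  se <- tryCatch({
    v <- diag(solve(H)); names(v) <- colnames(X); sqrt(v)
  }, error = function(e) rep(NA_real_, p))
  list(beta = beta, se = se, converged = converged)
}
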