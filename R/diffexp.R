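# Two-group moderated-t differential expression with empirical-Bayes
# variance shrinkage, estimated by closed-form moment matching on the log
# pooled variances:
#   z_g = log s_g^2,  e_g = z_g - digamma(d_g/2) + log(d_g/2)
#   trigamma(d0/2) = var(e) - trigamma(d_g/2)   (d0 = Inf if RHS <= 0)
#   log s0^2 = mean(e) + digamma(d0/2) - log(d0/2)
# Shrunken variance: s~_g^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g), and the
# moderated t has d0 + d_g degrees of freedom.

# Newton inversion of trigamma, monotone decreasing on (0, Inf)
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Empirical-Bayes prior for the moderated t
#'
#' Moment-matching estimate of the scaled inverse-chi-square prior
#' (`d0`, `s0_sq`) from per-gene pooled variances.  `d0` is capped at `1e6`,
#' representing an effectively infinite prior.
#'
#' @param s2 per-gene pooled sample variances (positive entries used).
#' @param d residual degrees of freedom (scalar).
#' @return list with `d0` and `s0_sq`.
#' @export
estimate_eb_prior <- function(s2, d) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 2L) stopf("need >= 2 positive variances to estimate the prior")
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  ev <- stats::var(e) - trigamma(d / 2)
  if (is.finite(ev) && ev > 0) {
    d0 <- 2 * trigamma_inverse(ev)
    d0 <- min(d0, 1e6)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess spread in the log variances: effectively infinite prior df,
    # prior variance = the common variance level
    d0 <- 1e6
    s0_sq <- mean(s2)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated-t two-group differential expression
#'
#' Compares high- vs low-risk samples gene by gene with an empirical-Bayes
#' moderated t-statistic (pooled two-sample design).  Log fold change is
#' `mean(high) - mean(low)` in the matrix's log units.  P-values are
#' two-sided from a t distribution with `d0 + d_g` degrees of freedom;
#' `fdr` is the Benjamini-Hochberg adjustment.
#'
#' @param expr an [expr_matrix()].
#' @param pheno a [phenotype_table()] whose `risk_label` labels every sample
#'   of `expr` as `"high"` or `"low"`; each group needs >= 2 samples.
#' @param d0_override optional: force the prior degrees of freedom (0 gives
#'   the ordinary pooled t; `Inf` the z-like limit with variance `s0_sq`).
#' @param s0_sq_override optional prior variance, used with `d0_override`.
#' @return a `de_result` data.frame (one row per gene, ordered as `expr`):
#'   `gene`, `mean_high`, `mean_low`, `log_fc`, `pooled_sd`, `moderated_t`,
#'   `p_value`, `fdr`, `direction`, `rank`; the estimated prior is in
#'   `attr(, "prior")`.
#' @export
moderated_t_test <- function(expr, pheno, d0_override = NULL,
                             s0_sq_override = NULL) {
  lab <- pheno$risk_label[match(samples(expr), pheno$sample_id)]
  if (any(is.na(lab)))
    stopf("every sample must have a high/low risk_label")
  x <- as.matrix(expr)
  hi <- x[, lab == "high", drop = FALSE]
  lo <- x[, lab == "low", drop = FALSE]
  n1 <- ncol(hi); n2 <- ncol(lo)
  if (n1 < 2L || n2 < 2L) stopf("each group needs >= 2 samples (got %d/%d)", n1, n2)
  mean_high <- rowMeans(hi); mean_low <- rowMeans(lo)
  v1 <- apply(hi, 1L, stats::var); v2 <- apply(lo, 1L, stats::var)
  d <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
  log_fc <- mean_high - mean_low
  zero_var <- s2 <= 0
  if (any(zero_var))
    warnf("%d gene(s) with zero variance in both groups: p set to 1", sum(zero_var))
  if (is.null(d0_override)) {
    prior <- estimate_eb_prior(s2, d)
  } else {
    if (is.infinite(d0_override)) d0_override <- 1e6
    prior <- list(d0 = d0_override,
                  s0_sq = s0_sq_override %||% estimate_eb_prior(s2, d)$s0_sq)
  }
  d0 <- prior$d0; s0_sq <- prior$s0_sq
  if (d0 > 0) {
    s2_tilde <- (d0 * s0_sq + d * s2) / (d0 + d)
  } else {
    s2_tilde <- s2
  }
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, log_fc / se, 0)
  df_total <- d0 + d
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  p[zero_var] <- 1
  tstat[zero_var] <- 0
  fdr <- benjamini_hochberg(p)
  gid <- genes(expr)
  # deterministic ranks: ascending p, ties by |log_fc| descending, then id
  ord <- order(p, -abs(log_fc), gid)
  rank <- integer(length(p)); rank[ord] <- seq_along(p)
  out <- data.frame(gene = gid, mean_high = mean_high, mean_low = mean_low,
                    log_fc = log_fc, pooled_sd = sqrt(s2),
                    moderated_t = tstat, p_value = p, fdr = fdr,
                    direction = ifelse(log_fc > 0, "up", "down"),
                    rank = rank, row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "prior") <- prior
  attr(out, "group_sizes") <- c(high = n1, low = n2)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with enforced monotonicity; order of the output
#' matches the input.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted values, elementwise >= input and <= 1.
#' @export
benjamini_hochberg <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stopf("p-values must be in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Select candidate prognostic genes at an FDR cutoff
#'
#' @param de a `de_result` from [moderated_t_test()].
#' @param fdr_cutoff FDR threshold in (0, 1).
#' @return list with `up` and `down`: gene ids with `fdr < fdr_cutoff`, split
#'   by fold-change direction, each ordered by ascending p (via `rank`).
#' @export
select_candidates <- function(de, fdr_cutoff = 0.05) {
  if (fdr_cutoff <= 0 || fdr_cutoff >= 1) stopf("fdr_cutoff must be in (0, 1)")
  keep <- de[de$fdr < fdr_cutoff, , drop = FALSE]
  keep <- keep[order(keep$rank), , drop = FALSE]
  list(up = keep$gene[keep$direction == "up"],
       down = keep$gene[keep$direction == "down"])
}

#' @export
print.de_result <- function(x, ...) {
  pr <- attr(x, "prior")
  cat(sprintf("de_result: %d genes; prior d0 = %.4g, s0^2 = %.4g\n",
              nrow(x), pr$d0, pr$s0_sq))
  cat(sprintf("  fdr < 0.05: %d up, %d down\n",
              sum(x$fdr < 0.05 & x$direction == "up"),
              sum(x$fdr < 0.05 & x$direction == "down")))
  invisible(x)
}
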