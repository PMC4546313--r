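# Representative-gene selection and the Gaussian naive-Bayes prognostic
# classifier, with leave-one-out cross-validation to size the model.

#' Select the representative gene of a functional core
#'
#' Among core genes whose mean expression across all training samples exceeds
#' the median of all genes' means (the "expressed above half the genome"
#' filter), the gene with the smallest differential-expression p is chosen.
#' If no core gene passes the filter, the smallest-p core gene is returned
#' with `passed_expression_filter = FALSE` and a warning.
#'
#' @param core a [functional_core()].
#' @param de a `de_result` from [moderated_t_test()].
#' @param expr the training [expr_matrix()].
#' @return a `representative_gene`: list with `gene_id`, `parent`, `de_p`,
#'   `de_rank`, `passed_expression_filter`.
#' @export
select_representative <- function(core, de, expr) {
  cg <- core$core_genes
  if (!length(cg)) stopf("empty functional core")
  x <- as.matrix(expr)
  gene_means <- rowMeans(x)
  cutoff <- stats::median(gene_means)
  cand <- de[match(cg, de$gene), , drop = FALSE]
  if (any(is.na(cand$gene))) stopf("core genes absent from the DE result")
  passes <- gene_means[cg] > cutoff
  pool <- if (any(passes)) cand[passes, , drop = FALSE] else cand
  pool <- pool[order(pool$rank), , drop = FALSE]
  if (!any(passes))
    warnf("no core gene above median expression; falling back to smallest p (%s)",
          pool$gene[1L])
  structure(list(gene_id = pool$gene[1L], parent = core,
                 de_p = pool$p_value[1L], de_rank = pool$rank[1L],
                 passed_expression_filter = any(passes)),
            class = "representative_gene")
}

#' Train a Gaussian naive-Bayes classifier
#'
#' Per class (high/low) and per gene, a Gaussian is fitted by the sample mean
#' and unbiased variance (floored at `1e-9` against degenerate folds); class
#' priors are the class frequencies.
#'
#' @param expr training [expr_matrix()].
#' @param genes model genes (present in `expr`).
#' @param pheno [phenotype_table()] labelling every sample high/low; >= 2
#'   samples per class.
#' @param cutoff posterior threshold for classification (default 0.5).
#' @return an `nb_model`: gene vector, per-class mean/variance vectors,
#'   priors, cutoff.
#' @export
train_naive_bayes <- function(expr, genes, pheno, cutoff = 0.5) {
  x <- as.matrix(expr)
  miss <- setdiff(genes, rownames(x))
  if (length(miss)) stopf("model genes absent from matrix: %s",
                          paste(miss, collapse = ", "))
  lab <- pheno$risk_label[match(colnames(x), pheno$sample_id)]
  if (any(is.na(lab))) stopf("every sample must be labelled high/low")
  if (min(table(lab)) < 2L) stopf("each class needs >= 2 samples")
  xg <- x[genes, , drop = FALSE]
  fit_class <- function(cls) {
    xc <- xg[, lab == cls, drop = FALSE]
    list(mean = rowMeans(xc),
         var = pmax(apply(xc, 1L, stats::var), 1e-9))
  }
  hi <- fit_class("high"); lo <- fit_class("low")
  structure(list(genes = genes,
                 mean_high = hi$mean, var_high = hi$var,
                 mean_low = lo$mean, var_low = lo$var,
                 prior_high = mean(lab == "high"),
                 prior_low = mean(lab == "low"),
                 cutoff = cutoff),
            class = "nb_model")
}

#' Posterior high-risk probability under a naive-Bayes model
#'
#' Computed in log space: the log joint of each class is the log prior plus
#' the sum of Gaussian log densities, and the posterior is the softmax of the
#' two, so extreme inputs cannot overflow.
#'
#' @param model an `nb_model`.
#' @param sample_values named numeric vector covering the model genes, or a
#'   gene-by-sample matrix / [expr_matrix()].
#' @return posterior probability (or per-sample vector) in (0, 1).
#' @export
predict_score <- function(model, sample_values) {
  if (inherits(sample_values, "expr_matrix"))
    sample_values <- as.matrix(sample_values)
  x <- if (is.matrix(sample_values)) sample_values
       else matrix(sample_values, ncol = 1L,
                   dimnames = list(names(sample_values), "sample"))
  miss <- setdiff(model$genes, rownames(x))
  if (length(miss)) stopf("missing gene value(s): %s", paste(miss, collapse = ", "))
  xg <- x[model$genes, , drop = FALSE]
  if (any(!is.finite(xg))) stopf("non-finite gene values")
  ll <- function(mu, v, prior)
    log(prior) + colSums(stats::dnorm(xg, mean = mu, sd = sqrt(v), log = TRUE))
  lh <- ll(model$mean_high, model$var_high, model$prior_high)
  llo <- ll(model$mean_low, model$var_low, model$prior_low)
  out <- 1 / (1 + exp(llo - lh))
  # posteriors live strictly inside (0, 1): clamp the float round-off at
  # astronomically extreme inputs
  out <- pmin(pmax(out, .Machine$double.xmin), 1 - 2^-53)
  names(out) <- colnames(x)
  out
}

# LOO posterior scores: score[i] comes from a model fitted without sample i
nb_loo_scores <- function(expr, genes, pheno) {
  x <- as.matrix(expr)
  n <- ncol(x)
  vapply(seq_len(n), function(i) {
    fold_expr <- expr_matrix(x[, -i, drop = FALSE], expr$platform)
    lab_rest <- pheno$risk_label[match(colnames(x)[-i], pheno$sample_id)]
    if (min(table(lab_rest)) < 2L) return(NA_real_)
    m <- train_naive_bayes(fold_expr, genes, pheno)
    predict_score(m, x[, i])
  }, numeric(1))
}

#' Size the model by leave-one-out cross-validation
#'
#' For `k = 1..K`, the candidate gene set is the top `k` up- plus top `k`
#' down-module representatives (paired nested subsets).  Each candidate is
#' scored by leave-one-out: the naive Bayes is refitted on `n - 1` samples,
#' the held-out sample's posterior is dichotomized at 0.5, and performance is
#' the log-rank test between the predicted groups on the training survival.
#' The selected `k` minimizes the log-rank p (ties: larger hazard ratio, then
#' smaller `k`); the final model is refitted on all samples.
#'
#' @param expr training [expr_matrix()].
#' @param pheno [phenotype_table()] with `risk_label`, `survival_time`,
#'   `event` for every sample.
#' @param up_reps,down_reps representative gene ids ordered by module rank;
#'   equal lengths `K`.
#' @return a `loocv_result`: `k` (selected pair count), `model` (refitted
#'   `nb_model`), `cv` (per-k table: `k`, `logrank_p`, `hazard_ratio`,
#'   `n_predicted_high`), `loo_scores` for the selected `k`, and
#'   `significant` flag (selected log-rank p < 0.05).
#' @export
loocv_select <- function(expr, pheno, up_reps, down_reps) {
  if (length(up_reps) != length(down_reps))
    stopf("up and down representative lists must have equal length")
  K <- length(up_reps)
  if (!K) stopf("no representative genes supplied")
  ord <- match(samples(expr), pheno$sample_id)
  times <- pheno$survival_time[ord]; events <- pheno$event[ord]
  cv <- data.frame(k = seq_len(K), logrank_p = NA_real_,
                   hazard_ratio = NA_real_, n_predicted_high = NA_integer_)
  scores_by_k <- vector("list", K)
  for (k in seq_len(K)) {
    gset <- c(up_reps[seq_len(k)], down_reps[seq_len(k)])
    sc <- tryCatch(nb_loo_scores(expr, gset, pheno), error = function(e) NULL)
    if (is.null(sc) || anyNA(sc)) {
      warnf("skipping k = %d: a LOO fold had a singleton class", k)
      next
    }
    scores_by_k[[k]] <- sc
    grp <- as.integer(sc >= 0.5)
    cv$n_predicted_high[k] <- sum(grp)
    if (length(unique(grp)) < 2L) next
    lr <- logrank_test(times, events, grp)
    cv$logrank_p[k] <- lr$p_value
    fit <- tryCatch(cox_ph(times, events,
                           data.frame(predicted_high = grp)),
                    error = function(e) NULL)
    cv$hazard_ratio[k] <- if (is.null(fit)) NA_real_ else fit$hazard_ratios[[1L]]
  }
  usable <- which(!is.na(cv$logrank_p))
  if (length(usable)) {
    hr <- ifelse(is.na(cv$hazard_ratio), -Inf, cv$hazard_ratio)
    best <- usable[order(cv$logrank_p[usable], -hr[usable], cv$k[usable])][1L]
  } else {
    warnf("no candidate size produced a two-group split; defaulting to k = %d", K)
    best <- K
  }
  gset <- c(up_reps[seq_len(best)], down_reps[seq_len(best)])
  model <- train_naive_bayes(expr, gset, pheno)
  structure(list(k = best, model = model, cv = cv,
                 loo_scores = scores_by_k[[best]],
                 significant = isTRUE(cv$logrank_p[best] < 0.05)),
            class = "loocv_result")
}

#' @export
print.nb_model <- function(x, ...) {
  cat(sprintf("nb_model: %d genes, priors high/low = %.2f/%.2f, cutoff %.2f\n",
              length(x$genes), x$prior_high, x$prior_low, x$cutoff))
  cat("  genes:", paste(x$genes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("loocv_result: selected k = %d (%d genes)%s\n", x$k,
              2L * x$k, if (x$significant) "" else " [cv not significant]"))
  print(x$cv, row.names = FALSE)
  invisible(x)
}
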