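# End-to-end model fitting: differential expression -> per-reference module
# detection -> stability calling and balancing -> functional cores ->
# representative genes -> naive-Bayes sizing by leave-one-out
# cross-validation.

#' Fit a module-based prognostic model
#'
#' Runs the full integrative pipeline on a labelled training cohort and two
#' unlabelled reference cohorts:
#' \enumerate{
#'   \item moderated-t differential expression (high vs low risk) and
#'     candidate selection at `fdr_cutoff`;
#'   \item co-expression module detection over the up- and the down-regulated
#'     candidates, separately in each reference cohort;
#'   \item cross-cohort stability calling (Fisher overlap, `stability_alpha`)
#'     and balancing of the up/down lists to equal length;
#'   \item functional-core extraction against canonical pathways with a
#'     cell-type-signature fallback;
#'   \item representative-gene selection and naive-Bayes training, with the
#'     model size (number of up/down pairs) chosen by leave-one-out
#'     cross-validation against the training survival.
#' }
#'
#' @param train_expr training [expr_matrix()].
#' @param train_pheno [phenotype_table()] with `risk_label`, `survival_time`
#'   and `event` for every training sample.
#' @param reference1,reference2 reference [expr_matrix()]s (no labels
#'   needed).
#' @param pathways,celltypes [gene_set_collection()]s for annotation.
#' @param fdr_cutoff candidate FDR threshold (default 0.05).
#' @param params [network_params()] for module detection.
#' @param stability_alpha Fisher overlap threshold for stability (default
#'   0.01).
#' @param core_p_threshold pathway-enrichment threshold for functional cores
#'   (default `1e-4`).
#' @return a `prognostic_model` with components `de`, `candidates`,
#'   `assignments`, `overlaps`, `stable`, `cores`, `representatives`, `cv`
#'   (the [loocv_select()] result), `nb` (the final `nb_model`) and
#'   `training` (expr/pheno references).
#' @seealso [predict.prognostic_model()], [fit_calibration()],
#'   [evaluate_score()]
#' @export
fit_prognostic_model <- function(train_expr, train_pheno,
                                 reference1, reference2,
                                 pathways, celltypes,
                                 fdr_cutoff = 0.05,
                                 params = network_params(),
                                 stability_alpha = 0.01,
                                 core_p_threshold = 1e-4) {
  de <- moderated_t_test(train_expr, train_pheno)
  candidates <- select_candidates(de, fdr_cutoff)
  if (!length(candidates$up) || !length(candidates$down))
    stopf("no candidate genes in one direction at fdr < %g", fdr_cutoff)
  universe <- genes(train_expr)

  assignments <- list(); overlaps <- list(); stable <- list()
  for (dir in c("up", "down")) {
    cand <- candidates[[dir]]
    a1 <- detect_modules(reference1,
                         intersect(cand, genes(reference1)), params,
                         dataset_tag = "reference1", direction_tag = dir)
    a2 <- detect_modules(reference2,
                         intersect(cand, genes(reference2)), params,
                         dataset_tag = "reference2", direction_tag = dir)
    ov <- overlap_table(a1, a2)
    assignments[[dir]] <- list(reference1 = a1, reference2 = a2)
    overlaps[[dir]] <- ov
    stable[[dir]] <- call_stable_modules(ov, alpha = stability_alpha)
  }
  balanced <- balance_directions(stable$up, stable$down)
  if (!length(balanced$up))
    stopf("no stable modules in both directions: cannot build a paired model")

  cores <- lapply(c(balanced$up, balanced$down), functional_core,
                  pathways = pathways, celltypes = celltypes,
                  universe = universe, p_threshold = core_p_threshold)
  reps <- lapply(cores, select_representative, de = de, expr = train_expr)
  K <- length(balanced$up)
  rep_ids <- vapply(reps, `[[`, "", "gene_id")
  up_reps <- rep_ids[seq_len(K)]
  down_reps <- rep_ids[K + seq_len(K)]

  cv <- loocv_select(train_expr, train_pheno, up_reps, down_reps)
  structure(list(de = de, candidates = candidates,
                 assignments = assignments, overlaps = overlaps,
                 stable = balanced, cores = cores, representatives = reps,
                 up_representatives = up_reps, down_representatives = down_reps,
                 cv = cv, nb = cv$model,
                 fdr_cutoff = fdr_cutoff, stability_alpha = stability_alpha,
                 params = params,
                 training = list(expr = train_expr, pheno = train_pheno)),
            class = "prognostic_model")
}

#' Score new samples with a fitted prognostic model
#'
#' @param object a `prognostic_model`.
#' @param newdata an [expr_matrix()] containing the model genes (calibrate
#'   cross-platform data first with [fit_calibration()] /
#'   [apply_calibration()]); default: the training cohort.
#' @param type `"score"` for posterior high-risk probabilities, `"class"`
#'   for high/low labels at the model cutoff.
#' @param ... unused.
#' @return named numeric vector of scores, or character vector of labels.
#' @export
predict.prognostic_model <- function(object, newdata = NULL,
                                     type = c("score", "class"), ...) {
  type <- match.arg(type)
  newdata <- newdata %||% object$training$expr
  sc <- predict_score(object$nb, newdata)
  if (type == "score") sc
  else ifelse(sc >= object$nb$cutoff, "high", "low")
}

#' @export
coef.prognostic_model <- function(object, ...) {
  m <- object$nb
  data.frame(gene = m$genes,
             direction = rep(c("up", "down"), each = object$cv$k),
             mean_high = m$mean_high, mean_low = m$mean_low,
             var_high = m$var_high, var_low = m$var_low,
             row.names = NULL)
}

#' @export
print.prognostic_model <- function(x, ...) {
  cat("prognostic_model\n")
  cat(sprintf("  candidates (fdr < %g): %d up, %d down\n", x$fdr_cutoff,
              length(x$candidates$up), length(x$candidates$down)))
  cat(sprintf("  stable modules: %d per direction (alpha = %g)\n",
              length(x$stable$up), x$stability_alpha))
  cat(sprintf("  model: %d gene pairs (LOO-CV), genes: %s\n",
              x$cv$k, paste(x$nb$genes, collapse = ", ")))
  if (!is.null(x$cv$cv$logrank_p[x$cv$k]))
    cat(sprintf("  cross-validated log-rank p = %.3g\n",
                x$cv$cv$logrank_p[x$cv$k]))
  invisible(x)
}

#' @export
summary.prognostic_model <- function(object, ...) {
  core_tab <- do.call(rbind, lapply(seq_along(object$cores), function(i) {
    cr <- object$cores[[i]]; rp <- object$representatives[[i]]
    data.frame(direction = cr$parent$direction,
               module = sprintf("%s~%s", cr$parent$module_a, cr$parent$module_b),
               module_size = length(cr$parent$gene_set),
               stability_p = cr$parent$best_p,
               core_source = cr$source_collection,
               core_set = cr$source_set_name, core_size = length(cr$core_genes),
               representative = rp$gene_id, de_p = rp$de_p,
               expressed = rp$passed_expression_filter,
               in_model = rp$gene_id %in% object$nb$genes,
               row.names = NULL)
  }))
  out <- list(modules = core_tab, cv = object$cv$cv, k = object$cv$k,
              prior = attr(object$de, "prior"))
  class(out) <- "summary.prognostic_model"
  out
}

#' @export
print.summary.prognostic_model <- function(x, ...) {
  cat("Stable modules, cores and representatives:\n")
  print(x$modules, row.names = FALSE)
  cat(sprintf("\nLOO-CV model-size selection (chosen k = %d):\n", x$k))
  print(x$cv, row.names = FALSE)
  invisible(x)
}

#' Kaplan-Meier plot of the model's risk groups
#'
#' Plots the training-cohort survival curves of the groups obtained by
#' dichotomizing the model scores at the cutoff.
#'
#' @param x a `prognostic_model`.
#' @param newdata optional [expr_matrix()] + `pheno` to plot another cohort.
#' @param pheno phenotype table for `newdata`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the per-group `km_curve`s.
#' @export
plot.prognostic_model <- function(x, newdata = NULL, pheno = NULL, ...) {
  expr <- newdata %||% x$training$expr
  pheno <- pheno %||% x$training$pheno
  sc <- predict_score(x$nb, expr)
  ord <- match(names(sc), pheno$sample_id)
  grp <- as.integer(sc >= x$nb$cutoff)
  km <- lapply(split(seq_along(grp), grp), function(ix)
    kaplan_meier(pheno$survival_time[ord][ix], pheno$event[ord][ix]))
  graphics::plot(NA, xlim = c(0, max(pheno$survival_time[ord])),
                 ylim = c(0, 1), xlab = "Months", ylab = "Survival",
                 main = "Predicted risk groups", ...)
  cols <- c(`0` = "#2166AC", `1` = "#B2182B")
  for (g in names(km))
    graphics::lines(stats::stepfun(km[[g]]$time[-1], km[[g]]$surv),
                    do.points = FALSE, col = cols[[g]], lwd = 2)
  graphics::legend("bottomleft", legend = c("low risk", "high risk"),
                   col = cols, lwd = 2, bty = "n")
  invisible(km)
}
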