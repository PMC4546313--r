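# Survival evaluation machinery: Kaplan-Meier curves, log-rank tests, Cox
# proportional hazards (Efron ties) and the concordance index, backed by the
# survival package behind a stable operation surface.

#' Kaplan-Meier product-limit estimator
#'
#' @param times nonnegative survival times.
#' @param events 0/1 event indicators.
#' @return a `km_curve` data.frame (`time`, `n_risk`, `n_event`, `surv`)
#'   including the `S(0) = 1` anchor; the curve is right-continuous and
#'   non-increasing.
#' @export
kaplan_meier <- function(times, events) {
  if (!length(times)) stopf("empty input")
  if (any(times < 0)) stopf("negative survival times")
  if (!all(events %in% c(0, 1))) stopf("events must be 0/1")
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = c(0, sf$time),
                    n_risk = c(length(times), sf$n.risk),
                    n_event = c(0, sf$n.event),
                    surv = c(1, sf$surv))
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier curve at given times
#' @param km a `km_curve`.
#' @param t times at which to read off `S(t)`.
#' @return survival probabilities (right-continuous step function).
#' @export
km_survival <- function(km, t) {
  idx <- findInterval(t, km$time)
  km$surv[pmax(idx, 1L)]
}

#' Two-group log-rank test
#'
#' @param times,events as in [kaplan_meier()].
#' @param groups binary group labels (two non-empty groups).
#' @return a `logrank_test` list: `chi_square` (1 df), `p_value`,
#'   `observed`, `expected` per group.
#' @export
logrank_test <- function(times, events, groups) {
  g <- as.factor(groups)
  if (nlevels(g) != 2L) stopf("exactly two non-empty groups required")
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ g)
  chi <- sd_$chisq
  structure(list(chi_square = chi,
                 p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
                 observed = sd_$obs, expected = sd_$exp),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("log-rank: chi-square = %.4g (1 df), p = %.4g\n",
              x$chi_square, x$p_value))
  invisible(x)
}

#' Cox proportional-hazards fit (Efron ties)
#'
#' @param times,events as in [kaplan_meier()] (>= 1 event).
#' @param covariates data.frame or matrix of finite covariates (no constant
#'   columns).
#' @param ties tie handling; `"efron"` (default) or `"breslow"`.
#' @return a `survival_fit`: `coefficients`, `hazard_ratios`, `se`,
#'   `wald_p`, `lrt_p`, `score_chi_square`, `concordance`, `separation`
#'   flag, and the underlying `coxph` fit.
#' @export
cox_ph <- function(times, events, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (sum(events) < 1) stopf("need at least one event")
  cv <- as.data.frame(covariates)
  if (!nrow(cv) || !ncol(cv)) stopf("empty covariate matrix")
  if (any(!vapply(cv, function(col) all(is.finite(as.numeric(col))), TRUE)))
    stopf("covariates must be finite")
  if (any(vapply(cv, function(col) length(unique(col)) == 1L, TRUE)))
    stopf("constant covariate supplied")
  dat <- cbind(data.frame(.time = times, .event = events), cv)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(sprintf("`%s`", names(cv)), collapse = " + ")))
  separation <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties,
                    control = survival::coxph.control(eps = 1e-9, iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  # the score test at beta = 0 is well defined even under monotone
  # likelihood; keep it from the unpenalized fit
  score_chi <- fit$score
  # refit only when coefficients actually diverge; the convergence warning
  # alone also fires on small well-behaved datasets
  if (any(!is.finite(stats::coef(fit))) || any(abs(stats::coef(fit)) > 15)) {
    separation <- TRUE
    warnf("monotone likelihood suspected: refitting with a small ridge penalty")
    fml2 <- stats::as.formula(paste(
      "survival::Surv(.time, .event) ~ survival::ridge(",
      paste(sprintf("`%s`", names(cv)), collapse = ", "), ", theta = 1e-4)"))
    fit <- suppressWarnings(survival::coxph(fml2, data = dat, ties = ties))
  }
  sm <- summary(fit)
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  wald_p <- 2 * stats::pnorm(-abs(co / se))
  lrt_p <- stats::pchisq(2 * (fit$loglik[2] - fit$loglik[1]),
                         df = length(co), lower.tail = FALSE)
  structure(list(coefficients = co, hazard_ratios = exp(co), se = se,
                 wald_p = wald_p, lrt_p = lrt_p,
                 score_chi_square = score_chi,
                 concordance = unname(sm$concordance["C"]),
                 separation = separation, fit = fit),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  out <- data.frame(coef = x$coefficients, HR = x$hazard_ratios,
                    se = x$se, wald_p = x$wald_p)
  print(out)
  cat(sprintf("LRT p = %.4g; concordance = %.3f%s\n", x$lrt_p, x$concordance,
              if (x$separation) " [ridge-stabilized]" else ""))
  invisible(x)
}

#' Concordance index of a risk score
#'
#' Fraction of comparable pairs (usable under censoring) in which the subject
#' with the higher risk score dies first; score ties count 0.5.
#'
#' @param times,events as in [kaplan_meier()].
#' @param scores finite risk scores (higher = predicted shorter survival).
#' @return concordance in `[0, 1]`.
#' @export
concordance_index <- function(times, events, scores) {
  if (any(!is.finite(scores))) stopf("scores must be finite")
  cf <- survival::concordance(survival::Surv(times, events) ~ scores,
                              reverse = TRUE)
  if (cf$count[["concordant"]] + cf$count[["discordant"]] +
      cf$count[["tied.x"]] == 0) stopf("no usable pairs")
  unname(cf$concordance)
}

#' Evaluate a prognostic score against survival
#'
#' Bundles (i) a univariate Cox fit on the continuous score, (ii) the
#' Kaplan-Meier / log-rank / hazard-ratio comparison of the groups obtained
#' by dichotomizing at `cutoff`, and (iii) bivariate Cox fits of the score
#' against each co-score (per-model Wald p).
#'
#' @param score per-sample risk scores (named by sample id or aligned with
#'   `pheno`).
#' @param pheno [phenotype_table()] with `survival_time` and `event`.
#' @param cutoff dichotomization threshold (default 0.5); use
#'   `cutoff = "median"` for the in-cohort median rule used for scores
#'   lacking a published cutoff.
#' @param co_scores optional named list of competing per-sample scores.
#' @return a `score_evaluation` list: `cox` (continuous fit),
#'   `concordance`, `km` per group, `logrank`, `hazard_ratio`,
#'   `dichotomy_degenerate` flag, and `bivariate` (per co-score fits with a
#'   `collinear` flag).
#' @export
evaluate_score <- function(score, pheno, cutoff = 0.5, co_scores = NULL) {
  if (!is.null(names(score))) {
    ord <- match(names(score), pheno$sample_id)
    if (anyNA(ord)) stopf("score names missing from the phenotype table")
    pheno <- pheno[ord, , drop = FALSE]
  } else if (length(score) != nrow(pheno)) {
    stopf("unnamed score must align with the phenotype table")
  }
  times <- pheno$survival_time; events <- pheno$event
  cut_val <- if (identical(cutoff, "median")) stats::median(score) else cutoff
  grp <- as.integer(score >= cut_val)
  degenerate <- length(unique(grp)) < 2L
  cox_cont <- cox_ph(times, events, data.frame(score = score))
  out <- list(cox = cox_cont,
              concordance = concordance_index(times, events, score),
              cutoff = cut_val, dichotomy_degenerate = degenerate)
  if (degenerate) {
    warnf("dichotomization at %.3g puts all samples on one side: no group test",
          cut_val)
    out$km <- out$logrank <- out$hazard_ratio <- NULL
  } else {
    out$km <- lapply(split(seq_along(grp), grp),
                     function(ix) kaplan_meier(times[ix], events[ix]))
    out$logrank <- logrank_test(times, events, grp)
    out$hazard_ratio <- cox_ph(times, events,
                               data.frame(high = grp))$hazard_ratios[[1L]]
  }
  if (!is.null(co_scores)) {
    out$bivariate <- lapply(co_scores, function(cs) {
      if (abs(stats::cor(score, cs)) > 0.999)
        return(list(collinear = TRUE, fit = NULL))
      list(collinear = FALSE,
           fit = cox_ph(times, events, data.frame(score = score, co_score = cs)))
    })
  }
  class(out) <- "score_evaluation"
  out
}

#' @export
print.score_evaluation <- function(x, ...) {
  cat(sprintf("score_evaluation: concordance = %.3f, continuous Cox p = %.3g\n",
              x$concordance, x$cox$wald_p[[1L]]))
  if (x$dichotomy_degenerate) {
    cat("  dichotomization degenerate: no group comparison\n")
  } else {
    cat(sprintf("  groups at cutoff %.3g: HR = %.3g, log-rank p = %.3g\n",
                x$cutoff, x$hazard_ratio, x$logrank$p_value))
  }
  invisible(x)
}
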