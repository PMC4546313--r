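test_that("representative selection applies the expression filter and p rule", {
  x <- rbind(g1 = rep(c(10, 10.5), 5), g2 = rep(c(2, 2.5), 5),
             g3 = rep(c(9, 9.5), 5), g4 = rep(c(1, 1.2), 5))
  colnames(x) <- paste0("s", 1:10)
  x <- x + matrix(rnorm(40, sd = 0.1), 4, 10)
  em <- make_expr(x)
  ph <- phenotype_table(data.frame(sample_id = colnames(x),
                                   risk_label = rep(c("high", "low"), 5)))
  de <- suppressWarnings(moderated_t_test(em, ph))
  # force known p ordering: g2 smallest, then g1, g3, g4
  de$p_value <- c(1e-5, 1e-8, 1e-3, 1e-6)
  de$rank <- c(3L, 1L, 4L, 2L)
  core <- structure(list(parent = NULL, core_genes = c("g1", "g2", "g3"),
                         source_set_name = "s", source_collection = "canonical_pathway",
                         p = 1e-9), class = "functional_core")
  # g2 has the smallest p but sits below median expression -> g1 wins
  rep1 <- select_representative(core, de, em)
  expect_equal(rep1$gene_id, "g1")
  expect_true(rep1$passed_expression_filter)
  # all core genes above the median: smallest p wins outright
  core2 <- core; core2$core_genes <- c("g1", "g3")
  expect_equal(select_representative(core2, de, em)$gene_id, "g1")
  # nothing passes the filter: fall back to smallest p with a warning
  core3 <- core; core3$core_genes <- c("g2", "g4")
  expect_warning(rep3 <- select_representative(core3, de, em), "median")
  expect_equal(rep3$gene_id, "g2")
  expect_false(rep3$passed_expression_filter)
})

test_that("naive-Bayes posterior matches brute force and the symmetry cases", {
  co <- toy_cohort(n_genes = 6, n1 = 10, n2 = 10,
                   shift_genes = 1:2, shift = 2, seed = 1)
  m <- train_naive_bayes(co$expr, c("g001", "g002"), co$pheno)
  set.seed(2)
  for (i in 1:5) {
    x <- setNames(rnorm(2, 0.5, 2), c("g001", "g002"))
    expect_equal(unname(predict_score(m, x)), nb_oracle(m, x),
                 tolerance = 1e-12)
  }
  # symmetric single gene: midpoint input -> posterior exactly 1/2
  ms <- structure(list(genes = "g", mean_high = c(g = 2), var_high = c(g = 1),
                       mean_low = c(g = 0), var_low = c(g = 1),
                       prior_high = 0.5, prior_low = 0.5, cutoff = 0.5),
                  class = "nb_model")
  expect_equal(unname(predict_score(ms, c(g = 1))), 0.5, tolerance = 1e-12)
  # identical class distributions: posterior == prior for any input
  mi <- ms; mi$mean_low <- c(g = 2); mi$prior_high <- 0.3; mi$prior_low <- 0.7
  expect_equal(unname(predict_score(mi, c(g = 37))), 0.3, tolerance = 1e-12)
  # extreme inputs stay finite in (0, 1): log-space contract
  p_ext <- predict_score(ms, c(g = 1e6))
  expect_true(is.finite(p_ext) && p_ext > 0 && p_ext < 1)
  expect_equal(unname(predict_score(ms, c(g = -1e6))) > 0, TRUE)
  expect_error(predict_score(ms, c(h = 1)), "missing gene")
})

test_that("naive Bayes agrees with the reference implementation", {
  skip_if_not_installed("e1071")
  co <- toy_cohort(n_genes = 4, n1 = 12, n2 = 12,
                   shift_genes = 1:2, shift = 1.5, seed = 3)
  gset <- c("g001", "g002", "g003")
  m <- train_naive_bayes(co$expr, gset, co$pheno)
  ref <- e1071::naiveBayes(t(as.matrix(co$expr)[gset, ]),
                           factor(co$pheno$risk_label))
  newx <- t(as.matrix(co$expr)[gset, 1:5])
  p_ref <- predict(ref, newx, type = "raw")[, "high"]
  p_our <- predict_score(m, t(newx))
  expect_equal(unname(p_our), unname(p_ref), tolerance = 1e-6)
})

test_that("LOO-CV sizes the model by survival separation without leakage", {
  set.seed(4)
  # construct a cohort where the first up/down pair separates perfectly
  n <- 40
  risk <- rep(c(1, 0), each = n / 2)
  x <- matrix(rnorm(6 * n, sd = 0.3), 6, n,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:n)))
  x[1, ] <- x[1, ] + 6 * risk      # up pair member, huge signal
  x[4, ] <- x[4, ] - 6 * risk      # down pair member
  ph <- phenotype_table(data.frame(
    sample_id = colnames(x), risk_label = ifelse(risk == 1, "high", "low"),
    survival_time = ifelse(risk == 1, rexp(n, 1 / 6), rexp(n, 1 / 40))[1:n],
    event = 1))
  em <- make_expr(x)
  res <- loocv_select(em, ph, up_reps = c("g1", "g2", "g3"),
                      down_reps = c("g4", "g5", "g6"))
  expect_equal(res$k, 1L)
  expect_lt(res$cv$logrank_p[1], min(res$cv$logrank_p[-1], na.rm = TRUE) + 1e-12)
  expect_true(res$significant)
  # no leakage: flipping a held-out sample's label leaves its fold's score
  # unchanged (the fold is fitted without that sample)
  sc <- prognomod:::nb_loo_scores(em, c("g1", "g4"), ph)
  ph_flip <- ph
  ph_flip$risk_label[7] <- ifelse(ph$risk_label[7] == "high", "low", "high")
  sc_flip <- prognomod:::nb_loo_scores(em, c("g1", "g4"), ph_flip)
  expect_equal(sc[7], sc_flip[7], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(sc[-7], sc_flip[-7])))
})

test_that("LOO-CV on null genes still returns a model, rarely flagged significant", {
  sig <- vapply(1:5, function(s) {
    set.seed(s)
    co <- toy_cohort(n_genes = 4, n1 = 15, n2 = 15, seed = s)
    ph <- co$pheno
    ph$survival_time <- rexp(30, 0.05)
    ph$event <- 1L
    res <- suppressWarnings(loocv_select(co$expr, ph,
                                         up_reps = c("g001", "g002"),
                                         down_reps = c("g003", "g004")))
    expect_s3_class(res$model, "nb_model")
    res$significant
  }, TRUE)
  expect_lte(sum(sig), 2L)
})

test_that("planted two-pair signal selects k = 2 in the majority of replicates", {
  picks <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 80
    risk <- rep(c(1, 0), each = n / 2)
    x <- matrix(rnorm(6 * n), 6, n,
                dimnames = list(paste0("g", 1:6), paste0("s", 1:n)))
    # modules 1-2 per direction carry signal; module 3 is null
    for (g in 1:2) x[g, ] <- x[g, ] + 1.5 * risk
    for (g in 4:5) x[g, ] <- x[g, ] - 1.5 * risk
    ph <- phenotype_table(data.frame(
      sample_id = colnames(x), risk_label = ifelse(risk == 1, "high", "low"),
      survival_time = rexp(n, 0.02 * exp(log(4) * risk)), event = 1))
    suppressWarnings(loocv_select(make_expr(x), ph,
                                  up_reps = paste0("g", 1:3),
                                  down_reps = paste0("g", 4:6))$k)
  }, 1L)
  expect_gte(sum(picks == 2L), 6L)
})

test_that("the four-gene score reproduces the published formula exactly", {
  # boundary: linear predictor 0 -> score = the universal 0.5 cutoff
  expect_equal(four_gene_score(-27.28 / 3.43, 0, 0, 0), 0.5, tolerance = 1e-12)
  # all-zero input evaluates the intercept alone
  expect_equal(four_gene_score(0, 0, 0, 0), exp(-27.28) / (1 + exp(-27.28)),
               tolerance = 1e-15)
  # unit input changes move the logit by exactly the published weights
  logit <- function(p) log(p / (1 - p))
  # base point with a moderate linear predictor so the logit is computed at
  # full float precision
  base <- c(mcm2 = -7, pros1 = 1, cd22 = 1, tmem66 = 1)
  s0 <- four_gene_score(base[1], base[2], base[3], base[4])
  bump <- function(i) {
    b <- base; b[i] <- b[i] + 1
    logit(four_gene_score(b[1], b[2], b[3], b[4])) - logit(s0)
  }
  expect_equal(bump(1), -3.43, tolerance = 1e-9)
  expect_equal(bump(2), -0.68, tolerance = 1e-9)
  expect_equal(bump(3), 3.06, tolerance = 1e-9)
  expect_equal(bump(4), 3.49, tolerance = 1e-9)
  # monotonicity sweep: increasing in CD22/TMEM66, decreasing in MCM2/PROS1
  grid <- seq(-5, 5, length.out = 21)
  s_cd22 <- four_gene_score(rep(0, 21), 0, grid, 0)
  s_tmem <- four_gene_score(rep(0, 21), 0, 0, grid)
  s_mcm2 <- four_gene_score(grid, 0, 0, 0)
  s_pros <- four_gene_score(0, grid, 0, 0)
  expect_true(all(diff(s_cd22) > 0) && all(diff(s_tmem) > 0))
  expect_true(all(diff(s_mcm2) < 0) && all(diff(s_pros) < 0))
  # scores stay inside (0, 1) even at extreme delta-Ct
  expect_true(four_gene_score(100, 100, -100, -100) >= 0)
  expect_true(four_gene_score(-100, -100, 100, 100) <= 1)
  expect_error(four_gene_score(NA, 0, 0, 0), "finite")
})

test_that("platform logistic refit recovers known coefficients", {
  set.seed(6)
  n <- 200
  g <- matrix(rnorm(4 * n), 4, n,
              dimnames = list(c("MCM2", "PROS1", "CD22", "TMEM66"),
                              sprintf("v%03d", 1:n)))
  beta <- c(-1.2, -0.4, 0.9, 1.1)
  eta <- -0.5 + drop(crossprod(g, beta))
  y <- rbinom(n, 1, plogis(eta))
  # deaths before 12 months mark the high extreme; survivors past 24 the low
  ph <- phenotype_table(data.frame(
    sample_id = colnames(g),
    survival_time = ifelse(y == 1, 6, 36), event = ifelse(y == 1, 1L, 0L)))
  em <- expr_matrix(g, "qpcr_deltact")
  fit <- fit_platform_logistic(em, ph, rownames(g))
  expect_true(all(abs(fit$coefficients - beta) < 2 * fit$se[-1]))
  # agrees with the standard IRLS fit
  gl <- glm(y ~ t(g), family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(gl)[-1]), tolerance = 1e-6)
  # predictions use the fitted logistic
  pr <- predict(fit, em)
  expect_equal(unname(pr[1]),
               plogis(fit$intercept + sum(fit$coefficients * g[, 1])),
               tolerance = 1e-12)
  expect_error(fit_platform_logistic(em, ph, rownames(g), t_low = 30,
                                     t_high = 24), "t_low")
})

test_that("null coefficients are covered and separation triggers the ridge", {
  set.seed(7)
  n <- 150
  g <- matrix(rnorm(2 * n), 2, n,
              dimnames = list(c("sig", "null"), sprintf("v%03d", 1:n)))
  y <- rbinom(n, 1, plogis(1.5 * g[1, ]))
  ph <- phenotype_table(data.frame(
    sample_id = colnames(g),
    survival_time = ifelse(y == 1, 6, 36), event = ifelse(y == 1, 1L, 0L)))
  fit <- fit_platform_logistic(expr_matrix(g, "qpcr_deltact"), ph, rownames(g))
  ci <- fit$coefficients["null"] + c(-2, 2) * fit$se["null"]
  expect_true(ci[1] < 0 && ci[2] > 0)
  # perfectly separated data: ridge fallback with a warning, finite coefs
  g2 <- matrix(c(rep(-2, 10), rep(2, 10)), 1, 20,
               dimnames = list("sep", sprintf("v%03d", 1:20)))
  y2 <- rep(c(0, 1), each = 10)
  ph2 <- phenotype_table(data.frame(
    sample_id = colnames(g2),
    survival_time = ifelse(y2 == 1, 6, 36), event = ifelse(y2 == 1, 1L, 0L)))
  expect_warning(fit2 <- fit_platform_logistic(expr_matrix(g2, "qpcr_deltact"),
                                               ph2, "sep"), "ridge")
  expect_true(all(is.finite(coef(fit2))))
  expect_true(fit2$ridged)
})
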