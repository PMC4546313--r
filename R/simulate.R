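# Multi-cohort synthetic-data generator.
#
# The generator emulates the study design the pipeline assumes: two large
# unlabelled reference cohorts sharing planted co-expression modules (used
# only for network construction), one labelled training cohort with survival
# in which the module genes are group-shifted, and RNA-seq / qPCR validation
# views obtained from a latent cohort through per-gene affine platform
# distortion.  Co-expression blocks follow a one-factor model per module:
# x_g = mu_g + noise_sd * (sqrt(rho) * f + sqrt(1 - rho) * eps), which gives
# expected within-block pairwise correlation rho exactly.

#' Specify a planted co-expression module
#'
#' @param name module name.
#' @param size gene count (>= 5).
#' @param direction `"up"`, `"down"` (group shift sign in the training
#'   cohort) or `"null"` (co-expressed but not prognostic).
#' @param within_correlation target pairwise correlation of module genes in
#'   the reference cohorts; in `[0, 1)`.
#' @param effect_size mean high-minus-low group shift in the training cohort,
#'   log2 units; sign must agree with `direction`.
#' @param shared if `TRUE` the module is planted in both reference cohorts,
#'   else only in reference 1.
#' @return a `module_spec` list.
#' @export
module_spec <- function(name, size, direction = c("up", "down", "null"),
                        within_correlation = 0.7,
                        effect_size = switch(match.arg(direction),
                                             up = 1, down = -1, null = 0),
                        shared = TRUE) {
  direction <- match.arg(direction)
  if (size < 5L) stopf("module size must be >= 5")
  if (within_correlation < 0 || within_correlation >= 1)
    stopf("within_correlation must be in [0, 1)")
  ok <- switch(direction, up = effect_size > 0, down = effect_size < 0,
               null = effect_size == 0)
  if (!ok) stopf("effect_size sign inconsistent with direction \"%s\"", direction)
  structure(list(name = name, size = as.integer(size), direction = direction,
                 within_correlation = within_correlation,
                 effect_size = effect_size, shared = isTRUE(shared)),
            class = "module_spec")
}

default_module_specs <- function() {
  list(module_spec("up_module_1", 25, "up", 0.7, 1.5),
       module_spec("up_module_2", 25, "up", 0.7, 1.5),
       module_spec("down_module_1", 25, "down", 0.7, -1.5),
       module_spec("down_module_2", 25, "down", 0.7, -1.5))
}

default_platform_maps <- function() {
  list(rnaseq = list(offset_sd = 2, gain_min = 0.8, gain_max = 1.2,
                     noise_sd = 0.2),
       qpcr = list(intercept_mean = 25, intercept_sd = 2,
                   slope_min = 0.8, slope_max = 1.2, noise_sd = 0.2))
}

#' Configuration for the synthetic multi-cohort study
#'
#' Defaults are the desk-scale study conditions the package is exercised
#' under: 2000 genes, two reference cohorts of 200 samples, a 30+30 training
#' cohort with two up- and two down-regulated prognostic modules (within
#' correlation 0.7, planted group shift of 1.5 residual standard deviations,
#' the convention used for all planted-recovery checks), exponential
#' survival with a between-group hazard ratio of 3, light censoring (~85%
#' observed deaths, matching typical CRPC cohort follow-up), and a
#' 25-sample validation cohort.
#'
#' @param n_genes total gene count.
#' @param module_specs list of [module_spec()]; total size must be <= `n_genes`.
#' @param n_reference_1,n_reference_2 reference cohort sample counts.
#' @param n_train_high,n_train_low training group sizes.
#' @param n_validation_high,n_validation_low validation cohort group sizes.
#' @param baseline_hazard exponential baseline hazard, per month.
#' @param log_hr log hazard ratio per unit latent risk (latent risk is 1 for
#'   high-risk, 0 for low-risk samples).
#' @param censoring_rate hazard of the independent exponential censoring
#'   process, per month.
#' @param noise_sd residual standard deviation of expression values.
#' @param platform_maps affine-distortion parameters for the RNA-seq and qPCR
#'   validation views; see `default_platform_maps()`.
#' @param seed integer seed; all cohorts derive their randomness from it.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 2000,
                              module_specs = default_module_specs(),
                              n_reference_1 = 200, n_reference_2 = 200,
                              n_train_high = 30, n_train_low = 30,
                              n_validation_high = 12, n_validation_low = 13,
                              baseline_hazard = 0.02, log_hr = log(3),
                              censoring_rate = 0.005, noise_sd = 1,
                              platform_maps = default_platform_maps(),
                              seed = 1L) {
  if (!all(vapply(module_specs, inherits, TRUE, "module_spec")))
    stopf("`module_specs` must be a list of module_spec objects")
  tot <- sum(vapply(module_specs, `[[`, 1L, "size"))
  if (tot > n_genes) stopf("module sizes sum (%d) exceeds n_genes (%d)", tot, n_genes)
  counts <- c(n_reference_1, n_reference_2, n_train_high, n_train_low,
              n_validation_high, n_validation_low)
  if (any(counts < 1)) stopf("all sample counts must be positive")
  if (anyDuplicated(vapply(module_specs, `[[`, "", "name")))
    stopf("duplicate module names")
  structure(list(n_genes = as.integer(n_genes), module_specs = module_specs,
                 n_reference_1 = as.integer(n_reference_1),
                 n_reference_2 = as.integer(n_reference_2),
                 n_train_high = as.integer(n_train_high),
                 n_train_low = as.integer(n_train_low),
                 n_validation_high = as.integer(n_validation_high),
                 n_validation_low = as.integer(n_validation_low),
                 baseline_hazard = baseline_hazard, log_hr = log_hr,
                 censoring_rate = censoring_rate, noise_sd = noise_sd,
                 platform_maps = platform_maps, seed = as.integer(seed)),
            class = "simulation_config")
}

# gene ids and module membership are a deterministic function of the config
sim_gene_ids <- function(config) sprintf("G%05d", seq_len(config$n_genes))

#' Planted module membership of a configuration
#' @param config a [simulation_config()].
#' @return named list of gene-id vectors, one per module spec.
#' @export
planted_modules <- function(config) {
  ids <- sim_gene_ids(config)
  out <- list(); at <- 0L
  for (ms in config$module_specs) {
    out[[ms$name]] <- ids[(at + 1L):(at + ms$size)]
    at <- at + ms$size
  }
  out
}

# per-gene baseline means, shared by every cohort (log2-intensity-like)
sim_gene_means <- function(config) {
  set.seed(config$seed)
  stats::rnorm(config$n_genes, mean = 8, sd = 1.5)
}

# latent expression for one cohort: factor-model blocks + background noise.
# `risk` is the per-sample latent risk (0/1); prognostic modules are shifted
# by effect_size * risk with the direction's sign already in effect_size.
sim_latent_matrix <- function(config, n, risk = rep(0, n), modules_present,
                              sample_prefix) {
  mu <- sim_gene_means(config)
  blocks <- planted_modules(config)
  ids <- sim_gene_ids(config)
  x <- matrix(stats::rnorm(config$n_genes * n), config$n_genes, n)
  for (ms in config$module_specs) {
    if (!ms$name %in% modules_present) next
    rows <- match(blocks[[ms$name]], ids)
    rho <- ms$within_correlation
    f <- stats::rnorm(n)
    x[rows, ] <- sqrt(rho) * matrix(f, length(rows), n, byrow = TRUE) +
      sqrt(1 - rho) * x[rows, ]
  }
  x <- mu + config$noise_sd * x
  for (ms in config$module_specs) {
    if (!ms$name %in% modules_present || ms$effect_size == 0) next
    rows <- match(blocks[[ms$name]], ids)
    x[rows, ] <- x[rows, ] + ms$effect_size * matrix(risk, length(rows), n,
                                                     byrow = TRUE)
  }
  dimnames(x) <- list(ids, sprintf("%s%03d", sample_prefix, seq_len(n)))
  x
}

sim_survival <- function(config, risk, sample_ids) {
  hz <- config$baseline_hazard * exp(config$log_hr * risk)
  t_event <- stats::rexp(length(risk), rate = hz)
  t_cens <- stats::rexp(length(risk), rate = config$censoring_rate)
  phenotype_table(data.frame(
    sample_id = sample_ids,
    risk_label = ifelse(risk > 0, "high", "low"),
    survival_time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    stringsAsFactors = FALSE))
}

#' Simulate an unlabelled reference cohort
#'
#' Shared modules are planted in both reference cohorts (same specs,
#' independent draws); unshared modules only in reference 1.  Reference
#' cohorts carry no group shift and no survival.
#'
#' @param config a [simulation_config()].
#' @param which `1` or `2`.
#' @return an [expr_matrix()] (platform `"microarray_log2"`).
#' @export
simulate_reference_cohort <- function(config, which = 1L) {
  if (!which %in% c(1L, 2L)) stopf("`which` must be 1 or 2")
  set.seed(config$seed + which)
  present <- vapply(config$module_specs,
                    function(ms) ms$shared || which == 1L, TRUE)
  n <- if (which == 1L) config$n_reference_1 else config$n_reference_2
  x <- sim_latent_matrix(config, n, risk = rep(0, n),
                         modules_present = vapply(config$module_specs, `[[`, "",
                                                  "name")[present],
                         sample_prefix = sprintf("R%d_", which))
  expr_matrix(x, "microarray_log2",
              sprintf("synthetic reference cohort %d (seed %d)", which, config$seed))
}

#' Simulate the labelled training cohort with survival
#'
#' High-risk samples have every prognostic module shifted by its effect size;
#' survival times are exponential with hazard multiplied by
#' `exp(log_hr * latent risk)`, censored by an independent exponential.
#'
#' @param config a [simulation_config()].
#' @return list with `expr` ([expr_matrix()]) and `pheno`
#'   ([phenotype_table()] with `risk_label`, `survival_time`, `event`).
#' @export
simulate_training_cohort <- function(config) {
  set.seed(config$seed + 3L)
  n <- config$n_train_high + config$n_train_low
  risk <- c(rep(1, config$n_train_high), rep(0, config$n_train_low))
  x <- sim_latent_matrix(config, n, risk = risk,
                         modules_present = vapply(config$module_specs, `[[`, "",
                                                  "name"),
                         sample_prefix = "T")
  pheno <- sim_survival(config, risk, colnames(x))
  list(expr = expr_matrix(x, "microarray_log2",
                          sprintf("synthetic training cohort (seed %d)", config$seed)),
       pheno = pheno)
}

#' Simulate a platform-distorted validation cohort
#'
#' A latent cohort with the training cohort's structure is generated, then
#' pushed through a per-gene affine platform map.  RNA-seq view:
#' `y = offset_g + gain_g * x + noise`.  qPCR view (delta-Ct convention:
#' lower Ct = more transcript): `y = intercept_g - slope_g * x + noise` with
#' `slope_g > 0`.
#'
#' @param config a [simulation_config()].
#' @param platform `"rnaseq_log2fpkm"` or `"qpcr_deltact"`.
#' @return list with `expr` (distorted view), `latent` (undistorted
#'   [expr_matrix()]) and `pheno`.
#' @export
simulate_validation_cohort <- function(config,
                                       platform = c("rnaseq_log2fpkm",
                                                    "qpcr_deltact")) {
  platform <- match.arg(platform)
  set.seed(config$seed + if (platform == "rnaseq_log2fpkm") 4L else 5L)
  n <- config$n_validation_high + config$n_validation_low
  risk <- c(rep(1, config$n_validation_high), rep(0, config$n_validation_low))
  x <- sim_latent_matrix(config, n, risk = risk,
                         modules_present = vapply(config$module_specs, `[[`, "",
                                                  "name"),
                         sample_prefix = if (platform == "rnaseq_log2fpkm") "VR" else "VQ")
  pheno <- sim_survival(config, risk, colnames(x))
  p <- config$n_genes
  if (platform == "rnaseq_log2fpkm") {
    pm <- config$platform_maps$rnaseq
    offset <- stats::rnorm(p, 0, pm$offset_sd)
    gain <- stats::runif(p, pm$gain_min, pm$gain_max)
    y <- offset + gain * x + stats::rnorm(p * n, 0, pm$noise_sd)
  } else {
    pm <- config$platform_maps$qpcr
    offset <- stats::rnorm(p, pm$intercept_mean, pm$intercept_sd)
    gain <- stats::runif(p, pm$slope_min, pm$slope_max)
    if (any(gain <= 0)) stopf("qPCR slope must be positive")
    y <- offset - gain * x + stats::rnorm(p * n, 0, pm$noise_sd)
  }
  dimnames(y) <- dimnames(x)
  list(expr = expr_matrix(y, platform,
                          sprintf("synthetic %s validation view (seed %d)",
                                  platform, config$seed)),
       latent = expr_matrix(x, "microarray_log2", "latent (undistorted) view"),
       pheno = pheno)
}

#' Simulate the full multi-cohort study
#' @param config a [simulation_config()].
#' @return list with `reference1`, `reference2`, `training`,
#'   `validation_rnaseq`, `validation_qpcr`, and a `manifest` recording the
#'   configuration (including the seed).
#' @export
simulate_study <- function(config = simulation_config()) {
  list(reference1 = simulate_reference_cohort(config, 1L),
       reference2 = simulate_reference_cohort(config, 2L),
       training = simulate_training_cohort(config),
       validation_rnaseq = simulate_validation_cohort(config, "rnaseq_log2fpkm"),
       validation_qpcr = simulate_validation_cohort(config, "qpcr_deltact"),
       manifest = unclass(config))
}
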