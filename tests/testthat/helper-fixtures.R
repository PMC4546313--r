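# Shared fixture builders. Everything is generated in code; the package-wide
# default test seed is 1.

make_expr <- function(values, platform = "microarray_log2") {
  expr_matrix(values, platform)
}

# tiny labelled two-group matrix: n1 high + n2 low samples
toy_cohort <- function(n_genes = 50, n1 = 10, n2 = 10, shift_genes = NULL,
                       shift = 0, seed = 1) {
  set.seed(seed)
  n <- n1 + n2
  x <- matrix(rnorm(n_genes * n), n_genes, n,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n))))
  if (length(shift_genes)) x[shift_genes, seq_len(n1)] <-
      x[shift_genes, seq_len(n1)] + shift
  pheno <- phenotype_table(data.frame(
    sample_id = colnames(x),
    risk_label = rep(c("high", "low"), c(n1, n2)),
    stringsAsFactors = FALSE))
  list(expr = make_expr(x), pheno = pheno)
}

# small full-study config used by pipeline-level tests
small_config <- function(seed = 1, ...) {
  simulation_config(n_genes = 600,
                    module_specs = list(
                      module_spec("up_module_1", 20, "up", 0.7, 1.5),
                      module_spec("up_module_2", 20, "up", 0.7, 1.5),
                      module_spec("down_module_1", 20, "down", 0.7, -1.5),
                      module_spec("down_module_2", 20, "down", 0.7, -1.5)),
                    n_reference_1 = 150, n_reference_2 = 150,
                    seed = seed, ...)
}

# gene-set collections aligned with a config's planted blocks
planted_collections <- function(config) {
  blocks <- planted_modules(config)
  ids <- sprintf("G%05d", seq_len(config$n_genes))
  list(pathways = gene_set_collection(list(
         cell_cycle = blocks[[1]], calcium_response = blocks[[2]],
         bcr_signaling = blocks[[3]], tcr_signaling = blocks[[4]])),
       celltypes = gene_set_collection(list(
         erythroid = blocks[[1]], megakaryocyte = blocks[[2]],
         b_cell = blocks[[3]], t_cell = blocks[[4]],
         unrelated = utils::tail(ids, 30))))
}

# independent hypergeometric upper-tail oracle via binomial coefficients
hyper_tail_oracle <- function(k, a, b, N) {
  lo <- max(k, a + b - N)
  hi <- min(a, b)
  if (lo > hi) return(0)
  sum(vapply(lo:hi, function(i)
    choose(a, i) * choose(N - a, b - i), numeric(1))) / choose(N, b)
}

# brute-force Gaussian naive-Bayes posterior
nb_oracle <- function(model, x) {
  dens <- function(mu, v) prod(stats::dnorm(x[model$genes], mu, sqrt(v)))
  ph <- model$prior_high * dens(model$mean_high, model$var_high)
  pl <- model$prior_low * dens(model$mean_low, model$var_low)
  ph / (ph + pl)
}

# exhaustive pairwise concordance oracle (ties in score = 0.5)
cindex_oracle <- function(times, events, scores) {
  num <- den <- 0
  n <- length(times)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    # comparable if the earlier time is an event (and times differ)
    ti <- times[i]; tj <- times[j]
    if (ti == tj) {
      if (events[i] == 1 && events[j] == 1) next  # tied event times unusable
      next
    }
    first <- if (ti < tj) i else j
    if (events[first] != 1) next
    den <- den + 1
    si <- scores[first]; sj <- scores[c(i, j)[c(i, j) != first]]
    if (si > sj) num <- num + 1 else if (si == sj) num <- num + 0.5
  }
  num / den
}
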