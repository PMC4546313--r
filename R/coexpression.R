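# Weighted co-expression network construction and module detection:
# Pearson correlation -> soft-threshold adjacency -> topological overlap ->
# average-linkage clustering of 1 - TOM -> fixed-height tree cut with a
# minimum module size; unassigned genes are labelled "grey".

#' Network construction parameters
#'
#' @param power soft-threshold exponent (>= 1).
#' @param signed if `TRUE` use the signed adjacency `((1 + cor)/2)^power`;
#'   default is the unsigned `|cor|^power`.
#' @param min_module_size smallest gene count of a non-grey module (>= 5).
#' @param cut_height tree-cut height on the 1 - TOM dendrogram, in (0, 1].
#' @return a `network_params` list.
#' @export
network_params <- function(power = 6, signed = FALSE,
                           min_module_size = 10, cut_height = 0.99) {
  if (power < 1) stopf("power must be >= 1")
  if (min_module_size < 5) stopf("min_module_size must be >= 5")
  if (cut_height <= 0 || cut_height > 1) stopf("cut_height must be in (0, 1]")
  structure(list(power = power, signed = isTRUE(signed),
                 min_module_size = as.integer(min_module_size),
                 cut_height = cut_height),
            class = "network_params")
}

#' Pearson correlation matrix over a gene list
#'
#' @param expr an [expr_matrix()] with >= 3 samples.
#' @param genes gene ids to use (default: all).
#' @return symmetric correlation matrix with unit diagonal.  Zero-variance
#'   genes get correlation 0 to every other gene, with a warning.
#' @export
correlation_matrix <- function(expr, genes = NULL) {
  x <- as.matrix(expr)
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(x))
    if (length(miss)) stopf("genes absent from matrix: %s",
                            paste(utils::head(miss, 5L), collapse = ", "))
    x <- x[genes, , drop = FALSE]
  }
  if (ncol(x) < 3L) stopf("need >= 3 samples")
  sds <- apply(x, 1L, stats::sd)
  cc <- suppressWarnings(stats::cor(t(x)))
  if (any(sds == 0)) {
    warnf("%d zero-variance gene(s): correlations set to 0", sum(sds == 0))
    cc[sds == 0, ] <- 0
    cc[, sds == 0] <- 0
  }
  diag(cc) <- 1
  cc
}

#' Pick the soft-threshold power by scale-free topology fit
#'
#' For each candidate power the weighted connectivities `k_i` are binned and
#' log10 frequency is regressed on log10 mean connectivity; the smallest
#' power whose fit R^2 reaches `rsq_cut` is returned.  If none qualifies the
#' conventional fallback power 6 is returned with a warning.
#'
#' @param corr correlation matrix.
#' @param powers candidate powers (>= 1), ascending.
#' @param rsq_cut scale-free fit threshold.
#' @param signed use the signed adjacency.
#' @param n_bins connectivity histogram bins.
#' @return selected power, with attributes `rsq` (per candidate) and
#'   `fallback` flag.
#' @export
pick_soft_threshold <- function(corr, powers = c(1:10, 12, 14, 16, 18, 20),
                                rsq_cut = 0.8, signed = FALSE, n_bins = 10) {
  if (any(powers < 1)) stopf("candidate powers must be >= 1")
  powers <- sort(powers)
  if (all(abs(corr[upper.tri(corr)]) < 1e-12))
    stopf("degenerate network: all off-diagonal correlations are 0")
  rsq <- vapply(powers, function(p) {
    a <- adjacency(corr, network_params(power = p, signed = signed))
    k <- colSums(a) - 1
    scale_free_rsq(k, n_bins)
  }, numeric(1))
  names(rsq) <- powers
  ok <- which(!is.na(rsq) & rsq >= rsq_cut)
  if (length(ok)) {
    out <- powers[ok[1L]]
    fallback <- FALSE
  } else {
    warnf("no candidate power reaches scale-free fit R^2 >= %.2f; falling back to power 6",
          rsq_cut)
    out <- 6
    fallback <- TRUE
  }
  structure(out, rsq = rsq, fallback = fallback)
}

# R^2 of log10(frequency) ~ log10(mean connectivity) over connectivity bins
scale_free_rsq <- function(k, n_bins = 10) {
  if (stats::sd(k) == 0) return(NA_real_)
  bins <- cut(k, breaks = n_bins)
  freq <- tapply(k, bins, length)
  meank <- tapply(k, bins, mean)
  keep <- !is.na(freq) & freq > 0 & meank > 0
  if (sum(keep) < 3L) return(NA_real_)
  stats::cor(log10(freq[keep]), log10(meank[keep]))^2
}

#' Soft-threshold adjacency
#'
#' Unsigned: `|cor|^power`; signed: `((1 + cor)/2)^power`.  Diagonal forced
#' to 1.
#'
#' @param corr correlation matrix.
#' @param params a [network_params()].
#' @return adjacency matrix in `[0, 1]`.
#' @export
adjacency <- function(corr, params = network_params()) {
  a <- if (params$signed) ((1 + corr) / 2)^params$power else abs(corr)^params$power
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with the
#' sum over `u != i, j` and `k_i` the connectivity `sum_{u != i} a_iu`;
#' `TOM_ii = 1`.
#'
#' @param adj symmetric adjacency with entries in `[0, 1]`, unit diagonal.
#' @return the TOM matrix (symmetric, entries in `[0, 1]`).
#' @export
topological_overlap <- function(adj) {
  if (any(adj < -1e-12 | adj > 1 + 1e-12)) stopf("adjacency entries must be in [0, 1]")
  a0 <- adj; diag(a0) <- 0
  # a0 has zero diagonal, so (a0 %*% a0)_ij already sums over u != i, j
  shared <- a0 %*% a0
  k <- colSums(a0)
  kmin <- outer(k, k, pmin)
  tom <- (shared + a0) / (kmin + 1 - a0)
  diag(tom) <- 1
  tom
}

#' TOM dissimilarity
#' @param adj adjacency matrix.
#' @return `1 - topological_overlap(adj)`.
#' @export
tom_dissimilarity <- function(adj) 1 - topological_overlap(adj)

#' Detect co-expression modules
#'
#' Builds the TOM dissimilarity over `genes` in `expr`, clusters it by
#' average linkage, cuts the tree at `params$cut_height`, and labels the
#' resulting branches of at least `params$min_module_size` genes `"M1"`,
#' `"M2"`, ... in decreasing size order; all other genes are `"grey"`.
#'
#' @param expr an [expr_matrix()].
#' @param genes gene ids to network (must be present in `expr`).
#' @param params a [network_params()].
#' @param dataset_tag,direction_tag free-text tags recorded on the result
#'   (module detection is run separately per direction, and the namespaces
#'   are never mixed).
#' @return a `module_assignment` data.frame (`gene`, `module`) with attributes
#'   `dataset_tag`, `direction_tag`, `params` and dendrogram `order`.
#' @export
detect_modules <- function(expr, genes, params = network_params(),
                           dataset_tag = "", direction_tag = "") {
  genes <- as.character(genes)
  if (length(genes) < params$min_module_size) {
    warnf("fewer genes (%d) than min_module_size (%d): all grey",
          length(genes), params$min_module_size)
    out <- data.frame(gene = genes, module = rep("grey", length(genes)),
                      stringsAsFactors = FALSE)
    return(structure(out, dataset_tag = dataset_tag,
                     direction_tag = direction_tag, params = params,
                     order = seq_along(genes),
                     class = c("module_assignment", "data.frame")))
  }
  cc <- correlation_matrix(expr, genes)
  adj <- adjacency(cc, params)
  diss <- 1 - topological_overlap(adj)
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  cl <- stats::cutree(hc, h = params$cut_height)
  sizes <- table(cl)
  big <- names(sizes)[sizes >= params$min_module_size]
  # label in decreasing size order; ties broken by first-gene position for
  # determinism
  if (length(big)) {
    first_pos <- vapply(big, function(b) min(which(cl == b)), 1L)
    big <- big[order(-sizes[big], first_pos)]
    lab <- rep("grey", length(genes))
    for (i in seq_along(big)) lab[cl == big[i]] <- paste0("M", i)
  } else {
    lab <- rep("grey", length(genes))
  }
  out <- data.frame(gene = genes, module = lab, stringsAsFactors = FALSE)
  structure(out, dataset_tag = dataset_tag, direction_tag = direction_tag,
            params = params, order = hc$order,
            class = c("module_assignment", "data.frame"))
}

#' Gene membership of one module
#' @param assign a `module_assignment`.
#' @param label module label (e.g. `"M1"`).
#' @return character vector of gene ids.
#' @export
module_genes <- function(assign, label) assign$gene[assign$module == label]
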