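# Functional annotation of stable modules: one-sided Fisher enrichment
# against canonical pathways with a fallback to hematopoietic cell-type
# overexpression signatures.  The enrichment universe is the full set of
# genes measured in the training cohort; no multiple-testing adjustment is
# applied inside enrich() -- the 1e-4 core threshold already encodes
# family-wise control.

#' Fisher enrichment of a gene set collection against a module
#'
#' Each collection set is intersected with the universe before testing; the
#' module must be a subset of the universe.
#'
#' @param module_genes character vector of module gene ids.
#' @param collection a [gene_set_collection()].
#' @param universe background gene ids (e.g. all genes measured).
#' @return an `enrichment_result` data.frame ranked by ascending p (ties by
#'   smaller set, then name): `set`, `overlap_count`, `set_size`,
#'   `module_size`, `universe_size`, `fisher_p`, `rank`.
#' @export
enrich <- function(module_genes, collection, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stopf("empty universe")
  module_genes <- unique(as.character(module_genes))
  out_of <- setdiff(module_genes, universe)
  if (length(out_of)) stopf("module genes outside the universe: %s",
                            paste(utils::head(out_of, 5L), collapse = ", "))
  m <- length(module_genes); N <- length(universe)
  rows <- lapply(names(collection$sets), function(nm) {
    s <- intersect(collection$sets[[nm]], universe)
    k <- length(intersect(module_genes, s))
    data.frame(set = nm, overlap_count = k, set_size = length(s),
               module_size = m, universe_size = N,
               fisher_p = if (length(s)) fisher_overlap(k, m, length(s), N) else 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(out$fisher_p, out$set_size, out$set)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Extract the functional core of a stable module
#'
#' The core is the intersection of the module with its most significantly
#' enriched canonical pathway, provided that pathway's enrichment p is below
#' `p_threshold`; otherwise the fallback is the intersection with the most
#' significantly enriched cell-type overexpression set, accepted without a
#' second threshold.
#'
#' @param module a `stable_module` (from [call_stable_modules()]).
#' @param pathways canonical-pathway [gene_set_collection()].
#' @param celltypes cell-type-signature [gene_set_collection()].
#' @param universe background gene ids.
#' @param p_threshold pathway significance threshold (default `1e-4`).
#' @return a `functional_core`: list with `parent`, `core_genes`,
#'   `source_set_name`, `source_collection`, `p`.
#' @export
functional_core <- function(module, pathways, celltypes, universe,
                            p_threshold = 1e-4) {
  if (!length(pathways$sets) && !length(celltypes$sets))
    stopf("both gene-set collections are empty")
  pick <- function(coll, source) {
    er <- enrich(module$gene_set, coll, universe)
    top <- er[1L, ]
    list(core = intersect(module$gene_set,
                          intersect(coll$sets[[top$set]], universe)),
         name = top$set, p = top$fisher_p, source = source)
  }
  best <- if (length(pathways$sets)) pick(pathways, "canonical_pathway") else NULL
  if (is.null(best) || best$p >= p_threshold) {
    if (length(celltypes$sets)) best <- pick(celltypes, "celltype_overexpression")
    else if (is.null(best)) stopf("both gene-set collections are empty")
  }
  structure(list(parent = module, core_genes = best$core,
                 source_set_name = best$name, source_collection = best$source,
                 p = best$p),
            class = "functional_core")
}

#' Cell-type enrichment profile of stable modules
#'
#' @param modules a `stable_modules` list (or list of `stable_module`s).
#' @param celltypes cell-type [gene_set_collection()].
#' @param universe background gene ids.
#' @return matrix of `-log10` enrichment p, modules in rows, cell-type sets
#'   in columns (heatmap-ready).
#' @export
celltype_profile <- function(modules, celltypes, universe) {
  labels <- vapply(modules, function(m)
    sprintf("%s:%s~%s", m$direction %||% "?", m$module_a, m$module_b), "")
  out <- t(vapply(modules, function(m) {
    er <- enrich(m$gene_set, celltypes, universe)
    -log10(er$fisher_p[match(names(celltypes$sets), er$set)])
  }, numeric(length(celltypes$sets))))
  dimnames(out) <- list(labels, names(celltypes$sets))
  out
}
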