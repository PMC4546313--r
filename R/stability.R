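# Cross-cohort module stability: every non-grey module pair between two
# independent module assignments is scored by the one-sided Fisher exact
# (hypergeometric) overlap test; each dataset-1 module keeps its best
# dataset-2 partner, and pairs below alpha become stable modules ranked by
# -log(p).  Up- and down-regulated lists are then truncated to equal length.

#' One-sided Fisher exact overlap p-value
#'
#' Hypergeometric upper tail `P(X >= k)` for the overlap of two gene sets of
#' sizes `size_a` and `size_b` drawn from a universe of `universe` genes.
#'
#' @param k observed overlap.
#' @param size_a,size_b set sizes.
#' @param universe universe size.
#' @return p-value in (0, 1].
#' @export
fisher_overlap <- function(k, size_a, size_b, universe) {
  if (any(c(k, size_a, size_b, universe) < 0)) stopf("counts must be nonnegative")
  if (size_a > universe || size_b > universe)
    stopf("set sizes cannot exceed the universe")
  if (k > min(size_a, size_b)) stopf("overlap exceeds the smaller set")
  if (k < size_a + size_b - universe)
    stopf("overlap below the minimum forced by the universe")
  stats::phyper(k - 1, size_a, universe - size_a, size_b, lower.tail = FALSE)
}

#' Overlap table between two module assignments
#'
#' The universe is the set of genes present in both assignments; grey genes
#' count in the universe but grey modules are excluded from pairing.
#'
#' @param assign_1,assign_2 `module_assignment`s over the same direction's
#'   candidate list (from the two reference cohorts).
#' @return a `module_overlap` data.frame: one row per non-grey module pair
#'   with `module_a`, `module_b`, `overlap_count`, `size_a`, `size_b`,
#'   `universe_size`, `fisher_p`.
#' @export
overlap_table <- function(assign_1, assign_2) {
  universe <- intersect(assign_1$gene, assign_2$gene)
  if (!length(universe)) stopf("assignments have disjoint gene universes")
  a1 <- assign_1[assign_1$gene %in% universe & assign_1$module != "grey", ]
  a2 <- assign_2[assign_2$gene %in% universe & assign_2$module != "grey", ]
  mods1 <- unique(a1$module); mods2 <- unique(a2$module)
  if (!length(mods1) || !length(mods2)) {
    out <- data.frame(module_a = character(), module_b = character(),
                      overlap_count = integer(), size_a = integer(),
                      size_b = integer(), universe_size = integer(),
                      fisher_p = numeric(), stringsAsFactors = FALSE)
  } else {
    grid <- expand.grid(module_a = mods1, module_b = mods2,
                        stringsAsFactors = FALSE)
    out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
      ga <- a1$gene[a1$module == grid$module_a[i]]
      gb <- a2$gene[a2$module == grid$module_b[i]]
      k <- length(intersect(ga, gb))
      data.frame(module_a = grid$module_a[i], module_b = grid$module_b[i],
                 overlap_count = k, size_a = length(ga), size_b = length(gb),
                 universe_size = length(universe),
                 fisher_p = fisher_overlap(k, length(ga), length(gb),
                                           length(universe)),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(out,
            assign_1 = assign_1, assign_2 = assign_2,
            universe = universe,
            direction_tag = attr(assign_1, "direction_tag"),
            class = c("module_overlap", "data.frame"))
}

#' Call stable modules from an overlap table
#'
#' Each dataset-1 module is matched to its best dataset-2 partner (smallest
#' overlap p; ties broken by larger overlap, then label order).  Matches with
#' `fisher_p < alpha` become stable modules, ranked by descending `-log(p)`.
#' The stable gene set is the intersection of the matched pair (restricted to
#' the shared universe).
#'
#' @param overlaps a `module_overlap` from [overlap_table()].
#' @param alpha stability significance threshold (default 0.01).
#' @param core_rule gene-set rule; only `"intersection"` is defined.
#' @return a `stable_modules` list; each element has `direction`, `gene_set`,
#'   `module_a`, `module_b`, `best_p`, `rank`.
#' @export
call_stable_modules <- function(overlaps, alpha = 0.01,
                                core_rule = c("intersection")) {
  core_rule <- match.arg(core_rule)
  if (!inherits(overlaps, "module_overlap")) stopf("`overlaps` must come from overlap_table()")
  if (!nrow(overlaps)) {
    if (is.null(attr(overlaps, "assign_1"))) stopf("no overlaps supplied")
    return(structure(list(), direction = attr(overlaps, "direction_tag"),
                     class = "stable_modules"))
  }
  a1 <- attr(overlaps, "assign_1"); a2 <- attr(overlaps, "assign_2")
  universe <- attr(overlaps, "universe")
  best <- do.call(rbind, lapply(split(overlaps, overlaps$module_a), function(d) {
    d <- d[order(d$fisher_p, -d$overlap_count, d$module_b), , drop = FALSE]
    d[1L, , drop = FALSE]
  }))
  best <- best[best$fisher_p < alpha, , drop = FALSE]
  if (!nrow(best))
    return(structure(list(), direction = attr(overlaps, "direction_tag"),
                     class = "stable_modules"))
  best <- best[order(best$fisher_p, -best$overlap_count, best$module_a), ,
               drop = FALSE]
  out <- lapply(seq_len(nrow(best)), function(i) {
    ga <- intersect(module_genes(a1, best$module_a[i]), universe)
    gb <- intersect(module_genes(a2, best$module_b[i]), universe)
    structure(list(direction = attr(overlaps, "direction_tag"),
                   gene_set = intersect(ga, gb),
                   module_a = best$module_a[i], module_b = best$module_b[i],
                   best_p = best$fisher_p[i], rank = i),
              class = "stable_module")
  })
  structure(out, direction = attr(overlaps, "direction_tag"),
            class = "stable_modules")
}

#' Balance the up- and down-regulated stable-module lists
#'
#' Truncates both ranked lists to the shorter length, discarding the
#' worst-ranked modules from the longer list, so models can pair one up- with
#' one down-regulated representative.
#'
#' @param up,down `stable_modules` lists ranked by stability.
#' @return list with truncated `up` and `down`.
#' @export
balance_directions <- function(up, down) {
  if (!length(up) || !length(down)) {
    warnf("one direction has no stable modules: both lists emptied")
    return(list(up = structure(list(), class = "stable_modules"),
                down = structure(list(), class = "stable_modules")))
  }
  k <- min(length(up), length(down))
  trim <- function(x) structure(x[seq_len(k)], direction = attr(x, "direction"),
                                class = "stable_modules")
  list(up = trim(up), down = trim(down))
}

#' @export
print.stable_modules <- function(x, ...) {
  cat(sprintf("stable_modules (%s): %d module(s)\n",
              attr(x, "direction") %||% "?", length(x)))
  for (m in x)
    cat(sprintf("  #%d %s~%s: %d genes, p = %.3g\n",
                m$rank, m$module_a, m$module_b, length(m$gene_set), m$best_p))
  invisible(x)
}
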