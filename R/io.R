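# Tab-delimited UTF-8 interchange, "NA" = missing, throughout.

#' Read a tab-delimited expression matrix
#'
#' Expects a header row of sample ids and a first column of gene ids.
#' Duplicate gene rows are collapsed by keeping the row with the highest mean
#' value (the standard probe-collapse heuristic), with a warning.
#'
#' @param path file path.
#' @param platform platform tag, see [expr_matrix()].
#' @param missing `"error"` to reject `NA` cells, `"na"` to keep them as
#'   flagged-missing entries.
#' @return an [expr_matrix()].
#' @export
read_expression_matrix <- function(path,
                                   platform = c("microarray_log2",
                                                "rnaseq_log2fpkm",
                                                "qpcr_deltact"),
                                   missing = c("error", "na")) {
  platform <- match.arg(platform)
  missing <- match.arg(missing)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!(seq_along(lines) == length(lines) & !nzchar(lines))]
  if (length(lines) < 2L) stopf("%s: empty or header-only file (line 1)", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) < 2L) stopf("%s: malformed header (line 1): need >=1 sample column", path)
  sample_ids <- header[-1L]
  n_col <- length(header)
  gene_ids <- character(length(fields) - 1L)
  vals <- matrix(NA_real_, length(fields) - 1L, n_col - 1L)
  for (i in seq_along(fields)[-1L]) {
    f <- fields[[i]]
    if (length(f) != n_col)
      stopf("%s: line %d has %d fields, expected %d", path, i, length(f), n_col)
    gene_ids[i - 1L] <- f[1L]
    cells <- f[-1L]
    num <- suppressWarnings(as.numeric(cells))
    bad <- is.na(num) & cells != "NA"
    if (any(bad))
      stopf("%s: non-numeric cell \"%s\" at line %d", path, cells[which(bad)[1L]], i)
    if (missing == "error" && any(cells == "NA"))
      stopf("%s: missing value (NA) at line %d", path, i)
    vals[i - 1L, ] <- num
  }
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    warnf("collapsing %d duplicated gene id(s) by highest mean value: %s",
          length(dup), paste(utils::head(dup, 5L), collapse = ", "))
    means <- rowMeans(vals, na.rm = TRUE)
    keep <- unlist(lapply(split(seq_along(gene_ids), gene_ids)[unique(gene_ids)],
                          function(ix) ix[which.max(means[ix])]))
    keep <- sort(unname(keep))
    vals <- vals[keep, , drop = FALSE]
    gene_ids <- gene_ids[keep]
  }
  dimnames(vals) <- list(gene_ids, sample_ids)
  expr_matrix(vals, platform)
}

#' Write an expression matrix as tab-delimited text
#' @param x an [expr_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("gene_id", samples(x)), collapse = "\t"), con)
  body <- apply(x$values, 1L, function(v)
    paste(formatC(v, digits = 15, format = "g"), collapse = "\t"))
  writeLines(paste(genes(x), body, sep = "\t"), con)
  invisible(path)
}

#' Read a GMT gene-set file (Broad dialect)
#'
#' One set per line: name, description, then one or more gene ids, all
#' tab-separated.  Duplicate genes within a set are collapsed.
#'
#' @param path file path.
#' @return a `gene_set_collection`: list with `sets` (named list of character
#'   vectors) and `source_note` (named character of per-set descriptions).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- nzchar(lines)
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  sets <- list(); notes <- character()
  for (j in seq_along(fields)) {
    f <- fields[[j]]
    if (length(f) < 3L)
      stopf("%s: line %d has %d fields, expected >=3 (name, description, genes)",
            path, idx[j], length(f))
    nm <- f[1L]
    if (nm %in% names(sets)) stopf("%s: duplicate set name \"%s\" at line %d",
                                   path, nm, idx[j])
    sets[[nm]] <- unique(f[-(1:2)])
    notes[nm] <- f[2L]
  }
  gene_set_collection(sets, notes)
}

#' Construct a gene-set collection
#' @param sets named list of character gene-id vectors; names unique, sets
#'   non-empty; duplicates within a set are collapsed.
#' @param source_note character (scalar or per-set) description.
#' @return a `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, source_note = "") {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stopf("all gene sets must be named")
  if (anyDuplicated(names(sets))) stopf("duplicate gene-set names")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0L)) stopf("empty gene set")
  structure(list(sets = sets, source_note = source_note),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, %d-%d genes each\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Write a gene-set collection as GMT
#' @param x a `gene_set_collection`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  notes <- x$source_note
  if (length(notes) == 1L) notes <- rep(notes, length(x$sets))
  if (is.null(names(notes))) names(notes) <- names(x$sets)
  out <- vapply(names(x$sets), function(nm) {
    note <- if (nm %in% names(notes) && nzchar(notes[[nm]])) notes[[nm]] else "na"
    paste(c(nm, note, x$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(out, file(path, encoding = "UTF-8"))
  invisible(path)
}

#' Read a tab-delimited phenotype table
#' @param path file path; header row required, `sample_id` column required.
#' @return a validated [phenotype_table()].
#' @export
read_phenotype <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = "NA", fileEncoding = "UTF-8")
  phenotype_table(df)
}

#' Write a phenotype table as tab-delimited text
#' @param pheno a [phenotype_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phenotype <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records the simulation/pipeline configuration (including the seed) next to
#' serialized results so a run can be reproduced.
#'
#' @param config a list (e.g. a [simulation_config()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
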