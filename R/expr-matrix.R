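#' Expression matrix container
#'
#' A light container for a log-scale gene-by-sample expression matrix with a
#' platform tag.  Values are expected on a log-like scale: log2 microarray
#' intensity, log2 FPKM for RNA-seq, or delta-Ct for qPCR (where *lower*
#' values mean more transcript).  Missing entries are explicit `NA`s, never
#' silent zeros.
#'
#' @param values numeric matrix, genes in rows and samples in columns, with
#'   unique non-empty rownames (gene ids) and colnames (sample ids).  Gene
#'   identifiers are opaque strings matched case-sensitively.
#' @param platform one of `"microarray_log2"`, `"rnaseq_log2fpkm"`,
#'   `"qpcr_deltact"`.
#' @param scale_note free-text note on the scale/normalisation of the values.
#' @return an object of class `expr_matrix`.
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' em <- expr_matrix(m, "microarray_log2")
#' dim(em)
#' @export
expr_matrix <- function(values,
                        platform = c("microarray_log2", "rnaseq_log2fpkm",
                                     "qpcr_deltact"),
                        scale_note = "") {
  platform <- match.arg(platform)
  if (!is.matrix(values) || !is.numeric(values))
    stopf("`values` must be a numeric matrix")
  gid <- rownames(values); sid <- colnames(values)
  if (is.null(gid) || is.null(sid) || any(!nzchar(gid)) || any(!nzchar(sid)))
    stopf("`values` needs non-empty gene rownames and sample colnames")
  if (anyDuplicated(gid)) stopf("duplicate gene ids: %s",
                                paste(unique(gid[duplicated(gid)]), collapse = ", "))
  if (anyDuplicated(sid)) stopf("duplicate sample ids: %s",
                                paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (any(is.infinite(values))) stopf("expression values must be finite (NA marks missing)")
  structure(list(values = values, platform = platform,
                 scale_note = as.character(scale_note)),
            class = "expr_matrix")
}

#' @export
as.matrix.expr_matrix <- function(x, ...) x$values

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Gene and sample identifiers of an expression matrix
#' @param x an `expr_matrix`.
#' @return character vector of ids, in storage order.
#' @export
genes <- function(x) UseMethod("genes")

#' @export
genes.expr_matrix <- function(x) rownames(x$values)

#' @rdname genes
#' @export
samples <- function(x) UseMethod("samples")

#' @export
samples.expr_matrix <- function(x) colnames(x$values)

#' @export
`[.expr_matrix` <- function(x, i, j, ...) {
  v <- x$values[i, j, drop = FALSE]
  expr_matrix(v, x$platform, x$scale_note)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$platform))
  if (nzchar(x$scale_note)) cat("  note:", x$scale_note, "\n")
  invisible(x)
}

#' Phenotype / survival table
#'
#' Validates and types a per-sample phenotype table.  Required column:
#' `sample_id`.  Recognised columns: `risk_label` (`"high"`/`"low"`),
#' `survival_time` (months, nonnegative; the column name `time` is accepted
#' and renamed), `event` (0/1, 1 = death observed).  All other columns are
#' kept as clinical covariates.
#'
#' @param df a data.frame.
#' @return the validated data.frame with class `phenotype_table`.
#' @export
phenotype_table <- function(df) {
  if (!is.data.frame(df)) stopf("`df` must be a data.frame")
  if (!"sample_id" %in% names(df)) stopf("missing required column `sample_id`")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stopf("duplicate sample_id values")
  if ("time" %in% names(df) && !"survival_time" %in% names(df))
    names(df)[names(df) == "time"] <- "survival_time"
  if ("survival_time" %in% names(df)) {
    st <- df$survival_time
    if (!is.numeric(st)) stopf("`survival_time` must be numeric")
    if (any(st < 0, na.rm = TRUE)) stopf("negative survival_time")
  }
  if ("event" %in% names(df)) {
    ev <- df$event
    if (!all(ev %in% c(0, 1) | is.na(ev)))
      stopf("`event` must be 0/1 (1 = death observed)")
    if (!"survival_time" %in% names(df) ||
        any(!is.na(ev) & is.na(df$survival_time)))
      stopf("`survival_time` must be present wherever `event` is present")
  }
  if ("risk_label" %in% names(df)) {
    rl <- as.character(df$risk_label)
    if (!all(rl %in% c("high", "low") | is.na(rl)))
      stopf("`risk_label` must be \"high\" or \"low\"")
    df$risk_label <- rl
  }
  class(df) <- unique(c("phenotype_table", class(df)))
  df
}

#' Clinical covariate columns of a phenotype table
#' @param pheno a `phenotype_table`.
#' @return data.frame of covariate columns (everything except the reserved
#'   columns), rownames = sample ids.
#' @export
covariates <- function(pheno) {
  reserved <- c("sample_id", "risk_label", "survival_time", "event")
  out <- pheno[, setdiff(names(pheno), reserved), drop = FALSE]
  rownames(out) <- pheno$sample_id
  out
}
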