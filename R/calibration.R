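# Cross-platform calibration: per gene, an affine transform maps a
# validation cohort's values so their median and median absolute deviation
# (raw MAD, no normal-consistency constant -- it would cancel anyway when
# used on both sides) equal those of the training cohort.  The same code
# path serves RNA-seq log2 FPKM and qPCR delta-Ct views.

#' Fit a per-gene median/MAD calibration map
#'
#' For each gene: `gain = target_mad / source_mad`,
#' `offset = target_median - gain * source_median`.  Genes with zero source
#' MAD get a shift-only transform (`gain = 1`) with a warning.
#'
#' @param training reference [expr_matrix()] (defines the target
#'   distribution; all training samples are used).
#' @param validation [expr_matrix()] to be calibrated (>= 3 samples).
#' @param genes genes to map (must be present in both); default: all genes
#'   shared by the two matrices.
#' @return a `calibration_map` data.frame: `gene`, `target_median`,
#'   `target_mad`, `source_median`, `source_mad`, `gain`, `offset`,
#'   `shift_only`, with the training platform tag as attribute.
#' @export
fit_calibration <- function(training, validation, genes = NULL) {
  tx <- as.matrix(training); vx <- as.matrix(validation)
  if (is.null(genes)) genes <- intersect(rownames(tx), rownames(vx))
  miss <- c(setdiff(genes, rownames(tx)), setdiff(genes, rownames(vx)))
  if (length(miss)) stopf("gene(s) absent from a matrix: %s",
                          paste(unique(utils::head(miss, 5L)), collapse = ", "))
  if (ncol(vx) < 3L) stopf("need >= 3 validation samples")
  raw_mad <- function(v) stats::mad(v, constant = 1)
  tm <- apply(tx[genes, , drop = FALSE], 1L, stats::median)
  tmad <- apply(tx[genes, , drop = FALSE], 1L, raw_mad)
  sm <- apply(vx[genes, , drop = FALSE], 1L, stats::median)
  smad <- apply(vx[genes, , drop = FALSE], 1L, raw_mad)
  shift_only <- smad == 0
  if (any(shift_only))
    warnf("%d gene(s) with zero MAD in the validation cohort: shift-only transform",
          sum(shift_only))
  gain <- ifelse(shift_only, 1, tmad / smad)
  offset <- tm - gain * sm
  out <- data.frame(gene = genes, target_median = tm, target_mad = tmad,
                    source_median = sm, source_mad = smad,
                    gain = gain, offset = offset, shift_only = shift_only,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, target_platform = training$platform,
            class = c("calibration_map", "data.frame"))
}

#' Apply a calibration map to a validation cohort
#'
#' Mapped genes are transformed `gain * x + offset`; genes not in the map
#' pass through untouched.  The platform tag of the result is the training
#' (target) platform.
#'
#' @param map a [fit_calibration()] result.
#' @param validation [expr_matrix()] containing the mapped genes.
#' @return calibrated [expr_matrix()]; per-gene median and MAD of mapped
#'   genes equal the targets up to float tolerance.
#' @export
apply_calibration <- function(map, validation) {
  x <- as.matrix(validation)
  miss <- setdiff(map$gene, rownames(x))
  if (length(miss)) stopf("mapped gene(s) absent: %s", paste(miss, collapse = ", "))
  rows <- match(map$gene, rownames(x))
  x[rows, ] <- map$gain * x[rows, ] + map$offset
  expr_matrix(x, attr(map, "target_platform"),
              paste("median/MAD calibrated;", validation$scale_note))
}
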