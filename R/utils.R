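stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Numerically safe logistic function
#'
#' @param s numeric vector of linear predictors.
#' @return `exp(s) / (1 + exp(s))`, computed without overflow.
#' @keywords internal
logistic <- function(s) stats::plogis(s)
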