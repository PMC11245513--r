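#' Numerically stable log-sum-exp
#'
#' @param x numeric vector of log-scale values.
#' @return `log(sum(exp(x)))` computed without overflow.
#' @keywords internal
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Row-wise log-sum-exp of a matrix
#' @param x numeric matrix.
#' @keywords internal
row_logsumexp <- function(x) {
  m <- apply(x, 1L, max)
  m + log(rowSums(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(...) {
  stop(structure(class = c("phescan_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_format <- function(...) {
  stop(structure(class = c("phescan_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
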