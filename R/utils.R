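# Internal helpers shared across modules.

#' @importFrom graphics abline legend
#' @importFrom stats predict
NULL

# Geometric mean; all values must be strictly positive.
geo_mean <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("geometric mean requires strictly positive finite values")
  }
  exp(mean(log(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ctx <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Validate a two-level grouping vector against a value matrix's columns.
check_labels <- function(labels, n) {
  labels <- as.character(labels)
  if (length(labels) != n) {
    stop_ctx("expected %d group labels, got %d", n, length(labels))
  }
  if (anyNA(labels)) stop_ctx("group labels must not be NA")
  lv <- unique(labels)
  if (length(lv) != 2L) {
    stop_ctx("exactly two groups required, found: %s",
             paste(lv, collapse = ", "))
  }
  labels
}
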