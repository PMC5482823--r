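#' @keywords internal
"_PACKAGE"

#' @importFrom stats pt sd cor prcomp hclust as.dist setNames rnorm runif
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Truncate long id vectors in error messages.
fmt_ids <- function(x, max = 10L) {
  if (length(x) > max) {
    paste0(paste(head(x, max), collapse = ", "), ", ... (", length(x), " total)")
  } else {
    paste(x, collapse = ", ")
  }
}

round1 <- function(x) round(x, 1L)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}
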