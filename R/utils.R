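#' @keywords internal
"_PACKAGE"

#' @importFrom stats quantile var sd cor prcomp loess predict kmeans
#'   rnbinom rpois rlnorm runif rnorm rbinom wilcox.test median dist
#'   setNames as.dist loess.control
#' @importFrom utils head read.csv write.csv
#' @importFrom methods as
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a reproducible child seed from a master seed and a stream index,
# kept within the 32-bit integer range.
derive_seed <- function(master, stream) {
  as.integer((as.double(master) * 7919 + as.double(stream) * 104729) %% 2147483647L)
}

# Shannon entropy (natural log) of a vector of category labels.
label_entropy <- function(labels) {
  p <- tabulate(as.integer(factor(labels)))
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

as_dense <- function(x) {
  if (inherits(x, "Matrix")) as.matrix(x) else x
}
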