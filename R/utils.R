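#' @import data.table
#' @importFrom stats cor cor.test lm loess loess.control predict quantile
#'   rnorm runif rlnorm rbinom p.adjust pnorm phyper prcomp sd var complete.cases
#'   model.matrix coef residuals wilcox.test setNames dist median
#' @importFrom utils head tail
NULL

# Deterministic child seed for a pipeline stage. Keeps results of one stage
# stable when another stage's random draws change, and stays within 32-bit
# integer range.
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

msg <- function(...) message("[agewave] ", ...)
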