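#' @keywords internal
"_PACKAGE"

#' @importFrom stats pnorm pt pchisq phyper p.adjust sd mad median quantile
#'   rnorm runif rbinom rgamma cor dist hclust cutree prcomp t.test
#'   wilcox.test var setNames aggregate as.dist complete.cases
#' @importFrom utils read.delim write.table head combn
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Normalize gene symbols
#'
#' Upper-cases and strips surrounding whitespace. All symbol matching in the
#' package goes through this helper so that case and whitespace differences
#' between resources never cause silent mismatches. No alias resolution is
#' attempted.
#'
#' @param x character vector of gene symbols.
#' @return normalized character vector.
#' @export
norm_symbol <- function(x) {
  toupper(trimws(as.character(x)))
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs in the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a child seed from a base seed and a stream index, staying inside
# the 32-bit integer range R requires.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
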