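#' @keywords internal
#' @importFrom minpack.lm nls.lm nls.lm.control
#' @importFrom mclust Mclust mclustBIC
#' @importFrom stats rnorm runif rgamma rgeom rbinom median sd mad quantile
#'   approx optim optimize dbinom dnorm setNames var cov
#' @importFrom utils write.csv read.csv str capture.output packageVersion
"_PACKAGE"

#' Derive a child seed from a master seed and a stream tag
#'
#' Gives every stochastic component of a workflow its own reproducible
#' stream from one user-supplied seed. The result is a deterministic
#' function of `(seed, tag)`, kept below 2^31 - 1 (R integers are
#' 32-bit).
#'
#' @param seed Integer master seed.
#' @param tag Character stream label.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647)
}

# Run an expression under a local RNG state (restores the caller's state).
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
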