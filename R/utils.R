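#' @keywords internal
"_PACKAGE"

#' @importFrom stats anova aov coef cor cor.test integrate lm median pf pnorm
#'   pt qnorm quantile rbinom rlnorm rnorm runif sd var wilcox.test
#' @importFrom utils head read.delim write.table
NULL

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never clobbers user RNG.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream seed from a master seed; keeps results < 2^31 and gives
# well-separated streams for the pipeline stages.
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 1103L + as.integer(stream) * 12347L) %% 2147483629L
}

stop_if_not_binary <- function(x, what = "mask") {
  v <- as.vector(x)
  if (anyNA(v) || !all(v %in% c(0, 1))) {
    stop(sprintf("%s must contain only 0/1 values", what), call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
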