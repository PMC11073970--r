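# Internal helpers shared across modules.

## Run `expr` under a fixed RNG seed without disturbing the caller's RNG
## stream. seed = NULL means "use the current stream".
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## Derive a child seed deterministically; kept below 2^31 - 1.
childSeed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1103L + as.numeric(offset) * 12347) %% 2147483629)
}

#' Per-protein z-scoring
#'
#' Standardises each column (protein) of a patients x proteins matrix to mean
#' 0 and unit variance, the scaling applied before clustering so that every
#' protein contributes comparably to distances. Constant columns are centred
#' only.
#'
#' @param x numeric matrix, patients in rows.
#' @return matrix of the same shape.
#' @export
zscoreColumns <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  sweep(sweep(x, 2L, mu, "-"), 2L, sdv, "/")
}

assertProbability <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  invisible(x)
}
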