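`%||%` <- function(x, y) if (is.null(x)) y else x

#' Map a p-value to the conventional significance stars
#'
#' Stars follow the usual figure-legend convention:
#' `****` p < 0.0001, `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' `ns` otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector of the same length.
#' @export
p_stars <- function(p) {
  stopifnot(is.numeric(p))
  out <- rep("ns", length(p))
  out[p < 0.05]   <- "*"
  out[p < 0.01]   <- "**"
  out[p < 0.001]  <- "***"
  out[p < 0.0001] <- "****"
  out[is.na(p)]   <- NA_character_
  out
}

# Deterministic child seed from a master seed; keeps values well inside the
# 32-bit integer range so derived seeds remain valid R integers.
child_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 1009 + offset * 9973) %% 2147483647)
}

# Evaluate an expression under a local RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
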