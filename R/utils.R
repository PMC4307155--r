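# Shared internal helpers.

#' Round half away from zero to the nearest integer
#'
#' Nominal-mass binning uses commercial ("half-up") rounding rather than the
#' IEC half-to-even rule of [base::round()], so that e.g. an m/z of 45.5
#' always bins to 46.
#'
#' @param x numeric vector.
#' @return integer vector.
#' @keywords internal
#' @noRd
round_half_up <- function(x) {
  as.integer(floor(x + 0.5))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
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
  force(expr)
}

# scalar checks used by constructors
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
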