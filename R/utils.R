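# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; replicate-number reporting uses the
#' conventional "round half away from zero" instead, so e.g. 8.5 -> 9 and
#' 4.5 -> 5.
#' @param x numeric vector
#' @return integer-valued numeric vector
#' @keywords internal
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's .Random.seed afterwards so library code never clobbers user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    set.seed(as.integer(seed))
  }
  force(expr)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x)) {
    abort(sprintf("`%s` must be numeric and non-missing", name))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!all(lo_ok & hi_ok)) {
    abort(sprintf("`%s` out of range [%s, %s]", name, lower, upper))
  }
  invisible(x)
}
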