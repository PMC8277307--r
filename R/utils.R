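# internal helpers shared across modules

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library functions never clobber the
# session RNG.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Canonical stance class order
#'
#' The fixed class order used throughout the package: antivaccine,
#' provaccine, neutral. Confusion matrices, coefficient matrices and
#' prediction tie-breaks all follow this order.
#'
#' @return Character vector `c("anti", "pro", "neutral")`.
#' @export
stance_levels <- function() c("anti", "pro", "neutral")

# locale-independent lexicographic sort (C collation via radix)
lex_sort <- function(x) sort(x, method = "radix")

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}
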