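# internal helpers shared across modules

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards so library functions never perturb user RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))  # use the caller's RNG stream
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Format a p-value the way clinical tables print it
#'
#' Values below 0.001 are displayed as `"<0.001"`; otherwise three decimals.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return character vector.
#' @export
#' @examples
#' format_pvalue(c(0.0079, 0.4751, 2e-5))
format_pvalue <- function(p) {
  stopifnot(is.numeric(p), all(is.na(p) | (p >= 0 & p <= 1)))
  out <- sprintf("%.3f", p)
  out[!is.na(p) & p < 1e-3] <- "<0.001"
  out[is.na(p)] <- NA_character_
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
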