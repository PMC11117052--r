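# shared constants and small helpers

#' Standard amino-acid alphabet
#'
#' The 20 canonical amino-acid one-letter codes. The stop symbol `"*"` is used
#' only to flag nonproductive chains and never appears in productive sequences.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

REGIONS_V <- c("FR1", "CDR1", "FR2", "CDR2", "FR3")
REGIONS_ALL <- c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4")
CDR_REGIONS <- c("CDR1", "CDR2", "CDR3")

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

rand_aa <- function(n) paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stopf("'%s' must be a single probability in [0, 1]", name)
  x
}
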