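# internal helpers shared across modules

# evaluate `code` under a temporary RNG state seeded with `seed`;
# the caller's RNG stream is left untouched
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

deg <- function(x) x * 180 / pi

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
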