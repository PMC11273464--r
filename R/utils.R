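#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run code under a local Mersenne-Twister stream without disturbing the
## caller's RNG state. All randomness in the package funnels through here so
## results are reproducible from a single integer seed.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", sample.kind = "Rejection")
  code
}

stop_fmll <- function(...) stop(sprintf(...), call. = FALSE)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
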