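## Seed handling: every stochastic entry point takes an explicit `seed` and
## runs under a local RNG state, so package calls never disturb the caller's
## stream and identical seeds give identical results.
withSeed <- function(seed, code) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(as.integer(seed))
    }
    force(code)
}

## Derive a child seed < 2^31 from a base seed and a stream label.
childSeed <- function(seed, stream) {
    if (is.null(seed)) return(NULL)
    h <- sum(utf8ToInt(as.character(stream)) * (31L^(seq_along(utf8ToInt(as.character(stream))) %% 7L)))
    as.integer((as.numeric(seed) * 48271 + h) %% 2147483562) + 1L
}

msgf <- function(fmt, ..., verbose = TRUE) {
    if (isTRUE(verbose)) message(sprintf(fmt, ...))
    invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
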