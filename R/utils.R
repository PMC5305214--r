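# Run expr under a local RNG state seeded with `seed`, restoring the caller's
# stream afterwards. All stochastic entry points route through this so a seed
# argument fully determines their output without touching global state.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv()))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(seed)
    }
    force(expr)
}

# Trapezoidal integral on a uniform or non-uniform grid.
trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

`%||%` <- function(a, b) if (is.null(a)) b else a

assertScalar <- function(x, name, lower = -Inf, upper = Inf) {
    if (length(x) != 1L || !is.finite(x) || x < lower || x > upper)
        stop(sprintf("'%s' must be a single finite value in [%g, %g]",
                     name, lower, upper), call. = FALSE)
    invisible(x)
}
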