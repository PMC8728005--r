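## Internal helpers shared across modules.

# Run code under a fixed RNG seed, restoring (or clearing) the caller's
# RNG state afterwards. All simulators and any seeded sampling go through
# this so that identical (seed, config) gives identical output regardless
# of surrounding RNG use.
with_seed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(code)
}

# Derive an independent substream seed for a named generator from one base
# seed, keeping the result a valid 32-bit R integer.
substream_seed <- function(seed, offset) {
    as.integer((as.numeric(seed) + 1000003 * offset) %% .Machine$integer.max)
}

# Median-of-3 smoothing with endpoint replication; used before valley and
# peak detection on k-mer spectra.
median3 <- function(x) {
    n <- length(x)
    if (n < 3L) return(x)
    xm <- cbind(c(x[1L], x[-n]), x, c(x[-1L], x[n]))
    apply(xm, 1L, stats::median)
}

random_dna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
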