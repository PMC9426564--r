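## Internal helpers.

## Evaluate expr under a local, seeded RNG stream without disturbing the
## caller's RNG state. seed = NULL uses the current stream.
.with_seed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    withr::with_seed(as.integer(seed), expr)
}

.assert <- function(cond, ...) {
    if (!isTRUE(cond)) stop(..., call. = FALSE)
    invisible(TRUE)
}

## Coerce sequence input (DNAStringSet, character vector, or a single
## string) to an upper-case character vector.
.as_seq_chr <- function(x) {
    if (methods::is(x, "XStringSet")) x <- as.character(x)
    .assert(is.character(x), "sequences must be a character vector or DNAStringSet")
    toupper(x)
}

## Reverse complement for plain character vectors (test-scale use).
.revcomp <- function(x) .revcomp_chr(toupper(x))

.canonical <- function(x) pmin(x, .revcomp(x))
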