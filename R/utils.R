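## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

## all genomic coordinates in this package are 0-based half-open [start, end),
## the native convention of BED and genePred; conversion to R's 1-based closed
## indexing happens only at sequence access.
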