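#' @keywords internal
"_PACKAGE"

#' @importFrom stats p.adjust pchisq phyper pnorm quantile rnbinom runif setNames var
#' @importFrom utils combn read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

# Deterministic sub-stream seeds: one user-facing seed per call, one derived
# seed per internal stage, so extending a simulation does not reshuffle
# earlier draws. Kept below 2^31 - 1.
substream_seed <- function(seed, stage) {
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 %% 2147483647 +
                9973 * as.numeric(stage)) %% 2147483647)
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
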