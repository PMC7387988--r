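#' @importFrom rlang .data
#' @importFrom stats rnorm runif var setNames
NULL

# Deterministic substream seeds: every stochastic component (simulation,
# weight init, dropout, splits) draws its own seed from the master seed so
# components are reproducible in isolation. Seeds stay below 2^31 - 1.
substream_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 2654435.0)
  as.integer((abs(master) * 69069 + h) %% 2147483587) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_sfcnn <- function(...) stop(..., call. = FALSE)
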