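#' @keywords internal
#' @importFrom rlang .data %||%
"_PACKAGE"

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# derive a per-run child seed that stays inside 32-bit integer range
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
}
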