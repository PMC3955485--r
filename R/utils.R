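## Internal helpers shared across modules.

# Classed condition so callers can distinguish load/validation failures.
pcx_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "pathconsensus_error"), ...)
}

#' Render a p-value the way the consensus report prints it
#'
#' Values below 1e-4 are rendered in scientific notation with two decimals
#' (e.g. `"8.33E-05"`); larger values as fixed-point with six decimals
#' (e.g. `"0.009461"`). [parse_pvalue()] inverts the rendering.
#'
#' @param p Numeric vector of probabilities.
#' @return Character vector, one rendered value per input.
#' @export
#' @examples
#' format_pvalue(c(8.33e-05, 0.009461))
format_pvalue <- function(p) {
  stopifnot(is.numeric(p))
  out <- character(length(p))
  sci <- !is.na(p) & p < 1e-4
  out[sci] <- sprintf("%.2E", p[sci])
  out[!sci] <- sprintf("%.6f", p[!sci])
  out[is.na(p)] <- NA_character_
  out
}

#' @rdname format_pvalue
#' @param x Character vector produced by `format_pvalue()`.
#' @export
parse_pvalue <- function(x) {
  as.numeric(x)
}

# Deterministic sub-seed derivation: distinct streams per stage/dataset from
# one user seed, kept within 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(offset)) %% .Machine$integer.max)
}
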