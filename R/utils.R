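#' Round half away from zero
#'
#' Screen percentages are reported with conventional half-up rounding
#' (5.0802 -> 5.1), not the banker's rounding of [base::round()].
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Derive a child seed from a master seed
#'
#' Every generator in the package takes an explicit integer seed. A single
#' master seed spawns per-component child seeds through this fixed scheme, so
#' regenerating one component never perturbs the draws of another. The result
#' is always a valid 32-bit R integer.
#'
#' @param seed master seed (single integer).
#' @param tag character tag naming the component (e.g. "interactome").
#' @return a single integer seed.
#' @export
child_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(tag))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(seed) * 7919 + h * 104729 + 13) %% 2147483562L + 1L)
}

# internal: strict scalar checks used by loaders and constructors
is_scalar_chr <- function(x) is.character(x) && length(x) == 1 && !is.na(x)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == floor(x)
}
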