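#' @importFrom rlang .data %||%
#' @importFrom generics tidy glance augment
#' @importFrom ggplot2 autoplot
#' @importFrom tibble as_tibble
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' @export
tibble::as_tibble

# Holm-Sidak step-down multiplicity correction.
# Ordered p-values get adj_i = cummax(1 - (1 - p_(j))^(m - j + 1)), clipped to 1.
#' Holm-Sidak adjusted p-values
#'
#' Step-down Sidak correction over a family of m tests: the j-th smallest
#' p-value is adjusted to `1 - (1 - p)^(m - j + 1)`, with a running maximum
#' enforcing monotonicity.
#'
#' @param p Numeric vector of raw p-values (NAs preserved).
#' @return Adjusted p-values in the original order.
#' @export
p_adjust_holm_sidak <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (length(ok) == 0) return(out)
  m <- length(ok)
  o <- order(p[ok])
  ps <- p[ok][o]
  adj <- pmin(1, cummax(1 - (1 - ps)^(m - seq_len(m) + 1)))
  out[ok[o]] <- adj
  out
}

# Deterministic sub-seed derivation, kept below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1000003L * as.integer(offset)) %% 214748329L
}
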