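#' Shannon entropy of a discrete probability distribution
#'
#' Computes `-sum(p * log2(p))` in bits, with the convention `0 * log2(0) = 0`.
#' Entropy is maximal (`log2(n)`) for the uniform distribution over `n`
#' outcomes and approaches 0 as any single outcome takes all the mass.
#'
#' @param p numeric vector of non-negative probabilities summing to 1.
#' @param tol tolerance on `sum(p) == 1` and on negativity of entries.
#' @return entropy in bits, a single non-negative number in `[0, log2(length(p))]`.
#' @examples
#' shannon_entropy(rep(0.25, 4)) # 2 bits
#' shannon_entropy(c(0.5, 0.25, 0.25)) # 1.5 bits
#' @export
shannon_entropy <- function(p, tol = 1e-9) {
  if (!is.numeric(p) || length(p) < 1) {
    stop("invalid distribution: 'p' must be a non-empty numeric vector")
  }
  if (any(!is.finite(p)) || any(p < -tol)) {
    stop("invalid distribution: entries must be finite and non-negative")
  }
  if (abs(sum(p) - 1) > tol) {
    stop("invalid distribution: entries must sum to 1 (got ", format(sum(p)), ")")
  }
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Normalize non-negative counts/energies to a probability vector.
normalize_prob <- function(x, what = "vector") {
  s <- sum(x)
  if (!is.finite(s) || s <= .Machine$double.eps * length(x)) {
    stop("degenerate ", what, ": total mass is zero, cannot normalize")
  }
  x / s
}
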