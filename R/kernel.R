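#' Binomial segregation probability mass
#'
#' Probability that the randomly selected daughter of a mother dividing with
#' `z0` plasmids inherits exactly `z` of them, when each plasmid moves into
#' the selected daughter independently with probability `p`:
#' `choose(z0, z) p^z (1-p)^(z0-z)`.
#'
#' @param z daughter copy number(s), `0 <= z <= z0`.
#' @param z0 mother copy number at division (single integer >= 0).
#' @param p segregation probability for this mother, in `[0, 1]`.
#' @return Probability mass at `z` (vectorized over `z`).
#' @seealso [segregation_kernel()]
#' @export
segregation_pmf <- function(z, z0, p) {
  if (length(z0) != 1L || z0 < 0 || z0 != floor(z0)) {
    stop("z0 must be a single non-negative integer")
  }
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("p must be a probability")
  }
  if (anyNA(z) || any(z < 0) || any(z > z0) || any(z != floor(z))) {
    stop("daughter copy number z must satisfy 0 <= z <= z0")
  }
  dbinom(z, size = z0, prob = p)
}

# d/dp of the binomial pmf, stable at p = 0 and p = 1:
# d/dp Bin(z; n, p) = n * (Bin(z-1; n-1, p) - Bin(z; n-1, p))
dsegregation_pmf <- function(z, z0, p) {
  if (z0 == 0L) return(rep(0, length(z)))
  z0 * (dbinom(z - 1, z0 - 1, p) - dbinom(z, z0 - 1, p))
}

#' Two-daughter segregation kernel
#'
#' Distribution of inherited copy numbers over *both* daughters of a mother
#' with `z0` plasmids: `k(z; z0) = g(z; z0) + g(z0 - z; z0)` with `g` the
#' binomial mass of [segregation_pmf()]. The kernel is symmetric,
#' `k(z; z0) = k(z0 - z; z0)` (and invariant under `p -> 1 - p`), and has
#' total mass 2 - one cell count per daughter.
#'
#' @inheritParams segregation_pmf
#' @param z0 mother copy number at division (single integer >= 1).
#' @return Kernel weight(s) at `z`.
#' @export
segregation_kernel <- function(z, z0, p) {
  if (length(z0) != 1L || z0 < 1 || z0 != floor(z0)) {
    stop("z0 must be a single integer >= 1")
  }
  segregation_pmf(z, z0, p) + segregation_pmf(z0 - z, z0, p)
}

dsegregation_kernel <- function(z, z0, p) {
  dsegregation_pmf(z, z0, p) + dsegregation_pmf(z0 - z, z0, p)
}
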