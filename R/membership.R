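#' Fuzzy c-means membership from centroid distances
#'
#' The shared membership functional of all three weight systems: given the
#' Euclidean distances of one point to `c` cluster centroids, the membership
#' to cluster i is
#' \deqn{u_i = 1 / \sum_j (d_i / d_j)^{2/(m-1)}}
#' so memberships lie in \[0, 1\] and sum to 1. When the point coincides
#' with one or more centroids (zero distance), the unit membership is split
#' equally among the coincident clusters and the rest receive 0.
#'
#' @param distances Numeric vector of `c >= 1` finite, non-negative
#'   distances.
#' @param m Fuzzifier exponent, > 1.
#'
#' @return Numeric vector of memberships, same length as `distances`,
#'   summing to 1.
#' @export
#' @examples
#' fuzzy_membership(c(1, 2), m = 2)   # c(0.8, 0.2)
#' fuzzy_membership(c(0, 5), m = 2)   # c(1, 0)
fuzzy_membership <- function(distances, m = 2) {
  if (!is.numeric(m) || length(m) != 1L || m <= 1)
    stop("fuzzifier 'm' must be a single number > 1", call. = FALSE)
  if (length(distances) < 1L || !all(is.finite(distances)))
    stop("'distances' must be a non-empty finite numeric vector", call. = FALSE)
  if (any(distances < 0))
    stop("'distances' must be non-negative", call. = FALSE)
  zero <- distances == 0
  if (any(zero)) {
    u <- as.numeric(zero) / sum(zero)
    return(u)
  }
  pw <- distances^(-2 / (m - 1))
  pw / sum(pw)
}

# Row-wise membership over a distance matrix (points x clusters); same
# semantics as fuzzy_membership applied per row, vectorized for the
# clustering engines.
.membership_rows <- function(D, m) {
  zero <- D == 0
  pw <- D^(-2 / (m - 1))
  U <- pw / rowSums(pw)
  hit <- rowSums(zero) > 0
  if (any(hit)) {
    Z <- zero[hit, , drop = FALSE]
    U[hit, ] <- Z / rowSums(Z)
  }
  U
}

# Elementwise two-cluster membership to the first centroid, for paired
# distance matrices d1 (to the "target" centroid) and d2 (to the other).
.membership2 <- function(d1, d2, m) {
  u <- 1 / (1 + (d1 / d2)^(2 / (m - 1)))
  both0 <- d1 == 0 & d2 == 0
  u[d1 == 0] <- 1
  u[d2 == 0 & d1 > 0] <- 0
  u[both0] <- 0.5
  u
}
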