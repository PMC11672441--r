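# Squared Euclidean distances from each row of X to each row of V.
.sqdist <- function(X, V) {
  d2 <- outer(rowSums(X^2), rowSums(V^2), "+") - 2 * tcrossprod(X, V)
  pmax(d2, 0)
}

# k-means++-style seeded centroid draw: first centroid uniform, each next
# one with probability proportional to its squared distance to the nearest
# centroid chosen so far.
.init_centroids <- function(X, c, seed) {
  withr::with_seed(seed, {
    n <- nrow(X)
    idx <- integer(c)
    idx[1] <- sample.int(n, 1L)
    if (c > 1L) for (j in 2:c) {
      d2 <- .sqdist(X, X[idx[seq_len(j - 1L)], , drop = FALSE])
      w <- apply(d2, 1L, min)
      idx[j] <- if (sum(w) > 0) sample.int(n, 1L, prob = w) else sample.int(n, 1L)
    }
    X[idx, , drop = FALSE]
  })
}

#' Fuzzy c-means clustering
#'
#' Standard FCM: alternating closed-form updates of the membership matrix
#' (via the shared membership functional) and the fuzzy-weighted centroids,
#' minimizing \eqn{J = \sum_{ij} u_{ij}^m d_{ij}^2}. Initialization is a
#' seeded k-means++-style draw from the data, so identical seeds give
#' identical models.
#'
#' @param points Numeric matrix (observations x features) or vector.
#' @param c Number of clusters, `1 <= c <= nrow(points)`.
#' @param config A [fuzzy_config()] (fuzzifier, tolerance, iteration cap,
#'   seed).
#' @return A `cluster_model`: list with `centroids` (c x d),
#'   `memberships` (n x c, rows summing to 1), `typicalities` (here equal
#'   to memberships), and `objective_trace`.
#' @export
fcm_fit <- function(points, c, config = fuzzy_config()) {
  X <- as.matrix(points)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (c < 1L || c > n)
    stop("'c' must satisfy 1 <= c <= number of points", call. = FALSE)
  m <- config$m
  V <- .init_centroids(X, c, config$seed)
  trace <- numeric(0)
  U <- NULL
  for (it in seq_len(config$max_iter)) {
    D2 <- .sqdist(X, V)
    U <- .membership_rows(sqrt(D2), m)
    Um <- U^m
    V <- (t(Um) %*% X) / pmax(colSums(Um), .Machine$double.xmin)
    J <- sum(Um * .sqdist(X, V))
    trace <- c(trace, J)
    if (it > 1L && abs(trace[it - 1L] - J) < config$tol) break
  }
  U <- .membership_rows(sqrt(.sqdist(X, V)), m)
  structure(list(centroids = V, memberships = U, typicalities = U,
                 objective_trace = trace, m = m),
            class = "cluster_model")
}

#' Possibilistic fuzzy c-means with regularization
#'
#' A reconstruction of the regularized PFCM family: the objective blends
#' the probabilistic membership term (weight `a`, fuzzifier `m`), the
#' possibilistic typicality term (weight `b`, exponent `eta`, per-cluster
#' scale `gamma`) and a quadratic membership regularizer
#' \eqn{\lambda \sum u^m} that flattens the solution space on small data:
#' \deqn{J = \sum_{ij} (a u_{ij}^m + b t_{ij}^\eta) d_{ij}^2
#'       + \sum_j \gamma_j \sum_i (1 - t_{ij})^\eta + \lambda \sum_{ij} u_{ij}^m}
#' Every alternating update is the exact minimizer of its block (the
#' regularizer folds into the membership update as an additive distance
#' offset), so the objective trace is non-increasing. `gamma` is
#' initialized from an FCM pre-pass as the within-cluster mean fuzzy
#' squared distance. With `lam = 0` and `b = 0` the model reduces to FCM.
#'
#' @inheritParams fcm_fit
#' @param params A [pfcm_params()].
#' @return A `cluster_model` with distinct `memberships` (rows summing to
#'   1) and `typicalities` (unconstrained in \[0, 1\]).
#' @export
pfcm_r_fit <- function(points, c, params = pfcm_params(),
                       config = fuzzy_config()) {
  X <- as.matrix(points)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (c < 1L || c > n)
    stop("'c' must satisfy 1 <= c <= number of points", call. = FALSE)
  m <- config$m
  a <- params$a; b <- params$b; eta <- params$eta; lam <- params$lam
  pre <- fcm_fit(X, c, config)
  Um <- pre$memberships^m
  D2 <- .sqdist(X, pre$centroids)
  gamma <- colSums(Um * D2) / pmax(colSums(Um), .Machine$double.xmin)
  gamma <- pmax(gamma, config$epsilon)
  V <- pre$centroids
  upd_u <- function(D2) {
    if (a > 0) .membership_rows(sqrt(a * D2 + lam), m)
    else matrix(1 / c, nrow(D2), ncol(D2))
  }
  upd_t <- function(D2) {
    if (b == 0) return(matrix(1, nrow(D2), ncol(D2)))
    r <- sweep(D2 * b, 2L, gamma, "/")
    1 / (1 + r^(1 / (eta - 1)))
  }
  obj <- function(U, Tt, D2)
    sum((a * U^m + b * Tt^eta) * D2) +
      sum(sweep((1 - Tt)^eta, 2L, gamma, "*")) + lam * sum(U^m)
  trace <- numeric(0)
  U <- Tt <- NULL
  for (it in seq_len(config$max_iter)) {
    D2 <- .sqdist(X, V)
    U <- upd_u(D2)
    Tt <- upd_t(D2)
    wts <- a * U^m + b * Tt^eta
    V <- (t(wts) %*% X) / pmax(colSums(wts), .Machine$double.xmin)
    J <- obj(U, Tt, .sqdist(X, V))
    trace <- c(trace, J)
    if (it > 1L && abs(trace[it - 1L] - J) < config$tol) break
  }
  D2 <- .sqdist(X, V)
  U <- upd_u(D2)
  Tt <- upd_t(D2)
  structure(list(centroids = V, memberships = U, typicalities = Tt,
                 objective_trace = trace, m = m, gamma = gamma,
                 params = params),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("Fuzzy cluster model: %d clusters, %d points, %d iterations (final objective %.6g)\n",
              nrow(x$centroids), nrow(x$memberships),
              length(x$objective_trace),
              if (length(x$objective_trace)) x$objective_trace[length(x$objective_trace)] else NA))
  invisible(x)
}
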