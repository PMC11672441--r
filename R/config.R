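#' Fuzzy inference configuration
#'
#' Bundles the numerical controls shared by every fuzzy engine: the fuzzifier
#' exponent, cluster-count context, distance floor, iteration caps and the
#' RNG seed used by the clustering engines.
#'
#' @param m Fuzzifier exponent (> 1). Controls membership softness; `m -> 1`
#'   approaches hard assignment. Default 2, the conventional fuzzy c-means
#'   choice.
#' @param c Cluster count for free clustering. Context dependent; engines
#'   that cluster against fixed centroids ignore it.
#' @param epsilon Small non-negative distance floor guarding ratio
#'   denominators in degenerate geometry.
#' @param max_iter Iteration cap for the alternating clustering updates.
#' @param tol Convergence tolerance on the objective decrease.
#' @param seed Integer seed for any randomized initialization.
#'
#' @return An object of class `fuzzy_config` (a named list).
#' @export
#' @examples
#' fuzzy_config(m = 1.5)
fuzzy_config <- function(m = 2, c = 2L, epsilon = 1e-12, max_iter = 100L,
                         tol = 1e-8, seed = 1L) {
  if (!is.numeric(m) || length(m) != 1L || m <= 1)
    stop("fuzzifier 'm' must be a single number > 1", call. = FALSE)
  if (epsilon <= 0) stop("'epsilon' must be > 0", call. = FALSE)
  structure(list(m = m, c = as.integer(c), epsilon = epsilon,
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed)),
            class = "fuzzy_config")
}

#' PFCM parameters
#'
#' Parameters of the possibilistic fuzzy c-means objective: the relative
#' weights of the probabilistic membership term (`a`) and the possibilistic
#' typicality term (`b`), the typicality exponent `eta`, and the strength
#' `lam` of the quadratic membership regularizer that stabilizes solutions
#' on small data.
#'
#' @param a Membership blend weight (>= 0).
#' @param b Typicality blend weight (>= 0); `a + b` must be positive.
#' @param eta Typicality exponent (> 1).
#' @param lam Regularization strength (>= 0).
#'
#' @return An object of class `pfcm_params`.
#' @export
pfcm_params <- function(a = 1, b = 1, eta = 2, lam = 0.1) {
  if (a < 0 || b < 0 || a + b <= 0)
    stop("need a >= 0, b >= 0 and a + b > 0", call. = FALSE)
  if (eta <= 1) stop("'eta' must be > 1", call. = FALSE)
  if (lam < 0) stop("'lam' must be >= 0", call. = FALSE)
  structure(list(a = a, b = b, eta = eta, lam = lam), class = "pfcm_params")
}

#' Noise-robustness protocol configuration
#'
#' Describes how corrupted query sets are built: query size, the noise
#' levels to evaluate (level L replaces L of the relevant symptoms with
#' symptoms unrelated to the target), replicate count and target
#' eligibility.
#'
#' @param query_size Number of symptoms per query (default 5).
#' @param levels Noise levels to build, a subset of `0:3` by default; level
#'   L queries carry exactly L unrelated symptoms.
#' @param replicates Number of independently sampled query sets per target.
#' @param seed Integer RNG seed for all sampling in the protocol.
#' @param min_symptoms Eligibility threshold: targets need at least this
#'   many registered symptoms (default 5).
#' @param n_targets Number of eligible target diseases to evaluate; when
#'   more diseases are eligible a seeded uniform subsample of this size is
#'   used. `NULL` evaluates every eligible target.
#'
#' @return An object of class `noise_protocol`.
#' @export
noise_protocol <- function(query_size = 5L, levels = 0:3, replicates = 1L,
                           seed = 1L, min_symptoms = 5L, n_targets = 50L) {
  levels <- sort(unique(as.integer(levels)))
  if (any(levels < 0)) stop("noise levels must be >= 0", call. = FALSE)
  if (max(levels) > query_size)
    stop("noise count cannot exceed 'query_size'", call. = FALSE)
  if (replicates < 1) stop("'replicates' must be >= 1", call. = FALSE)
  structure(list(query_size = as.integer(query_size), levels = levels,
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 min_symptoms = as.integer(min_symptoms),
                 n_targets = if (is.null(n_targets)) NULL else as.integer(n_targets)),
            class = "noise_protocol")
}

#' Synthetic knowledge-base configuration
#'
#' Structural statistics of the generated symptom-disease knowledge base.
#' Defaults emulate the scale of the motivating textbook-derived database:
#' 241 symptoms over 16 observed parts, 249 diseases over 12 appeared
#' parts, with at least 50 diseases carrying 5+ symptoms so the noise
#' benchmark always has its full target pool.
#'
#' @param n_symptoms,n_diseases Vocabulary sizes.
#' @param n_observed_parts Number of owner-facing observation locations
#'   (>= `n_appeared_parts`).
#' @param n_appeared_parts Number of body systems a disease manifests on.
#' @param symptoms_per_disease Integer range `c(min, max)` from which each
#'   disease's symptom count is drawn uniformly.
#' @param cross_part_rate Probability `rho` that an individual
#'   disease-symptom draw comes from a body part other than the disease's
#'   own (emulating symptoms that show up away from the affected system).
#' @param min_eligible Required number of diseases with >= 5 symptoms;
#'   generation re-draws (bounded retries) until satisfied.
#' @param seed Integer RNG seed.
#'
#' @return An object of class `synthetic_kb_config`.
#' @export
synthetic_kb_config <- function(n_symptoms = 241L, n_diseases = 249L,
                                n_observed_parts = 16L, n_appeared_parts = 12L,
                                symptoms_per_disease = c(3L, 12L),
                                cross_part_rate = 0.2, min_eligible = 50L,
                                seed = 1L) {
  if (n_observed_parts < n_appeared_parts || n_appeared_parts < 1)
    stop("need n_observed_parts >= n_appeared_parts >= 1", call. = FALSE)
  if (length(symptoms_per_disease) != 2L || symptoms_per_disease[1] < 1 ||
      symptoms_per_disease[2] < symptoms_per_disease[1])
    stop("'symptoms_per_disease' must be an increasing range with min >= 1",
         call. = FALSE)
  if (cross_part_rate < 0 || cross_part_rate > 1)
    stop("'cross_part_rate' must lie in [0, 1]", call. = FALSE)
  structure(list(n_symptoms = as.integer(n_symptoms),
                 n_diseases = as.integer(n_diseases),
                 n_observed_parts = as.integer(n_observed_parts),
                 n_appeared_parts = as.integer(n_appeared_parts),
                 symptoms_per_disease = as.integer(symptoms_per_disease),
                 cross_part_rate = cross_part_rate,
                 min_eligible = as.integer(min_eligible),
                 seed = as.integer(seed)),
            class = "synthetic_kb_config")
}
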