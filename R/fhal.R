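#' Train the hybrid fuzzy association learner
#'
#' Builds the three association matrices of the double-layered learner
#' from knowledge-base counts:
#' \itemize{
#'   \item `w1` (symptom x appeared part, input to middle layer):
#'     `w1[s, p]` is the fraction of diseases carrying s that appear on
#'     part p; rows of symptoms that occur in at least one disease sum
#'     to 1.
#'   \item `w2` (appeared part x disease, middle to output layer): within
#'     each part, diseases are weighted by their symptom count and
#'     normalized, so `w2[p, z]` is z's share of part p's symptom mass.
#'   \item `w3` (symptom x disease, direct association): `1/|S_z|` when
#'     (z, s) are associated, 0 otherwise.
#' }
#'
#' @param kb A `knowledge_base`.
#' @param tau First-layer pass fraction in (0, 1]: a query symptom is kept
#'   only if its support on the dominant part reaches `tau` times the mean
#'   dominant-part support of the query.
#' @param alpha Blend in \[0, 1\] between the direct path (`alpha`) and
#'   the indirect path through the part layer (`1 - alpha`).
#' @return An object of class `fhal_weights`.
#' @export
fhal_train <- function(kb, tau = 0.5, alpha = 0.5) {
  if (tau <= 0 || tau > 1) stop("'tau' must lie in (0, 1]", call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("'alpha' must lie in [0, 1]", call. = FALSE)
  parts <- kb$appeared_parts$part_id
  inc <- kb$incidence
  # diseases on part p containing s, per (s, p)
  byp <- rowsum(inc, kb$diseases$appeared_part)           # used parts x symptoms
  counts <- matrix(0, nrow(kb$symptoms), length(parts),
                   dimnames = list(as.character(kb$symptoms$symptom_id),
                                   as.character(parts)))
  counts[, rownames(byp)] <- t(byp)
  tot <- rowSums(counts)
  w1 <- counts / pmax(tot, 1)
  nsym <- kb$derived$n_symptoms_per_disease
  w2 <- matrix(0, length(parts), nrow(kb$diseases),
               dimnames = list(as.character(parts),
                               as.character(kb$diseases$disease_id)))
  for (p in seq_along(parts)) {
    on_p <- kb$diseases$appeared_part == parts[p]
    mass <- nsym * on_p
    if (sum(mass) > 0) w2[p, ] <- mass / sum(mass)
  }
  w3 <- t(inc / pmax(nsym, 1))
  structure(list(w1 = w1, w2 = w2, w3 = w3, tau = tau, alpha = alpha,
                 parts = parts), class = "fhal_weights")
}

#' Hybrid fuzzy association inference
#'
#' Two-pass inference. First layer: the query's support for each appeared
#' part is accumulated through `w1`; the dominant part `p*` is the argmax
#' (ties to the smaller part id), and query symptoms whose support on
#' `p*` falls below `tau` times the query's mean support there are
#' filtered out as likely outliers. Second layer: the surviving symptoms
#' drive the indirect part-mediated score `w1[s, part(z)] * w2[part(z), z]`,
#' blended with the direct association score from `w3` over the full
#' query. If every symptom is filtered the engine falls back to the
#' direct path alone.
#'
#' @param kb A `knowledge_base`.
#' @param weights An `fhal_weights` from [fhal_train()].
#' @param query A query data frame.
#' @param config A [fuzzy_config()] (accepted for engine-contract
#'   uniformity; this engine is count-based and deterministic).
#' @return A `ranked_diagnosis`.
#' @export
fhal_infer <- function(kb, weights, query, config = fuzzy_config()) {
  validate_query(kb, query)
  si <- match(query$symptom_id, kb$symptoms$symptom_id)
  W1q <- weights$w1[si, , drop = FALSE]
  A <- colSums(W1q)
  pstar <- which.max(A)  # ties: first index = smaller part id
  n <- nrow(query)
  thr <- weights$tau * A[pstar] / n
  keep <- W1q[, pstar] >= thr
  if (!any(keep))
    message("all query symptoms filtered by the part layer; using direct associations only")
  zpart <- match(kb$diseases$appeared_part, weights$parts)
  direct <- as.numeric(t(weights$w3[si, , drop = FALSE]) %*% rep(1, n))
  indirect <- numeric(nrow(kb$diseases))
  if (any(keep)) {
    ks <- which(keep)
    supp <- colSums(W1q[ks, , drop = FALSE])     # per-part retained support
    indirect <- supp[zpart] * weights$w2[cbind(zpart, seq_len(nrow(kb$diseases)))]
  }
  alpha <- weights$alpha
  score <- if (any(keep)) alpha * direct + (1 - alpha) * indirect else direct
  .rank_diagnosis(data.frame(disease_id = kb$diseases$disease_id,
                             score = score),
                  kb, "fhal")
}
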