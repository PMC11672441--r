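#' Symptom relevance coordinates
#'
#' Places every symptom in the unit square used by the first weight layer:
#' `x` is the number of diseases carrying the symptom divided by the total
#' disease count, `y` the number of distinct appeared parts among those
#' diseases divided by the appeared-part vocabulary size. A symptom near
#' (0, 0) is carried by few diseases on few body systems and is therefore
#' highly informative ("related"); a symptom near (1, 1) is ubiquitous
#' ("unrelated").
#'
#' @param kb A `knowledge_base`.
#' @return Data frame with columns `symptom_id`, `x`, `y`.
#' @export
compute_symptom_coords <- function(kb) {
  nd <- nrow(kb$diseases)
  np <- nrow(kb$appeared_parts)
  counts <- colSums(kb$incidence)
  # appeared-part x symptom presence: how many parts each symptom spans
  byp <- rowsum(kb$incidence, kb$diseases$appeared_part)
  spans <- colSums(byp > 0)
  data.frame(symptom_id = kb$symptoms$symptom_id,
             x = counts / nd, y = spans / np)
}

#' First-layer weights: symptom relevance (W1)
#'
#' For each query symptom, the fuzzy membership of its relevance
#' coordinates to the "related" centroid at (0, 0) versus the "unrelated"
#' centroid at (1, 1). The membership itself is the weight; the layer
#' output is weight times the input activation (1 for a selected symptom).
#'
#' @param kb A `knowledge_base`.
#' @param query A validated query (see [query_from_symptoms()]).
#' @param config A [fuzzy_config()].
#' @return Data frame with one row per query symptom: `symptom_id`, `x`,
#'   `y`, `d_related`, `d_unrelated`, `u`, `w`, `y_out`.
#' @export
compute_w1 <- function(kb, query, config = fuzzy_config()) {
  validate_query(kb, query)
  coords <- compute_symptom_coords(kb)
  i <- match(query$symptom_id, coords$symptom_id)
  x <- coords$x[i]; y <- coords$y[i]
  d_rel <- sqrt(x^2 + y^2)
  d_unrel <- sqrt((x - 1)^2 + (y - 1)^2)
  u <- .membership2(d_rel, d_unrel, config$m)
  data.frame(symptom_id = query$symptom_id, x = x, y = y,
             d_related = d_rel, d_unrelated = d_unrel,
             u = u, w = u, y_out = u * 1)
}

#' Second-layer weights: part-consistent symptom-disease connection (W2)
#'
#' Each query symptom's observed part is mapped through the part map to an
#' appeared part `p`. Diseases appearing on a different part receive the
#' fixed penalty weight -0.5 — the part the owner pointed at is not where
#' the disease manifests. Diseases on part `p` (the candidate set) share a
#' unit of membership computed from the Euclidean distance between the
#' symptom's one-hot indicator and each candidate's L1-normalized symptom
#' profile, so the connection is strongest to diseases in which the
#' symptom is most specific.
#'
#' @inheritParams compute_w1
#' @return Matrix of weights, diseases x query symptoms, with dimnames;
#'   entries are either a positive membership or exactly -0.5.
#' @export
compute_w2 <- function(kb, query, config = fuzzy_config()) {
  validate_query(kb, query)
  nd <- nrow(kb$diseases)
  nq <- nrow(query)
  W <- matrix(-0.5, nd, nq,
              dimnames = list(as.character(kb$diseases$disease_id),
                              as.character(query$symptom_id)))
  prof <- kb$derived$profiles_l1
  pr2 <- rowSums(prof^2)
  for (k in seq_len(nq)) {
    si <- match(query$symptom_id[k], kb$symptoms$symptom_id)
    p <- kb$derived$part_image[query$observed_part[k]]
    cand <- which(kb$diseases$appeared_part == p)
    if (length(cand) == 0L) {
      message("no disease appears on mapped part ", p,
              " for symptom ", query$symptom_id[k], "; all connections penalized")
      next
    }
    d2 <- pr2[cand] - 2 * prof[cand, si] + 1
    d <- sqrt(pmax(d2, 0))
    W[cand, k] <- fuzzy_membership(d, config$m)
  }
  W
}

#' Disease activation (layer N3)
#'
#' Aggregates the two weight layers over the query: the activation of
#' disease z is the mean over query symptoms of `w1_i * w2_{z,i}` (input
#' activations are 1). A disease whose part disagrees with every query
#' symptom bottoms out at -0.5; a disease is *activated* when its
#' activation is strictly positive.
#'
#' @param w1 Output of [compute_w1()].
#' @param w2 Output of [compute_w2()] for the same query.
#' @param query The query both were computed from.
#' @return Data frame with columns `disease_id`, `activation`,
#'   `activated`.
#' @export
activate_diseases <- function(w1, w2, query) {
  stopifnot(nrow(w1) == nrow(query), ncol(w2) == nrow(query))
  n <- nrow(query)
  y <- as.numeric(w2 %*% w1$w) / n
  data.frame(disease_id = as.integer(rownames(w2)),
             activation = y, activated = y > 0)
}

#' Third-layer refinement: disease neighborhood (W3)
#'
#' For each activated candidate target t, every activated disease z is
#' placed in a unit square where `x` is one minus the shared-symptom
#' fraction and `y` is one minus the normalized symptom-count difference
#' (both relative to `max(|S_z|, |S_t|)`), so z = t lands exactly on the
#' target centroid (0, 1). Membership is computed against that centroid
#' versus the anti-centroid (1, 0), and the final score of t is the mean
#' over activated nodes of membership times activation.
#'
#' @param kb A `knowledge_base`.
#' @param activations Output of [activate_diseases()].
#' @param config A [fuzzy_config()].
#' @return Data frame `disease_id`, `score` over activated candidates
#'   (unsorted); zero rows when nothing is activated.
#' @export
refine_w3 <- function(kb, activations, config = fuzzy_config()) {
  act <- activations[activations$activated, , drop = FALSE]
  if (nrow(act) == 0L)
    return(data.frame(disease_id = integer(), score = numeric()))
  di <- match(act$disease_id, kb$diseases$disease_id)
  sizes <- kb$derived$n_symptoms_per_disease[di]
  O <- kb$derived$co_occurrence[di, di, drop = FALSE]
  mx <- outer(sizes, sizes, pmax)
  X <- 1 - O / pmax(mx, 1)
  Y <- 1 - abs(outer(sizes, sizes, "-")) / pmax(mx, 1)
  # two empty symptom sets are identical: put them on the target centroid
  if (any(mx == 0)) { X[mx == 0] <- 0; Y[mx == 0] <- 1 }
  d1 <- sqrt(X^2 + (Y - 1)^2)     # to target centroid (0, 1)
  d2 <- sqrt((X - 1)^2 + Y^2)     # to anti-centroid (1, 0)
  U <- .membership2(d1, d2, config$m)
  score <- colMeans(U * act$activation)
  data.frame(disease_id = act$disease_id, score = score)
}

.rank_diagnosis <- function(scores, kb, engine, k = 5L) {
  o <- order(-scores$score, scores$disease_id)
  top <- scores[o, , drop = FALSE][seq_len(min(k, nrow(scores))), , drop = FALSE]
  di <- match(top$disease_id, kb$diseases$disease_id)
  out <- data.frame(disease_id = top$disease_id,
                    label = kb$diseases$description[di],
                    score = top$score)
  rownames(out) <- NULL
  structure(out, class = c("ranked_diagnosis", "data.frame"), engine = engine)
}

#' Multi-layered neuro-fuzzy inference
#'
#' The full pipeline: symptom-relevance weighting (W1), part-consistency
#' connection with -0.5 penalty (W2), mean activation per disease, and
#' disease-neighborhood refinement (W3), returning at most the five
#' highest-scoring activated diseases (ties broken by ascending disease
#' id). An empty ranking signals that no disease was activated, i.e. no
#' inference is possible for the query.
#'
#' @param kb A `knowledge_base`.
#' @param query A query (data frame of `observed_part`, `symptom_id`).
#' @param config A [fuzzy_config()].
#' @return A `ranked_diagnosis`: data frame `disease_id`, `label`, `score`
#'   sorted by descending score.
#' @export
#' @examples
#' kb <- generate_disjoint_kb(n_diseases = 6, symptoms_per_disease = 5,
#'                            parts = 6, seed = 1)
#' q <- query_from_symptoms(kb, kb$associations$symptom_id[1:5])
#' mnfl_infer(kb, q)
mnfl_infer <- function(kb, query, config = fuzzy_config()) {
  w1 <- compute_w1(kb, query, config)
  w2 <- compute_w2(kb, query, config)
  act <- activate_diseases(w1, w2, query)
  sc <- refine_w3(kb, act, config)
  .rank_diagnosis(sc, kb, "mnfl")
}

#' @export
print.ranked_diagnosis <- function(x, ...) {
  cat(sprintf("Ranked pre-diagnosis (%s engine)\n", attr(x, "engine")))
  if (nrow(x) == 0L) {
    cat("  <no disease activated>\n")
  } else {
    print.data.frame(cbind(rank = seq_len(nrow(x)), as.data.frame(x)),
                     row.names = FALSE, digits = 4)
  }
  invisible(x)
}
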