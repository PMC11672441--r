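#' PFCM-R inference over fixed disease prototypes
#'
#' The possibilistic-fuzzy baseline engine. Each disease is a fixed
#' prototype — its binary symptom profile scaled to unit Euclidean norm —
#' and the query is embedded the same way, so profile size does not bias
#' distances. The score of disease z blends the probabilistic membership
#' of the query over all prototypes with its possibilistic typicality:
#' \deqn{score_z = a u_z + b t_z, \quad
#'       t_z = 1 / (1 + (b d_z^2 / \gamma)^{1/(\eta - 1)})}
#' with the typicality scale \eqn{\gamma} set to the mean squared distance
#' between disease prototypes (a fixed property of the knowledge base).
#' The top five diseases by score are returned, ties broken by ascending
#' disease id; equidistant degenerate queries therefore fall back to id
#' order.
#'
#' @param kb A `knowledge_base`.
#' @param query A query data frame (`observed_part`, `symptom_id`).
#' @param params A [pfcm_params()].
#' @param config A [fuzzy_config()].
#' @return A `ranked_diagnosis`.
#' @export
pfcmr_infer <- function(kb, query, params = pfcm_params(),
                        config = fuzzy_config()) {
  validate_query(kb, query)
  si <- match(query$symptom_id, kb$symptoms$symptom_id)
  x <- numeric(nrow(kb$symptoms))
  x[si] <- 1
  x <- x / sqrt(sum(x))
  P <- kb$derived$profiles_l2
  d2 <- pmax(rowSums(P^2) - 2 * as.numeric(P %*% x) + 1, 0)
  u <- fuzzy_membership(sqrt(d2), config$m)
  gamma <- kb$derived$proto_gamma
  tt <- if (params$b == 0) rep(1, length(d2)) else
    1 / (1 + (params$b * d2 / gamma)^(1 / (params$eta - 1)))
  score <- params$a * u + params$b * tt
  .rank_diagnosis(data.frame(disease_id = kb$diseases$disease_id,
                             score = score),
                  kb, "pfcmr")
}
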