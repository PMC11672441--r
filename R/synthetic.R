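#' Generate a seeded synthetic knowledge base
#'
#' Emulates the structural statistics of a textbook-derived canine
#' symptom-disease database: symptoms spread uniformly over the observed
#' parts, a surjective observed-to-appeared part map, and diseases that
#' draw most of their symptoms from their own body system with a
#' contamination rate `rho` of cross-part draws (real diseases do present
#' symptoms away from the primarily affected system). Generation re-draws
#' with a derived sub-seed until at least `min_eligible` diseases carry
#' five or more symptoms, so the noise benchmark always has its target
#' pool.
#'
#' @param config A [synthetic_kb_config()].
#' @param max_attempts Bounded retries before giving up.
#' @return A validated `knowledge_base`.
#' @export
#' @examples
#' kb <- generate_kb(synthetic_kb_config(n_symptoms = 40, n_diseases = 20,
#'                                       min_eligible = 5, seed = 7))
#' kb
generate_kb <- function(config = synthetic_kb_config(), max_attempts = 25L) {
  stopifnot(inherits(config, "synthetic_kb_config"))
  if (config$n_symptoms < config$symptoms_per_disease[2])
    stop("not enough symptoms to satisfy the per-disease range", call. = FALSE)
  attempt_seeds <- withr::with_seed(config$seed,
    sample.int(.Machine$integer.max, max_attempts))
  for (s in attempt_seeds) {
    kb <- withr::with_seed(s, .generate_kb_once(config))
    n_elig <- sum(kb$derived$n_symptoms_per_disease >= 5)
    if (n_elig >= config$min_eligible) return(kb)
  }
  stop("could not generate a knowledge base with ", config$min_eligible,
       " eligible diseases in ", max_attempts, " attempts; ",
       "the configuration is infeasible", call. = FALSE)
}

.generate_kb_once <- function(cfg) {
  n_obs <- cfg$n_observed_parts; n_app <- cfg$n_appeared_parts
  observed_parts <- data.frame(part_id = seq_len(n_obs),
                               label = sprintf("observed_part_%02d", seq_len(n_obs)))
  appeared_parts <- data.frame(part_id = seq_len(n_app),
                               label = sprintf("appeared_part_%02d", seq_len(n_app)))
  # surjective map: every appeared part gets at least one observed part
  image <- sample(c(seq_len(n_app),
                    sample.int(n_app, n_obs - n_app, replace = TRUE)))
  part_map <- data.frame(observed_part = seq_len(n_obs), appeared_part = image)
  symptoms <- data.frame(
    symptom_id = seq_len(cfg$n_symptoms),
    description = sprintf("symptom_%03d", seq_len(cfg$n_symptoms)),
    observed_part = sample.int(n_obs, cfg$n_symptoms, replace = TRUE))
  diseases <- data.frame(
    disease_id = seq_len(cfg$n_diseases),
    description = sprintf("disease_%03d", seq_len(cfg$n_diseases)),
    appeared_part = sample.int(n_app, cfg$n_diseases, replace = TRUE))
  sym_app <- image[symptoms$observed_part]   # appeared-part image per symptom
  rng <- cfg$symptoms_per_disease
  assoc <- vector("list", cfg$n_diseases)
  for (z in seq_len(cfg$n_diseases)) {
    k <- sample(seq(rng[1], rng[2]), 1L)
    own <- which(sym_app == diseases$appeared_part[z])
    other <- which(sym_app != diseases$appeared_part[z])
    n_cross <- stats::rbinom(1L, k, cfg$cross_part_rate)
    n_cross <- min(n_cross, length(other))
    n_own <- min(k - n_cross, length(own))
    n_cross <- min(k - n_own, length(other))
    picked <- c(if (n_own > 0) .sample1(own, n_own),
                if (n_cross > 0) .sample1(other, n_cross))
    assoc[[z]] <- data.frame(disease_id = z, symptom_id = sort(picked))
  }
  assoc <- do.call(rbind, assoc)
  assoc <- cbind(id = seq_len(nrow(assoc)), assoc)
  knowledge_base(symptoms, diseases, assoc, observed_parts, appeared_parts,
                 part_map)
}

#' Generate a disjoint-symptom oracle knowledge base
#'
#' A deliberately easy fixture: every disease owns a pairwise-disjoint,
#' part-consistent block of symptoms, so the unique maximal-overlap
#' disease for any uncorrupted query is its target. Used by the
#' perfect-recovery checks.
#'
#' @param n_diseases Number of diseases.
#' @param symptoms_per_disease Symptoms owned by each disease.
#' @param parts Number of body parts (observed = appeared; identity part
#'   map). Diseases are assigned to parts round-robin.
#' @param seed Integer seed (kept for interface symmetry; construction is
#'   deterministic).
#' @return A validated `knowledge_base`.
#' @export
generate_disjoint_kb <- function(n_diseases, symptoms_per_disease, parts,
                                 seed = 1L) {
  n_sym <- n_diseases * symptoms_per_disease
  part_of_disease <- ((seq_len(n_diseases) - 1L) %% parts) + 1L
  sym_disease <- rep(seq_len(n_diseases), each = symptoms_per_disease)
  symptoms <- data.frame(
    symptom_id = seq_len(n_sym),
    description = sprintf("symptom_%03d", seq_len(n_sym)),
    observed_part = part_of_disease[sym_disease])
  diseases <- data.frame(
    disease_id = seq_len(n_diseases),
    description = sprintf("disease_%03d", seq_len(n_diseases)),
    appeared_part = part_of_disease)
  assoc <- data.frame(id = seq_len(n_sym),
                      disease_id = sym_disease,
                      symptom_id = seq_len(n_sym))
  vocab <- data.frame(part_id = seq_len(parts),
                      label = sprintf("part_%02d", seq_len(parts)))
  part_map <- data.frame(observed_part = seq_len(parts),
                         appeared_part = seq_len(parts))
  knowledge_base(symptoms, diseases, assoc, vocab, vocab, part_map)
}
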