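# In-code fixtures shared across test files.

# Minimal two-part vocabulary tables for hand-built bases.
toy_parts <- function(n) {
  data.frame(part_id = seq_len(n), label = sprintf("part_%02d", seq_len(n)))
}

identity_part_map <- function(n) {
  data.frame(observed_part = seq_len(n), appeared_part = seq_len(n))
}

toy_symptoms <- function(observed_parts) {
  n <- length(observed_parts)
  data.frame(symptom_id = seq_len(n),
             description = sprintf("symptom_%03d", seq_len(n)),
             observed_part = observed_parts)
}

toy_diseases <- function(appeared_parts) {
  n <- length(appeared_parts)
  data.frame(disease_id = seq_len(n),
             description = sprintf("disease_%03d", seq_len(n)),
             appeared_part = appeared_parts)
}

toy_assoc <- function(pairs) {
  data.frame(id = seq_len(nrow(pairs)),
             disease_id = pairs[, 1], symptom_id = pairs[, 2])
}

# 3 symptoms (parts 1,1,2) x 2 diseases (parts 1,2); disease 1 carries
# symptoms 1,2 and disease 2 carries symptom 3.
toy_kb <- function() {
  knowledge_base(
    symptoms = toy_symptoms(c(1, 1, 2)),
    diseases = toy_diseases(c(1, 2)),
    associations = toy_assoc(rbind(c(1, 1), c(1, 2), c(2, 3))),
    observed_parts = toy_parts(2), appeared_parts = toy_parts(2),
    part_map = identity_part_map(2))
}

# The default-scale synthetic base is expensive enough to build once.
default_synth_kb <- local({
  kb <- NULL
  function() {
    if (is.null(kb)) kb <<- generate_kb(synthetic_kb_config(seed = 20260927L))
    kb
  }
})

# Symptoms associated with one disease, in id order.
disease_symptoms <- function(kb, disease_id) {
  sort(kb$associations$symptom_id[kb$associations$disease_id == disease_id])
}
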