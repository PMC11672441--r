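# Small bases engineered to land symptoms on exact relevance coordinates.

test_that("symptom coordinates are normalized disease and part counts", {
  # 10 diseases on 1 part, 12-part vocabulary, symptom 1 in 2 diseases
  kb <- knowledge_base(
    toy_symptoms(rep(1, 2)), toy_diseases(rep(1, 10)),
    toy_assoc(rbind(c(1, 1), c(2, 1))),
    toy_parts(12), toy_parts(12), identity_part_map(12))
  co <- compute_symptom_coords(kb)
  expect_equal(co$x[1], 0.2)
  expect_equal(co$y[1], 1 / 12)
  # symptom 2 is absent from every disease
  expect_equal(c(co$x[2], co$y[2]), c(0, 0))
})

test_that("W1 hits the centroid conventions and the equidistant midpoint", {
  # 2 diseases on 2 parts; symptom 1 in both diseases (x = 1, y = 1),
  # symptom 2 in one disease (x = 0.5, y = 0.5), symptom 3 in none (0, 0)
  kb <- knowledge_base(
    toy_symptoms(c(1, 1, 2)), toy_diseases(c(1, 2)),
    toy_assoc(rbind(c(1, 1), c(2, 1), c(1, 2))),
    toy_parts(2), toy_parts(2), identity_part_map(2))
  q <- query_from_symptoms(kb, c(1, 2, 3))
  w1 <- compute_w1(kb, q)
  expect_equal(w1$w, c(0, 0.5, 1))
  expect_equal(w1$u + .membership2(w1$d_unrelated, w1$d_related, 2),
               rep(1, 3))
})

test_that("W2 penalizes part mismatch with exactly -0.5 and normalizes candidates", {
  kb <- toy_kb()   # disease 1 on part 1, disease 2 on part 2
  q <- query_from_symptoms(kb, 1)   # symptom 1: observed part 1 -> appeared 1
  w2 <- compute_w2(kb, q)
  expect_identical(w2["2", 1], -0.5)   # part-mismatched disease
  expect_equal(w2["1", 1], 1)          # single candidate on the part

  # two candidate diseases on one part: membership from profile distances
  kb2 <- knowledge_base(
    toy_symptoms(rep(1, 4)), toy_diseases(c(1, 1)),
    toy_assoc(rbind(c(1, 1), c(1, 2), c(2, 3), c(2, 4))),
    toy_parts(1), toy_parts(1), identity_part_map(1))
  q2 <- query_from_symptoms(kb2, 1)
  w22 <- compute_w2(kb2, q2)
  # oracle: distances of the one-hot symptom vector to the L1 profiles
  p1 <- c(0.5, 0.5, 0, 0); p2 <- c(0, 0, 0.5, 0.5); e <- c(1, 0, 0, 0)
  d <- c(sqrt(sum((e - p1)^2)), sqrt(sum((e - p2)^2)))
  expect_equal(unname(w22[, 1]), fuzzy_membership(d, 2))
  expect_equal(sum(w22[, 1]), 1)
})

test_that("activation is the mean relevance-scaled connection", {
  mk_act <- function(w1w, w2col) {
    q <- data.frame(observed_part = 1, symptom_id = seq_along(w1w))
    w1 <- data.frame(w = w1w)
    w2 <- matrix(w2col, nrow = 1, dimnames = list("7", NULL))
    activate_diseases(w1, w2, q)
  }
  expect_equal(mk_act(0.8, 1)$activation, 0.8)
  a <- mk_act(c(1, 1), c(1, -0.5))
  expect_equal(a$activation, 0.25)
  expect_true(a$activated)
  b <- mk_act(c(1, 1, 1), c(-0.5, -0.5, -0.5))  # every part mismatched
  expect_equal(b$activation, -0.5)
  expect_false(b$activated)
})

test_that("W3 places the self-point on the target centroid", {
  # diseases 1 and 2 share symptom set {1,2}; disease 3 is disjoint with
  # equal size {3,4}; all on one part
  kb <- knowledge_base(
    toy_symptoms(rep(1, 4)), toy_diseases(c(1, 1, 1)),
    toy_assoc(rbind(c(1, 1), c(1, 2), c(2, 1), c(2, 2), c(3, 3), c(3, 4))),
    toy_parts(1), toy_parts(1), identity_part_map(1))
  act <- data.frame(disease_id = 1:3, activation = c(0.6, 0.3, 0.3),
                    activated = TRUE)
  sc <- refine_w3(kb, act)
  # for target 1: z = 1 at (0,1) u = 1; z = 2 identical set also (0,1)
  # u = 1; z = 3 disjoint equal size at (1,1), equidistant -> u = 0.5
  expect_equal(sc$score[1], (1 * 0.6 + 1 * 0.3 + 0.5 * 0.3) / 3)
  # a single activated disease scores its own activation
  one <- refine_w3(kb, act[2, , drop = FALSE])
  expect_equal(one$score, 0.3)
  # no activation -> empty refinement
  none <- act; none$activated <- FALSE
  expect_identical(nrow(refine_w3(kb, none)), 0L)
})

test_that("the full pipeline recovers targets on disjoint symptom sets", {
  kb <- generate_disjoint_kb(n_diseases = 24, symptoms_per_disease = 5,
                             parts = 12, seed = 1)
  # exhaustive: every disease is top-ranked for its own full query
  for (d in kb$diseases$disease_id) {
    r <- mnfl_infer(kb, query_from_symptoms(kb, disease_symptoms(kb, d)))
    expect_equal(r$disease_id[1], d)
    expect_lte(nrow(r), 5L)
  }
})

test_that("identical symptom sets tie and break by ascending disease id", {
  # diseases 1 and 2 share the identical set {1,2,3}; diseases 3 and 4
  # keep the shared symptoms off the (1,1) "unrelated" centroid
  kb <- knowledge_base(
    toy_symptoms(rep(1, 5)), toy_diseases(c(1, 1, 1, 1)),
    toy_assoc(rbind(c(1, 1), c(1, 2), c(1, 3), c(2, 1), c(2, 2), c(2, 3),
                    c(3, 4), c(4, 5))),
    toy_parts(1), toy_parts(1), identity_part_map(1))
  r <- mnfl_infer(kb, query_from_symptoms(kb, 1:3))
  expect_equal(r$disease_id[1:2], c(1L, 2L))
  expect_equal(r$score[1], r$score[2])
})

test_that("inference is permutation-invariant and deterministic", {
  kb <- default_synth_kb()
  t <- eligible_targets(kb)[3]
  syms <- disease_symptoms(kb, t)[1:5]
  r1 <- mnfl_infer(kb, query_from_symptoms(kb, syms))
  withr::with_seed(99, {
    for (i in 1:3) {
      r2 <- mnfl_infer(kb, query_from_symptoms(kb, sample(syms)))
      expect_equal(as.data.frame(r2), as.data.frame(r1))
    }
  })
  expect_identical(as.data.frame(mnfl_infer(kb, query_from_symptoms(kb, syms))),
                   as.data.frame(r1))
})

test_that("appending a part-mismatched symptom never raises an activation", {
  kb <- default_synth_kb()
  cfg <- fuzzy_config()
  withr::with_seed(7, {
    for (rep in 1:5) {
      t <- sample(eligible_targets(kb), 1)
      ti <- match(t, kb$diseases$disease_id)
      p_t <- kb$diseases$appeared_part[ti]
      syms <- .sample1(disease_symptoms(kb, t), 4)
      # a symptom whose mapped appeared part differs from the target's
      mism <- kb$symptoms$symptom_id[
        kb$derived$part_image[kb$symptoms$observed_part] != p_t]
      extra <- .sample1(setdiff(mism, syms), 1)
      act0 <- activate_diseases(
        compute_w1(kb, q0 <- query_from_symptoms(kb, syms), cfg),
        compute_w2(kb, q0, cfg), q0)
      act1 <- activate_diseases(
        compute_w1(kb, q1 <- query_from_symptoms(kb, c(syms, extra)), cfg),
        compute_w2(kb, q1, cfg), q1)
      expect_lte(act1$activation[ti], act0$activation[ti] + 1e-12)
    }
  })
})

test_that("empty activation yields an empty ranking, not an error", {
  # one disease on part 1; the only query symptom maps to part 2
  kb <- knowledge_base(
    toy_symptoms(2), toy_diseases(1),
    toy_assoc(rbind(c(1, 1))),
    toy_parts(2), toy_parts(2), identity_part_map(2))
  r <- mnfl_infer(kb, query_from_symptoms(kb, 1))
  expect_identical(nrow(r), 0L)
})
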