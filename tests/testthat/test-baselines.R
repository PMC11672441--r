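make_blobs <- function(n_per = 25, sep = 8, sd = 1, seed = 11) {
  withr::with_seed(seed, {
    X <- rbind(cbind(stats::rnorm(n_per, 0, sd), stats::rnorm(n_per, 0, sd)),
               cbind(stats::rnorm(n_per, sep, sd), stats::rnorm(n_per, sep, sd)))
  })
  list(X = X, labels = rep(1:2, each = n_per))
}

partition_agreement <- function(model, labels) {
  hard <- max.col(model$memberships)
  max(mean(hard == labels), mean(hard == 3 - labels))  # label-permutation invariant
}

test_that("fcm recovers planted blobs and handles degenerate inputs", {
  b <- make_blobs()
  fit <- fcm_fit(b$X, 2, fuzzy_config(seed = 5))
  expect_equal(partition_agreement(fit, b$labels), 1)
  expect_equal(rowSums(fit$memberships), rep(1, nrow(b$X)))

  one <- fcm_fit(b$X, 1, fuzzy_config(seed = 5))
  expect_equal(as.numeric(one$memberships), rep(1, nrow(b$X)))
  expect_equal(as.numeric(one$centroids), colMeans(b$X))

  same <- matrix(1, 6, 2)
  deg <- fcm_fit(same, 2, fuzzy_config(seed = 5))
  expect_equal(unname(deg$memberships), matrix(0.5, 6, 2))
  expect_equal(deg$centroids[1, ], deg$centroids[2, ])
})

test_that("objective traces are non-increasing for both clustering engines", {
  withr::with_seed(21, {
    for (rep in 1:10) {
      X <- matrix(stats::rnorm(60 * 3), 60, 3)
      cfg <- fuzzy_config(seed = rep, max_iter = 40)
      for (fit in list(fcm_fit(X, 3, cfg),
                       pfcm_r_fit(X, 3, pfcm_params(), cfg))) {
        tr <- fit$objective_trace
        expect_true(all(diff(tr) <= 1e-9), label = "monotone objective")
      }
    }
  })
})

test_that("pfcm-r reduces to fcm at the parameter limit and matches its partition", {
  b <- make_blobs()
  cfg <- fuzzy_config(seed = 9)
  fcm <- fcm_fit(b$X, 2, cfg)
  lim <- pfcm_r_fit(b$X, 2, pfcm_params(b = 0, lam = 0), cfg)
  expect_equal(lim$memberships, fcm$memberships, tolerance = 1e-4)

  full <- pfcm_r_fit(b$X, 2, pfcm_params(), cfg)
  expect_equal(partition_agreement(full, b$labels),
               partition_agreement(fcm, b$labels))
  expect_true(all(full$typicalities >= 0 & full$typicalities <= 1))
})

test_that("an extreme outlier is atypical of both blob clusters", {
  b <- make_blobs(n_per = 20, sep = 6, sd = 0.5, seed = 3)
  X <- rbind(b$X, c(30, -30))
  fit <- pfcm_r_fit(X, 2, pfcm_params(), fuzzy_config(seed = 1))
  # scenario precondition: the two centroids sit on the blobs, not the outlier
  near <- apply(fit$centroids, 1, function(v)
    min(sum((v - c(0, 0))^2), sum((v - c(6, 6))^2)))
  expect_true(all(near < 4))
  out_typ <- fit$typicalities[nrow(X), ]
  blob_med <- apply(fit$typicalities[-nrow(X), ], 2, stats::median)
  expect_true(all(out_typ < blob_med))
})

test_that("seeded clustering is reproducible", {
  b <- make_blobs()
  f1 <- pfcm_r_fit(b$X, 2, pfcm_params(), fuzzy_config(seed = 17))
  f2 <- pfcm_r_fit(b$X, 2, pfcm_params(), fuzzy_config(seed = 17))
  expect_identical(f1, f2)
})

test_that("pfcmr inference scores prototype proximity", {
  kb <- generate_disjoint_kb(24, 5, 12, seed = 1)
  for (d in c(1L, 7L, 24L)) {
    r <- pfcmr_infer(kb, query_from_symptoms(kb, disease_symptoms(kb, d)))
    expect_equal(r$disease_id[1], d)
  }
  # query matching disease 1's profile strictly better than disease 2's
  q <- query_from_symptoms(kb, c(disease_symptoms(kb, 1)[1:4],
                                 disease_symptoms(kb, 2)[1]))
  r <- pfcmr_infer(kb, q)
  s1 <- r$score[r$disease_id == 1]
  s2 <- r$score[r$disease_id == 2]
  expect_gt(s1, s2)
})

test_that("a query orthogonal to every disease falls back to id order", {
  # symptoms 6,7 belong to no disease
  kb <- knowledge_base(
    toy_symptoms(rep(1, 7)), toy_diseases(rep(1, 5)),
    toy_assoc(cbind(1:5, 1:5)),
    toy_parts(1), toy_parts(1), identity_part_map(1))
  r <- pfcmr_infer(kb, query_from_symptoms(kb, c(6, 7)))
  expect_equal(r$disease_id, 1:5)
  expect_equal(diff(r$score), rep(0, 4))
})

test_that("fhal weight matrices match hand-computed counts", {
  # parts 1,2; diseases: 1 and 2 on part 1 (sizes 2 and 1), 3 on part 2 (size 2)
  kb <- knowledge_base(
    toy_symptoms(c(1, 1, 2, 2)), toy_diseases(c(1, 1, 2)),
    toy_assoc(rbind(c(1, 1), c(1, 2), c(2, 1), c(3, 3), c(3, 4))),
    toy_parts(2), toy_parts(2), identity_part_map(2))
  w <- fhal_train(kb)
  # symptom 1 occurs in diseases 1,2, both on part 1
  expect_equal(unname(w$w1["1", ]), c(1, 0))
  # symptom 3 only in disease 3 on part 2
  expect_equal(unname(w$w1["3", ]), c(0, 1))
  expect_equal(unname(w$w2["1", ]), c(2 / 3, 1 / 3, 0))
  expect_equal(unname(w$w2["2", ]), c(0, 0, 1))
  expect_equal(unname(w$w3[, "1"]), c(0.5, 0.5, 0, 0))
  expect_equal(unname(w$w3[, "2"]), c(1, 0, 0, 0))
  # a symptom absent from every disease has an all-zero w1 row
  kb2 <- knowledge_base(
    toy_symptoms(c(1, 1)), toy_diseases(1),
    toy_assoc(rbind(c(1, 1))),
    toy_parts(1), toy_parts(1), identity_part_map(1))
  expect_equal(unname(fhal_train(kb2)$w1["2", ]), 0)
})

test_that("fhal filters the foreign-part symptom and respects alpha", {
  kb <- generate_disjoint_kb(12, 5, 6, seed = 1)
  w <- fhal_train(kb)
  own <- disease_symptoms(kb, 1)[1:4]
  foreign <- disease_symptoms(kb, 2)[1]   # disease 2 sits on another part
  q <- query_from_symptoms(kb, c(own, foreign))
  W1q <- w$w1[match(q$symptom_id, kb$symptoms$symptom_id), ]
  A <- colSums(W1q)
  pstar <- which.max(A)
  keep <- W1q[, pstar] >= w$tau * A[pstar] / nrow(q)
  expect_equal(unname(keep), c(TRUE, TRUE, TRUE, TRUE, FALSE))

  # with all symptoms from one part's pool nothing is filtered
  q0 <- query_from_symptoms(kb, disease_symptoms(kb, 1))
  W10 <- w$w1[match(q0$symptom_id, kb$symptoms$symptom_id), ]
  A0 <- colSums(W10)
  expect_true(all(W10[, which.max(A0)] >= w$tau * max(A0) / nrow(q0)))

  # alpha = 1 reduces to the pure direct-association ranking
  w_direct <- fhal_train(kb, alpha = 1)
  r <- fhal_infer(kb, w_direct, q)
  direct <- colSums(w_direct$w3[match(q$symptom_id, kb$symptoms$symptom_id), ])
  ord <- order(-direct, kb$diseases$disease_id)[1:5]
  expect_equal(r$disease_id, kb$diseases$disease_id[ord])
})
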