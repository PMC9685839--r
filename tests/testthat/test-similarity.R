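kb <- crc_demo_kb()
query <- crc_demo_query()
ctx32 <- build_context(parse_patient_table(patients_csv_path()))

test_that("self-similarity is 1 and disjoint concepts score 0", {
  a <- formal_concept(c("P2", "P3"), c("Age_M", "Lym_H"))
  expect_equal(concept_similarity(a, a), 1)
  b <- formal_concept("P1", c("Age_H", "Lym_L", "CEA_H"))
  expect_equal(concept_similarity(a, b), 0)
  expect_equal(concept_similarity(a, b, alpha = 0, beta = 1), 0)
})

test_that("the published-excerpt concept pair scores 0.409 at equal weights", {
  # extents disjoint, intents share 9 of 11: 0.5*0 + 0.5*(9/11)
  c39 <- kb[[1]]; c40 <- kb[[3]]
  s <- concept_similarity(c39, c40, alpha = 0.5, beta = 0.5)
  expect_equal(s, 0.5 * 9 / 11)
  expect_equal(round_half_up(s, 3), 0.409)
})

test_that("similarity is symmetric and bounded by alpha + beta", {
  set.seed(5)
  obs <- paste0("o", 1:8); att <- paste0("a", 1:8)
  for (i in 1:40) {
    c1 <- formal_concept(sample(obs, sample(0:5, 1)), sample(att, sample(0:5, 1)))
    c2 <- formal_concept(sample(obs, sample(0:5, 1)), sample(att, sample(0:5, 1)))
    al <- runif(1, 0, 2); be <- runif(1, 0.1, 2)
    s12 <- concept_similarity(c1, c2, al, be)
    expect_equal(s12, concept_similarity(c2, c1, al, be))
    expect_gte(s12, 0)
    expect_lte(s12, al + be + 1e-12)
    same <- setequal(c1$extent, c2$extent) && setequal(c1$intent, c2$intent) &&
      length(c1$extent) > 0 && length(c1$intent) > 0
    if (same) expect_equal(s12, al + be)
  }
})

test_that("invalid weights are rejected", {
  a <- formal_concept("x", "y")
  expect_error(concept_similarity(a, a, alpha = -1, beta = 1),
               class = "fcakb_validation_error")
  expect_error(concept_similarity(a, a, alpha = 0, beta = 0),
               class = "fcakb_validation_error")
})

test_that("queries are concept-shaped with empty extent", {
  q <- query_from_attributes(query, ctx32)
  expect_s3_class(q, "formal_concept")
  expect_length(q$extent, 0)
  expect_length(q$intent, 11)
  q1 <- query_from_attributes("CEA_H", ctx32)
  expect_equal(q1$intent, "CEA_H")
  expect_error(query_from_attributes("NotAnAttr", ctx32), class = "fcakb_lookup_error")
  expect_error(query_from_attributes(character(0), ctx32),
               class = "fcakb_validation_error")
  # spelling variants normalize
  expect_equal(query_from_attributes(c("ca199_L", "Ly_N"), ctx32)$intent,
               c("Ca199_L", "Lv_N"))
})

test_that("retrieval reproduces the published top-10 score sequence", {
  res <- retrieve_similar(kb, query, alpha = 0, beta = 1, top_k = 10)
  expect_equal(res$score,
               c(1.000, 0.818, 0.818, 0.727, 0.727, 0.636, 0.636, 0.636, 0.636, 0.545))
  expect_equal(res$rank, 1:10)
  expect_equal(res$concept_id[1], "C31739")
  expect_equal(res$score_exact[1], 1)
  # the exact-intent match shares everything and distinguishes nothing
  expect_setequal(strsplit(res$shared_attributes[1], ", ")[[1]], query)
  expect_equal(res$distinguishing_attributes[1], "")
})

test_that("ties break by extent size then id, and top_k truncates", {
  res <- retrieve_similar(kb, query, top_k = 10)
  sixes <- res[abs(res$score_exact - 6 / 11) < 1e-9, ]
  expect_equal(sixes$n_objects, sort(sixes$n_objects, decreasing = TRUE))
  one <- retrieve_similar(kb, query, top_k = 1)
  expect_equal(nrow(one), 1)
  expect_equal(one$score, 1.000)
  expect_error(retrieve_similar(kb, query, top_k = 0), class = "fcakb_validation_error")
})

test_that("retrieval is a permutation with consecutive ranks", {
  res <- retrieve_similar(kb, query, top_k = 100)
  expect_equal(nrow(res), length(kb))
  expect_equal(res$rank, seq_len(nrow(res)))
  expect_equal(sort(res$concept_id), sort(vapply(kb, `[[`, "", "id")))
})

test_that("empty-extent concepts are excluded by default but restorable", {
  lat <- concept_lattice(formal_context(rbind(g1 = c(1, 0), g2 = c(0, 1)),
                                        attributes = c("a", "b")))
  # bottom concept has empty extent and full intent
  res <- retrieve_similar(lat, "a", top_k = 10)
  expect_false(any(res$n_objects == 0))
  res2 <- retrieve_similar(lat, "a", top_k = 10, include_empty_extent = TRUE)
  expect_true(any(res2$n_objects == 0))
})

test_that("adding a concept-intent attribute to the query never shrinks the overlap", {
  co <- kb[[4]]
  q1 <- c("Age_L", "T2")
  q2 <- c(q1, "Lym_H")  # in co's intent
  n1 <- length(intersect(co$intent, q1))
  n2 <- length(intersect(co$intent, q2))
  expect_gte(n2, n1)
})

test_that("predict() routes raw records through the coding scheme", {
  df <- parse_patient_table(patients_csv_path())
  lat <- concept_lattice(build_context(df))
  res <- predict(lat, df[2, ], top_k = 3)
  expect_s3_class(res, "fcakb_retrieval")
  expect_equal(res$score[1], 1)      # the patient's own full-intent concept
  many <- predict(lat, df[1:2, ], top_k = 2)
  expect_length(many, 2)
  expect_named(many, c("p1", "p2"))
})
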