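test_that("generate_training_patients honours the degenerate and seeded contracts", {
  w <- toy_world(37, n_terms = 50, n_diseases = 6)
  ids <- kb_disease_ids(w$kb)

  # degenerate generator: no dropout, no noise -> exact annotation sets
  pats <- generate_training_patients(w$kb, per_disease = 1, dropout = 0,
                                     noise_rate = 0, seed = 3)
  expect_length(pats, length(ids))
  for (p in pats) {
    expect_setequal(p$phenotypes, kb_disease_terms(w$kb, p$true_disease))
  }

  # count contract: per_disease x diseases
  pats10 <- generate_training_patients(w$kb, per_disease = 10, seed = 3)
  expect_length(pats10, 10L * length(ids))

  # seeding: same seed identical, different seeds differ
  a <- generate_training_patients(w$kb, per_disease = 3, seed = 11)
  b <- generate_training_patients(w$kb, per_disease = 3, seed = 11)
  c <- generate_training_patients(w$kb, per_disease = 3, seed = 12)
  expect_identical(a, b)
  expect_false(identical(a, c))

  # no empty patients even under heavy dropout
  h <- generate_training_patients(w$kb, per_disease = 20, dropout = 0.95,
                                  noise_rate = 0, seed = 5)
  expect_true(all(lengths(lapply(h, `[[`, "phenotypes")) >= 1L))

  expect_error(generate_training_patients(w$kb, dropout = 1), "dropout")
  expect_error(generate_training_patients(w$kb, noise_rate = -1), "noise")
})

test_that("build_features rows equal query vectors over the vocabulary", {
  w <- toy_world(41, n_terms = 50, n_diseases = 6)
  ids <- kb_disease_ids(w$kb)

  # exact-annotation patient reproduces the disease's weight row
  pats <- generate_training_patients(w$kb, per_disease = 1, dropout = 0,
                                     noise_rate = 0, seed = 1)
  fm <- build_features(pats, w$graph, w$ic, w$wm$vocabulary)
  expect_equal(dim(fm$X), c(length(ids), length(w$wm$vocabulary)))
  for (i in seq_along(ids)) {
    expect_equal(unname(fm$X[i, ]),
                 unname(disease_vector(w$kb, fm$labels[i], w$wm)),
                 tolerance = 1e-12)
  }

  # duplicate terms produce the same row as the deduplicated record
  p1 <- patient_record("p1", rep(kb_disease_terms(w$kb, ids[1]), 2),
                       ids[1], "emr")
  p2 <- patient_record("p2", kb_disease_terms(w$kb, ids[1]), ids[1], "emr")
  fm2 <- build_features(list(p1, p2), w$graph, w$ic, w$wm$vocabulary)
  expect_equal(unname(fm2$X[1, ]), unname(fm2$X[2, ]))

  # unresolvable-only patient is dropped with a warning
  p3 <- patient_record("p3", "NO:1", ids[1], "emr")
  expect_warning(fm3 <- build_features(list(p1, p3), w$graph, w$ic,
                                       w$wm$vocabulary), "dropped")
  expect_equal(nrow(fm3$X), 1L)
})

test_that("train_ensemble weights members by validation accuracy", {
  # separable toy: disjoint annotation sets, no noise
  spec <- synthetic_spec(n_terms = 80, depth = 5, branching = 3,
                         n_diseases = 5, terms_per_disease = c(4L, 4L),
                         seed = 43)
  onto <- make_toy_ontology(spec)
  kb <- make_toy_kb(onto$graph, spec, disjoint_support = TRUE)
  ic <- compute_ic(onto$graph, kb)
  wm <- tfidf_hierarchy_weights(onto$graph, kb, ic)
  pats <- generate_training_patients(kb, per_disease = 6, dropout = 0,
                                     noise_rate = 0, seed = 2)
  fm <- build_features(pats, onto$graph, ic, wm$vocabulary)

  # single spec, no validation -> weight 1
  e1 <- train_ensemble(fm, list(classifier_spec("naive_bayes", seed = 1)),
                       validation_fraction = 0, seed = 9)
  expect_equal(e1$weights, 1)

  # separable data: every member validates at accuracy 1, weights uniform
  specs <- default_classifier_specs(9, c("naive_bayes", "knn",
                                         "logistic_regression"))
  e3 <- train_ensemble(fm, specs, validation_fraction = 0.2, seed = 9)
  expect_equal(unname(e3$validation_accuracy), rep(1, 3))
  expect_equal(unname(e3$weights), rep(1 / 3, 3))

  # distribution contract on every member and the combined ranking
  q <- kb_disease_terms(kb, kb_disease_ids(kb)[3])
  r <- rank_ml(q, e3, onto$graph, ic)
  expect_equal(sum(r$items$score), 1, tolerance = 1e-9)
  expect_true(all(r$items$score >= 0))
  expect_equal(r$items$disease_id[1], kb_disease_ids(kb)[3])

  expect_error(train_ensemble(fm, list()), "at least one")
  # every label needs >= 2 rows under validation
  fm1 <- build_features(generate_training_patients(kb, per_disease = 1,
                                                   dropout = 0, noise_rate = 0,
                                                   seed = 2),
                        onto$graph, ic, wm$vocabulary)
  expect_error(train_ensemble(fm1, specs, validation_fraction = 0.2),
               ">= 2 rows")
})

test_that("all six backends satisfy the distribution contract", {
  spec <- synthetic_spec(n_terms = 60, depth = 4, branching = 3,
                         n_diseases = 4, terms_per_disease = c(3L, 3L),
                         seed = 47)
  onto <- make_toy_ontology(spec)
  kb <- make_toy_kb(onto$graph, spec, disjoint_support = TRUE)
  ic <- compute_ic(onto$graph, kb)
  wm <- tfidf_hierarchy_weights(onto$graph, kb, ic)
  pats <- generate_training_patients(kb, per_disease = 5, dropout = 0.1,
                                     noise_rate = 1, seed = 4)
  fm <- build_features(pats, onto$graph, ic, wm$vocabulary)
  specs <- default_classifier_specs(21)   # all six algorithms
  hp <- list(ntree = 15L, epochs = 40L)
  specs <- lapply(specs, function(s) {
    s$hyperparameters <- hp; s
  })
  ens <- train_ensemble(fm, specs, validation_fraction = 0.2, seed = 21)
  expect_length(ens$members, 6L)
  X <- fm$X[1:3, , drop = FALSE]
  for (m in ens$members) {
    P <- phenodx:::predict_member(m, X)
    expect_true(all(P >= 0))
    expect_equal(unname(rowSums(P)), rep(1, 3), tolerance = 1e-9)
    expect_equal(colnames(P), ens$label_set)
  }
})

test_that("rank_ml reduces to a single member and reproduces bit-identically", {
  w <- toy_world(53, n_terms = 60, n_diseases = 6)
  pats <- generate_training_patients(w$kb, per_disease = 4, dropout = 0.1,
                                     noise_rate = 1, seed = 6)
  fm <- build_features(pats, w$graph, w$ic, w$wm$vocabulary)
  q <- kb_disease_terms(w$kb, kb_disease_ids(w$kb)[2])

  # single member: ranking identical to that member's distribution
  e1 <- train_ensemble(fm, list(classifier_spec("naive_bayes", seed = 3)),
                       validation_fraction = 0, seed = 3)
  r1 <- rank_ml(q, e1, w$graph, w$ic)
  v <- query_vector(q, w$graph, w$ic, w$wm$vocabulary)
  P <- phenodx:::predict_member(e1$members[[1]],
                                matrix(as.numeric(v), 1,
                                       dimnames = list(NULL, w$wm$vocabulary)))
  expect_equal(r1$items$score,
               unname(sort(P[1, ], decreasing = TRUE)), tolerance = 1e-12)

  # reproducibility: identical seeds/specs/data -> identical rankings
  specs <- default_classifier_specs(8, c("naive_bayes", "knn"))
  ea <- train_ensemble(fm, specs, validation_fraction = 0.2, seed = 8)
  eb <- train_ensemble(fm, specs, validation_fraction = 0.2, seed = 8)
  expect_identical(rank_ml(q, ea, w$graph, w$ic),
                   rank_ml(q, eb, w$graph, w$ic))

  # two members with identical distributions combine to the same
  e2 <- train_ensemble(fm, list(classifier_spec("naive_bayes", seed = 3),
                                classifier_spec("naive_bayes", seed = 3)),
                       validation_fraction = 0, seed = 3)
  expect_equal(rank_ml(q, e2, w$graph, w$ic)$items,
               r1$items, tolerance = 1e-12)

  # batch ranking agrees with per-record ranking
  qs <- lapply(kb_disease_ids(w$kb)[1:3],
               function(d) kb_disease_terms(w$kb, d))
  rb <- rank_ml_batch(qs, ea, w$graph, w$ic)
  for (i in 1:3) {
    expect_equal(rb[[i]]$items, rank_ml(qs[[i]], ea, w$graph, w$ic)$items,
                 tolerance = 1e-12)
  }
})

test_that("APML equals CPML when the text-mined layer is empty", {
  spec <- synthetic_spec(n_terms = 60, n_diseases = 6,
                         terms_per_disease = c(3L, 5L), seed = 59)
  onto <- make_toy_ontology(spec)
  cur <- make_toy_kb(onto$graph, spec)   # no text-mined layer
  rows <- do.call(rbind, lapply(kb_disease_ids(cur), function(d) {
    data.frame(disease_id = d, name = cur$diseases[[d]]$name,
               term = kb_disease_terms(cur, d))
  }))
  kb_c <- build_kb(rows, mode = "curated_only")
  kb_a <- build_kb(rows, text_mined = rows[0, ],
                   mode = "curated_plus_textmined")
  run <- function(kb, model) {
    ic <- compute_ic(onto$graph, kb)
    wm <- tfidf_hierarchy_weights(onto$graph, kb, ic)
    pats <- generate_training_patients(kb, per_disease = 4, dropout = 0.1,
                                       noise_rate = 1, seed = 7)
    fm <- build_features(pats, onto$graph, ic, wm$vocabulary)
    ens <- train_ensemble(fm, default_classifier_specs(7, c("naive_bayes", "knn")),
                          validation_fraction = 0.2, seed = 7, model = model)
    rank_ml(kb_disease_terms(kb, kb_disease_ids(kb)[1]), ens, onto$graph, ic)
  }
  rc <- run(kb_c, "CPML"); ra <- run(kb_a, "APML")
  expect_equal(rc$items, ra$items, tolerance = 1e-12)
})

test_that("ensembles persist and reload", {
  w <- toy_world(61, n_terms = 50, n_diseases = 5)
  pats <- generate_training_patients(w$kb, per_disease = 3, seed = 2)
  fm <- build_features(pats, w$graph, w$ic, w$wm$vocabulary)
  ens <- train_ensemble(fm, list(classifier_spec("naive_bayes", seed = 1)),
                        validation_fraction = 0, seed = 2)
  dir <- withr::local_tempdir()
  save_ensemble(ens, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  ens2 <- load_ensemble(dir)
  q <- kb_disease_terms(w$kb, kb_disease_ids(w$kb)[1])
  expect_identical(rank_ml(q, ens, w$graph, w$ic),
                   rank_ml(q, ens2, w$graph, w$ic))
})
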