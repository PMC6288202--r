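test_that("vector similarities match hand values and the naive oracle", {
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_equal(cosine_similarity(c(0, 0), c(1, 1)), 0)

  expect_equal(tanimoto(c(2, 3), c(2, 3)), 1)
  expect_equal(tanimoto(c(1, 0), c(0, 1)), 0)
  expect_equal(tanimoto(c(1, 1, 0), c(1, 0, 1)), 1 / 3)
  expect_equal(tanimoto(c(0, 0), c(0, 0)), 0)

  set.seed(99)
  for (i in 1:200) {
    a <- rbinom(20, 1, 0.3) * runif(20, 0, 3)
    b <- rbinom(20, 1, 0.3) * runif(20, 0, 3)
    expect_equal(cosine_similarity(a, b), oracle_cosine(a, b),
                 tolerance = 1e-9)
    expect_equal(tanimoto(a, b), oracle_tanimoto(a, b), tolerance = 1e-9)
  }
})

test_that("psi score counts the symmetric difference and clamps", {
  expect_equal(psi_score(c("a", "b"), c("a", "b")), 1)
  expect_equal(psi_score(c("a", "b", "c"), c("a", "b", "c", "d")), 0.75)
  # disjoint size-3 sets: raw 1 - 6/3 = -1, clamped to 0
  expect_equal(psi_score(c("a", "b", "c"), c("x", "y", "z")), 0)
  expect_error(psi_score(character(0), "a"), "non-empty")

  set.seed(7)
  pool <- letters
  for (i in 1:200) {
    q <- sample(pool, sample(1:8, 1)); d <- sample(pool, sample(1:8, 1))
    expect_equal(psi_score(q, d), oracle_psi(q, d), tolerance = 1e-12)
  }
})

test_that("MICA set similarity matches the brute-force oracle", {
  d <- make_diamond()
  ic <- compute_ic(d, make_diamond_kb())

  expect_equal(mica_similarity_directed("T:4", "T:4", d, ic),
               unname(ic$ic[["T:4"]]))
  # disjoint root subtrees: all MICAs are the root
  expect_equal(mica_similarity_directed("T:5", "T:3", d, ic), 0)
  expect_error(mica_similarity_directed(character(0), "T:4", d, ic))

  # toy diamond, brute-force over all pairs
  a <- c("T:4", "T:5"); b <- c("T:3", "T:5")
  expect_equal(mica_similarity_directed(a, b, d, ic),
               oracle_directed(a, b, d, ic), tolerance = 1e-12)
  expect_equal(mica_similarity_symmetric(a, b, d, ic),
               0.5 * oracle_directed(a, b, d, ic) +
               0.5 * oracle_directed(b, a, d, ic), tolerance = 1e-12)
  expect_equal(mica_similarity_symmetric(a, a, d, ic),
               mean(ic$ic[a]), tolerance = 1e-12)

  # symmetry on random sets over a random world
  w <- toy_world(17)
  set.seed(17)
  for (i in 1:20) {
    s1 <- sample(w$graph$terms, 4); s2 <- sample(w$graph$terms, 3)
    expect_equal(mica_similarity_symmetric(s1, s2, w$graph, w$ic),
                 mica_similarity_symmetric(s2, s1, w$graph, w$ic),
                 tolerance = 1e-12)
    expect_equal(mica_similarity_directed(s1, s2, w$graph, w$ic),
                 oracle_directed(s1, s2, w$graph, w$ic), tolerance = 1e-9)
  }
})

test_that("gene-space similarities match hand values", {
  d <- make_diamond()
  gm <- read_gene_associations(c("T:4\tG1", "T:4\tG2",
                                 "T:5\tG2", "T:5\tG3",
                                 "T:3\tG9"), d)
  expect_equal(pgas_phenotype_similarity("T:4", "T:4", gm, "cosine"), 1)
  expect_equal(pgas_phenotype_similarity("T:4", "T:3", gm, "cosine"), 0)
  expect_equal(pgas_phenotype_similarity("T:4", "T:5", gm, "cosine"), 0.5)
  expect_equal(pgas_phenotype_similarity("T:4", "T:5", gm, "tanimoto"), 1 / 3)
  # absent term -> zero vector
  expect_equal(pgas_phenotype_similarity("T:1", "T:4", gm, "cosine"), 0)

  # disease score: best match is self when sets coincide
  expect_equal(pgas_disease_score(c("T:4", "T:5"), c("T:4", "T:5"), gm,
                                  "cosine"), 1)
  expect_equal(pgas_disease_score("T:4", "T:3", gm, "cosine"), 0)
  # hand-average: q={T:4}, d={T:5,T:3}; row maxima (0.5), column maxima
  # (0.5, 0) -> 0.5*0.5 + 0.5*0.25
  expect_equal(pgas_disease_score("T:4", c("T:5", "T:3"), gm, "cosine"),
               0.375)
  expect_equal(pgas_disease_score(c("T:4", "T:5"), c("T:5", "T:3"), gm,
                                  "tanimoto"),
               oracle_pgas_score(c("T:4", "T:5"), c("T:5", "T:3"), gm,
                                 "tanimoto"), tolerance = 1e-12)
})

test_that("ranked_result orders by score with lexicographic ties", {
  r <- ranked_result(c("DX:2", "DX:1", "DX:3"), c(0.5, 0.5, 0.9))
  expect_equal(r$items$disease_id, c("DX:3", "DX:1", "DX:2"))
  expect_equal(r$items$rank, 1:3)
  expect_error(ranked_result(c("DX:1", "DX:1"), c(1, 2)), "duplicate")
  expect_equal(truth_rank(r, "DX:1"), 2L)
  expect_true(is.na(truth_rank(r, "DX:9")))
})

test_that("rank_pics retrieves the annotating disease and is stable", {
  w <- toy_world(23, n_terms = 60, n_diseases = 10)
  ids <- kb_disease_ids(w$kb)

  # exact-annotation queries on pairwise-distinct sets retrieve the disease
  sets <- lapply(ids, function(d) kb_disease_terms(w$kb, d))
  distinct <- !duplicated(vapply(sets, paste, "", collapse = "|"))
  for (i in which(distinct)[1:5]) {
    r <- rank_pics(sets[[i]], w$kb, w$graph, w$ic, w$wm)
    expect_equal(r$items$disease_id[1], ids[i])
  }

  # all four classifier components stay in [0, 1]: combined scores are a
  # convex mix of normalized members, so the combined vector is a
  # distribution
  r <- rank_pics(sets[[1]], w$kb, w$graph, w$ic, w$wm)
  expect_true(all(r$items$score >= 0))
  expect_equal(sum(r$items$score), 1, tolerance = 1e-9)

  # single-disease KB: that disease ranks first for any query
  kb1 <- build_kb(data.frame(disease_id = "DX:1", name = "only",
                             term = sets[[2]][1]))
  ic1 <- compute_ic(w$graph, kb1)
  wm1 <- tfidf_hierarchy_weights(w$graph, kb1, ic1)
  r1 <- rank_pics(sets[[3]], kb1, w$graph, ic1, wm1)
  expect_equal(r1$items$disease_id, "DX:1")

  # identical annotations tie, broken lexicographically
  kb2 <- build_kb(data.frame(disease_id = rep(c("DX:b", "DX:a"), each = 2),
                             name = "twin",
                             term = rep(sets[[1]][1:2], 2)))
  ic2 <- compute_ic(w$graph, kb2)
  wm2 <- tfidf_hierarchy_weights(w$graph, kb2, ic2)
  r2 <- rank_pics(sets[[1]][1:2], kb2, w$graph, ic2, wm2)
  expect_equal(r2$items$disease_id, c("DX:a", "DX:b"))

  # unresolvable query terms are dropped with a warning
  expect_warning(rank_pics(c(sets[[1]], "NO:1"), w$kb, w$graph, w$ic, w$wm),
                 "dropped")
})

test_that("rank_pgas retrieves the annotating disease", {
  w <- toy_world(29, n_terms = 60, n_diseases = 10)
  spec <- w$spec
  gm <- make_gene_map(w$graph, spec)
  ids <- kb_disease_ids(w$kb)
  hits <- 0L
  for (d in ids) {
    r <- rank_pgas(kb_disease_terms(w$kb, d), w$kb, gm)
    hits <- hits + (r$items$disease_id[1] == d)
  }
  expect_equal(hits, length(ids))

  kb1 <- build_kb(data.frame(disease_id = "DX:1", name = "only",
                             term = kb_disease_terms(w$kb, ids[1])[1]))
  r1 <- rank_pgas(kb_disease_terms(w$kb, ids[2]), kb1, gm)
  expect_equal(r1$items$disease_id, "DX:1")

  # terms with no gene mapping raise a warning but still rank
  gm0 <- gm; gm0$genes_of[["XX"]] <- NULL
  expect_warning(rank_pgas(c("ZZ:404"), w$kb, gm), "no gene mapping")
})

test_that("rankings are invariant to candidate input order", {
  w <- toy_world(31, n_terms = 50, n_diseases = 8)
  ids <- kb_disease_ids(w$kb)
  q <- kb_disease_terms(w$kb, ids[2])
  r1 <- rank_pics(q, w$kb, w$graph, w$ic, w$wm)

  # rebuild the KB from shuffled annotation rows
  rows <- do.call(rbind, lapply(ids, function(d) {
    data.frame(disease_id = d, name = w$kb$diseases[[d]]$name,
               term = kb_disease_terms(w$kb, d))
  }))
  set.seed(1); rows <- rows[sample(nrow(rows)), ]
  kb2 <- build_kb(rows)
  ic2 <- compute_ic(w$graph, kb2)
  wm2 <- tfidf_hierarchy_weights(w$graph, kb2, ic2)
  r2 <- rank_pics(q, kb2, w$graph, ic2, wm2)
  expect_equal(r1$items, r2$items, tolerance = 1e-12)
})
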