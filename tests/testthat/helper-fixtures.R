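# Shared toy fixtures and independent brute-force oracles. Oracles are
# deliberately naive (loops, path enumeration) and never reuse the code
# paths they check.

# diamond: T:4 under both T:2 and T:3, which sit under root T:1;
# T:5 is a second child of T:2; T:9 is an alt_id of T:2
diamond_obo <- c(
  "[Term]", "id: T:1", "name: root", "",
  "[Term]", "id: T:2", "name: left", "alt_id: T:9", "is_a: T:1", "",
  "[Term]", "id: T:3", "name: right", "is_a: T:1", "",
  "[Term]", "id: T:4", "name: bottom", "is_a: T:2", "is_a: T:3", "",
  "[Term]", "id: T:5", "name: leaf", "is_a: T:2", "")

make_diamond <- function() parse_obo(diamond_obo)

# four diseases over the diamond; annotations chosen so term frequencies
# differ (T:4 rare, T:2 common)
diamond_annotations <- function() {
  data.frame(
    disease_id = c("DX:1", "DX:1", "DX:2", "DX:3", "DX:4"),
    name = "toy",
    term = c("T:4", "T:5", "T:5", "T:2", "T:3"),
    stringsAsFactors = FALSE)
}

make_diamond_kb <- function() build_kb(diamond_annotations())

# small random world shared by similarity property tests
toy_world <- function(seed = 42, n_terms = 50, n_diseases = 8) {
  spec <- synthetic_spec(n_terms = n_terms, depth = 5, branching = 3,
                         n_diseases = n_diseases,
                         terms_per_disease = c(3L, 6L), seed = seed)
  onto <- make_toy_ontology(spec)
  kb <- make_toy_kb(onto$graph, spec)
  ic <- compute_ic(onto$graph, kb)
  list(spec = spec, graph = onto$graph, obo = onto$obo, kb = kb, ic = ic,
       wm = tfidf_hierarchy_weights(onto$graph, kb, ic))
}

# --- oracles -------------------------------------------------------------

oracle_cosine <- function(a, b) {
  dot <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    dot <- dot + a[i] * b[i]; na <- na + a[i]^2; nb <- nb + b[i]^2
  }
  if (na == 0 || nb == 0) 0 else dot / (sqrt(na) * sqrt(nb))
}

oracle_tanimoto <- function(a, b) {
  dot <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    dot <- dot + a[i] * b[i]; na <- na + a[i]^2; nb <- nb + b[i]^2
  }
  if (na + nb - dot == 0) 0 else dot / (na + nb - dot)
}

oracle_psi <- function(q, d) {
  q <- unique(q); d <- unique(d)
  n <- 0
  for (t in union(q, d)) if (xor(t %in% q, t %in% d)) n <- n + 1
  max(min(1 - n / max(length(q), length(d)), 1), 0)
}

# ancestor closure by exhaustive path enumeration toward the roots
oracle_ancestors <- function(graph, term, include_self = FALSE) {
  out <- character(0)
  walk <- function(t) {
    for (p in graph$parents[[t]]) {
      out <<- c(out, p)
      walk(p)
    }
  }
  walk(term)
  res <- unique(out)
  if (include_self) res <- unique(c(term, res))
  sort(res, method = "radix")
}

oracle_mica_ic <- function(graph, ic, t1, t2) {
  common <- intersect(oracle_ancestors(graph, t1, TRUE),
                      oracle_ancestors(graph, t2, TRUE))
  if (!length(common)) 0 else max(ic$ic[common])
}

oracle_directed <- function(from_set, to_set, graph, ic) {
  vals <- numeric(0)
  for (t in unique(from_set)) {
    best <- -Inf
    for (s in unique(to_set)) {
      best <- max(best, oracle_mica_ic(graph, ic, t, s))
    }
    vals <- c(vals, best)
  }
  mean(vals)
}

oracle_pgas_pair <- function(p1, p2, gm, metric) {
  g1 <- gm$genes_of[[p1]]; g2 <- gm$genes_of[[p2]]
  if (is.null(g1)) g1 <- character(0)
  if (is.null(g2)) g2 <- character(0)
  genes <- union(g1, g2)
  a <- as.numeric(genes %in% g1); b <- as.numeric(genes %in% g2)
  if (metric == "cosine") oracle_cosine(a, b) else oracle_tanimoto(a, b)
}

oracle_pgas_score <- function(q, d, gm, metric) {
  sims <- outer(q, d, Vectorize(function(x, y) oracle_pgas_pair(x, y, gm, metric)))
  0.5 * mean(apply(sims, 1, max)) + 0.5 * mean(apply(sims, 2, max))
}

# naive per-record top-k evaluation loop
oracle_topk <- function(results, truths, k) {
  tp <- fp <- fn <- 0
  for (i in seq_along(results)) {
    items <- results[[i]]$items
    if (nrow(items) == 0 || max(items$score) <= 0) { fn <- fn + 1; next }
    hit <- FALSE
    for (j in seq_len(min(k, nrow(items)))) {
      if (items$disease_id[j] == truths[i]) hit <- TRUE
    }
    if (hit) tp <- tp + 1 else fp <- fp + 1
  }
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  list(tp = tp, fp = fp, fn = fn, precision = p, recall = r,
       f1 = if (p + r > 0) 2 * p * r / (p + r) else 0)
}

# a ranking object built directly from ids/scores, bypassing the models
fake_ranking <- function(ids, scores, model = "PICS") {
  ranked_result(ids, scores, model = model)
}
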