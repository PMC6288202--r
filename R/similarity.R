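# Similarity models: vector/set scorers and the PICS / PGAS rankers.

#' Cosine and Tanimoto similarity of weighted vectors
#'
#' Both operate on non-negative vectors over a shared vocabulary. Cosine
#' is the dot product over the norm product and lies in \[0,1\] for
#' non-negative input; Tanimoto is the continuous extension of the Jaccard
#' index, `a.b / (|a|^2 + |b|^2 - a.b)`. Zero vectors score 0.
#'
#' @param a,b numeric vectors of equal length
#' @return similarity in \[0,1\]
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' @rdname cosine_similarity
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  dot <- sum(a * b)
  den <- sum(a * a) + sum(b * b) - dot
  if (den == 0) return(0)
  dot / den
}

#' Set-mismatch score (Psi)
#'
#' `Psi = 1 - n / max(|query|, |disease|)` where n is the size of the
#' symmetric difference between the query phenotype set and the disease's
#' annotation set. The raw value can go negative for very dissimilar sets
#' and is clamped to \[0,1\] so all classifier scores stay commensurable
#' for averaging.
#'
#' @param query,disease_terms non-empty character vectors of term ids
#' @return score in \[0,1\]
#' @export
psi_score <- function(query, disease_terms) {
  q <- unique(query); d <- unique(disease_terms)
  if (!length(q) || !length(d)) stop_input("psi_score requires non-empty sets")
  n <- length(setdiff(q, d)) + length(setdiff(d, q))
  raw <- 1 - n / max(length(q), length(d))
  min(max(raw, 0), 1)
}

#' Directed and symmetric MICA set similarity
#'
#' The directed form averages, over every term of `from_set`, the best
#' (maximum) IC of the most informative common ancestor against the terms
#' of `to_set`. The symmetric form is the mean of the two directions and
#' is the one used for ranking; it is orientation-proof.
#'
#' @param from_set,to_set,a,b non-empty character vectors of term ids
#' @param graph a `phenodx_ontology`
#' @param ic a `phenodx_ic`
#' @return non-negative similarity (nats; normalize by `ic$max_ic` for a
#'   \[0,1\] score)
#' @export
mica_similarity_directed <- function(from_set, to_set, graph, ic) {
  f <- unique(resolve_terms(graph, from_set, error = TRUE))
  t <- unique(resolve_terms(graph, to_set, error = TRUE))
  if (!length(f) || !length(t)) stop_input("empty term set")
  mean(vapply(f, function(x) max(mica_ic_row(graph, ic, x, t)), 0))
}

#' @rdname mica_similarity_directed
#' @export
mica_similarity_symmetric <- function(a, b, graph, ic) {
  0.5 * mica_similarity_directed(a, b, graph, ic) +
    0.5 * mica_similarity_directed(b, a, graph, ic)
}

#' Gene-space phenotype similarity
#'
#' Two phenotype terms are compared through their binary gene-incidence
#' vectors: a term's vector has a 1 for every gene associated with it.
#' Terms absent from the gene map contribute zero vectors and score 0.
#'
#' @param p1,p2 term ids
#' @param gm a `phenodx_genemap`
#' @param metric `"cosine"` or `"tanimoto"`
#' @return similarity in \[0,1\]
#' @export
pgas_phenotype_similarity <- function(p1, p2, gm,
                                      metric = c("cosine", "tanimoto")) {
  metric <- match.arg(metric)
  g1 <- gm$genes_of[[p1]] %||% character(0)
  g2 <- gm$genes_of[[p2]] %||% character(0)
  n1 <- length(g1); n2 <- length(g2)
  inter <- length(intersect(g1, g2))
  if (metric == "cosine") {
    if (n1 == 0 || n2 == 0) return(0)
    inter / sqrt(n1 * n2)
  } else {
    den <- n1 + n2 - inter
    if (den == 0) return(0)
    inter / den
  }
}

#' Gene-space disease score
#'
#' Symmetric best-match average between a query phenotype set and a
#' disease's phenotype set, where the per-pair similarity is
#' [pgas_phenotype_similarity()] (the gene-vector analogue of IC(MICA) in
#' the directed set similarity).
#'
#' @param query,disease_terms non-empty character vectors of term ids
#' @inheritParams pgas_phenotype_similarity
#' @return score in \[0,1\]
#' @export
pgas_disease_score <- function(query, disease_terms, gm,
                               metric = c("cosine", "tanimoto")) {
  metric <- match.arg(metric)
  q <- unique(query); d <- unique(disease_terms)
  if (!length(q) || !length(d)) stop_input("empty term set")
  sim <- outer(q, d, Vectorize(function(x, y)
    pgas_phenotype_similarity(x, y, gm, metric)))
  0.5 * mean(apply(sim, 1, max)) + 0.5 * mean(apply(sim, 2, max))
}

# --- RankedResult --------------------------------------------------------

#' Construct a ranked candidate-disease result
#'
#' Candidates are sorted by descending score; ties break on the
#' lexicographically smallest disease id so results are bit-reproducible.
#'
#' @param ids character vector of candidate disease ids (no duplicates)
#' @param scores numeric scores, same length
#' @param query_terms the query term list
#' @param model one of `"PICS"`, `"PGAS"`, `"CPML"`, `"APML"`
#' @return object of class `phenodx_ranking` with a data.frame `items`
#'   (`rank`, `disease_id`, `score`)
#' @export
ranked_result <- function(ids, scores, query_terms = character(0),
                          model = c("PICS", "PGAS", "CPML", "APML")) {
  model <- match.arg(model)
  if (anyDuplicated(ids)) stop_input("duplicate candidate disease id")
  o <- order_ranked(ids, scores)
  items <- data.frame(rank = seq_along(ids), disease_id = ids[o],
                      score = unname(scores[o]), stringsAsFactors = FALSE)
  structure(list(items = items, query_terms = query_terms, model = model),
            class = "phenodx_ranking")
}

#' @export
print.phenodx_ranking <- function(x, n = 10, ...) {
  cat(sprintf("%s ranking over %d candidates (query: %d terms)\n",
              x$model, nrow(x$items), length(x$query_terms)))
  print(utils::head(x$items, n), row.names = FALSE)
  invisible(x)
}

#' Rank of the true disease inside a result (NA if absent)
#' @param result a `phenodx_ranking`
#' @param disease_id disease to look up
#' @export
truth_rank <- function(result, disease_id) {
  i <- match(disease_id, result$items$disease_id)
  if (is.na(i)) NA_integer_ else result$items$rank[i]
}

# --- PICS ----------------------------------------------------------------

#' Rank candidate diseases with the phenotype-similarity (PICS) model
#'
#' Scores every knowledge-base disease with four classifiers -- cosine and
#' Tanimoto similarity on TF-IDF-Hierarchy weighted vectors, the Psi
#' set-mismatch score, and symmetric MICA set similarity (normalized by
#' the maximum vocabulary IC) -- then combines the four score vectors by
#' Bayesian averaging and sorts.
#'
#' @param query character vector of query term ids (aliases resolve;
#'   unresolvable terms are dropped with a warning)
#' @param kb a `phenodx_kb`
#' @param graph a `phenodx_ontology`
#' @param ic a `phenodx_ic` built from `kb`
#' @param wm a `phenodx_weights` built from `kb`
#' @param weights optional 4 classifier weights (cosine, tanimoto, psi,
#'   mica); uniform by default
#' @return a `phenodx_ranking`
#' @export
rank_pics <- function(query, kb, graph, ic, wm, weights = NULL) {
  resolved <- resolve_terms(graph, query)
  if (all(is.na(resolved))) stop_input("no query term resolves in the ontology")
  if (anyNA(resolved)) {
    warning(sum(is.na(resolved)), " query term(s) dropped", call. = FALSE)
  }
  qset <- unique(resolved[!is.na(resolved)])
  ids <- kb_disease_ids(kb)

  qv <- query_vector(qset, graph, ic, wm$vocabulary)
  W <- wm$W
  dots <- as.numeric(W %*% qv)
  rn2 <- Matrix::rowSums(W^2)
  qn2 <- sum(qv^2)
  cosv <- ifelse(rn2 > 0 & qn2 > 0, dots / sqrt(rn2 * qn2), 0)
  tden <- rn2 + qn2 - dots
  tanv <- ifelse(tden > 0, dots / tden, 0)

  # pairwise MICA ICs between query terms and the KB term universe,
  # computed once and sliced per disease
  universe <- kb_term_universe(kb)
  micam <- matrix(0, length(qset), length(universe),
                  dimnames = list(qset, universe))
  for (t in qset) micam[t, ] <- mica_ic_row(graph, ic, t, universe)

  psiv <- numeric(length(ids)); micav <- numeric(length(ids))
  for (k in seq_along(ids)) {
    dset <- resolve_terms(graph, kb_disease_terms(kb, ids[k]))
    dset <- unique(dset[!is.na(dset)])
    psiv[k] <- psi_score(qset, dset)
    sub <- micam[, dset, drop = FALSE]
    d1 <- mean(apply(sub, 1, max))   # query -> disease
    d2 <- mean(apply(sub, 2, max))   # disease -> query
    micav[k] <- 0.5 * d1 + 0.5 * d2
  }
  mica_norm <- if (ic$max_ic > 0) pmin(micav / ic$max_ic, 1) else micav

  members <- lapply(list(cosv, tanv, psiv, mica_norm), function(s) {
    normalize_scores(stats::setNames(s, ids))
  })
  combined <- bayesian_average(members, weights %||% rep(1, 4))
  ranked_result(names(combined), combined, query_terms = qset, model = "PICS")
}

# --- PGAS ----------------------------------------------------------------

#' Rank candidate diseases with the gene-space (PGAS) model
#'
#' Every disease receives the symmetric best-match gene-space score under
#' both the cosine and the Tanimoto metric; the two score vectors are
#' combined by Bayesian averaging. Query terms with no gene mapping
#' contribute zero vectors (their count is reported via warning).
#'
#' @inheritParams rank_pics
#' @param gm a `phenodx_genemap`
#' @param weights optional 2 classifier weights (cosine, tanimoto)
#' @return a `phenodx_ranking`
#' @export
rank_pgas <- function(query, kb, gm, weights = NULL, graph = NULL) {
  qset <- unique(query)
  if (!is.null(graph)) {
    resolved <- resolve_terms(graph, qset)
    if (all(is.na(resolved))) stop_input("no query term resolves")
    qset <- unique(resolved[!is.na(resolved)])
  }
  n_unmapped <- sum(!qset %in% names(gm$genes_of))
  if (n_unmapped > 0L) {
    warning(n_unmapped, " query term(s) have no gene mapping", call. = FALSE)
  }
  ids <- kb_disease_ids(kb)
  score_under <- function(metric) {
    vapply(ids, function(d)
      pgas_disease_score(qset, kb_disease_terms(kb, d), gm, metric), 0)
  }
  members <- list(normalize_scores(stats::setNames(score_under("cosine"), ids)),
                  normalize_scores(stats::setNames(score_under("tanimoto"), ids)))
  combined <- bayesian_average(members, weights %||% rep(1, 2))
  ranked_result(names(combined), combined, query_terms = qset, model = "PGAS")
}

#' Write a ranking as TSV or JSON
#'
#' TSV columns: `rank`, `disease_id`, `name` (when a KB is given),
#' `score`.
#' @param result a `phenodx_ranking`
#' @param path output file
#' @param format `"tsv"` or `"json"`
#' @param kb optional `phenodx_kb` supplying disease names
#' @param top_k truncate to the first k rows (default all)
#' @export
write_ranking <- function(result, path, format = c("tsv", "json"), kb = NULL,
                          top_k = Inf) {
  format <- match.arg(format)
  items <- utils::head(result$items, top_k)
  items$name <- if (!is.null(kb)) {
    vapply(items$disease_id,
           function(d) kb$diseases[[d]]$name %||% "", "")
  } else ""
  items <- items[, c("rank", "disease_id", "name", "score")]
  if (format == "tsv") {
    utils::write.table(items, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(model = result$model, query_terms = result$query_terms,
           items = items),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
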