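# Ontology module: OBO parsing, ancestor closures, information content,
# MICA, and TF-IDF-Hierarchy term weights.

#' Parse an OBO flat file into a phenotype ontology graph
#'
#' Reads OBO 1.2/1.4 `[Term]` stanzas and keeps the `is_a` hierarchy only
#' (the phenotype hierarchy of ontologies such as HPO is is_a-structured;
#' `part_of` and other relationship types are ignored). Obsolete terms are
#' dropped from the graph but retained in the alias map when they carry a
#' `replaced_by` target, so lookups of retired ids still resolve. `alt_id`s
#' resolve to their primary term.
#'
#' @param x path to an OBO file, or a character vector of OBO lines.
#' @return an object of class `phenodx_ontology`: a list with elements
#'   `terms` (character vector of primary ids), `name` (named character),
#'   `parents`, `children`, `ancestors` (named lists of character vectors;
#'   `ancestors` excludes the term itself), `alias` (named character mapping
#'   alt/obsolete ids to primary ids), and `roots`.
#' @examples
#' obo <- c("[Term]", "id: T:1", "name: root",
#'          "[Term]", "id: T:2", "name: child", "is_a: T:1 ! root")
#' g <- parse_obo(obo)
#' g$roots
#' @export
parse_obo <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else if (length(x) == 1L && grepl("\n", x)) {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(x)
  }
  lines <- trimws(lines)

  # split into stanzas
  stanza_starts <- which(lines == "[Term]")
  other_starts <- which(grepl("^\\[.+\\]$", lines) & lines != "[Term]")
  bounds <- sort(c(stanza_starts, other_starts, length(lines) + 1L))

  ids <- character(0); names_ <- character(0)
  parents <- list(); alt_ids <- list()
  obsolete <- logical(0); replaced <- character(0)

  strip_comment <- function(v) trimws(sub("\\s*!.*$", "", v))

  for (s in stanza_starts) {
    e <- min(bounds[bounds > s]) - 1L
    body <- lines[seq.int(s + 1L, max(s, e))]
    tagval <- regmatches(body, regexec("^([A-Za-z_]+):\\s*(.*)$", body))
    tags <- vapply(tagval, function(m) if (length(m)) m[2] else "", "")
    vals <- vapply(tagval, function(m) if (length(m)) m[3] else "", "")
    id <- vals[tags == "id"][1]
    if (is.na(id) || !nzchar(id)) next
    id <- strip_comment(id)
    ids <- c(ids, id)
    names_ <- c(names_, strip_comment(vals[tags == "name"][1] %||% ""))
    parents[[length(ids)]] <- strip_comment(vals[tags == "is_a"])
    alt_ids[[length(ids)]] <- strip_comment(vals[tags == "alt_id"])
    obs <- vals[tags == "is_obsolete"]
    obsolete <- c(obsolete, length(obs) > 0L && any(grepl("true", obs)))
    rb <- strip_comment(vals[tags == "replaced_by"])
    replaced <- c(replaced, if (length(rb)) rb[1] else NA_character_)
  }
  if (anyDuplicated(ids)) {
    stop_input("duplicate term id in OBO input: ", ids[duplicated(ids)][1])
  }

  keep <- !obsolete
  primary <- ids[keep]
  alias <- character(0)
  for (i in which(keep)) {
    for (a in alt_ids[[i]]) alias[a] <- ids[i]
  }
  for (i in which(!keep)) {
    if (!is.na(replaced[i])) alias[ids[i]] <- replaced[i]
  }
  # collapse alias chains onto primary terms; drop unresolvable aliases
  alias <- alias[!is.na(alias)]
  resolve1 <- function(t) {
    seen <- character(0)
    while (!(t %in% primary) && t %in% names(alias) && !(t %in% seen)) {
      seen <- c(seen, t); t <- alias[[t]]
    }
    t
  }
  if (length(alias)) {
    alias <- vapply(alias, resolve1, "")
    alias <- alias[alias %in% primary]
  }

  plist <- stats::setNames(vector("list", length(primary)), primary)
  for (i in which(keep)) {
    ps <- parents[[i]]
    ps <- ps[nzchar(ps)]
    if (length(ps)) {
      bad <- setdiff(ps, c(primary, names(alias)))
      if (length(bad)) {
        stop_input("is_a reference to unknown term '", bad[1],
                   "' from '", ids[i], "'")
      }
      ps <- vapply(ps, function(p) if (p %in% primary) p else alias[[p]], "")
    }
    plist[[ids[i]]] <- unique(unname(ps))
  }

  build_ontology(primary, stats::setNames(names_[keep], primary), plist, alias)
}

# assemble + validate the graph (acyclicity via topological sort)
build_ontology <- function(terms, name, parents, alias = character(0)) {
  terms <- sort_c(terms)
  parents <- parents[terms]
  names(parents) <- terms
  parents <- lapply(parents, function(p) {
    if (is.null(p) || !length(p)) character(0) else unname(p)
  })
  children <- stats::setNames(vector("list", length(terms)), terms)
  for (t in terms) {
    for (p in parents[[t]]) children[[p]] <- c(children[[p]], t)
  }
  indeg <- vapply(parents, length, 0L)  # edges toward parents
  roots <- terms[indeg == 0L]
  if (!length(roots)) stop_input("ontology has no root (cycle in is_a)")

  # Kahn topological order from roots downward; detects cycles
  remaining <- indeg
  queue <- roots
  topo <- character(0)
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]
    topo <- c(topo, t)
    for (ch in children[[t]]) {
      remaining[ch] <- remaining[ch] - 1L
      if (remaining[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(topo) != length(terms)) {
    cyc <- setdiff(terms, topo)
    stop_input("cycle in is_a hierarchy involving term '", cyc[1], "'")
  }

  # ancestors (excluding self) by accumulation in topological order
  anc <- stats::setNames(vector("list", length(terms)), terms)
  for (t in topo) {
    ps <- parents[[t]]
    if (length(ps)) {
      anc[[t]] <- sort_c(unique(c(ps, unlist(anc[ps], use.names = FALSE))))
    } else {
      anc[[t]] <- character(0)
    }
  }

  structure(list(
    terms = terms, name = name[terms], parents = parents,
    children = children, ancestors = anc, alias = alias,
    roots = sort_c(roots), topo = topo
  ), class = "phenodx_ontology")
}

#' @export
print.phenodx_ontology <- function(x, ...) {
  cat(sprintf("phenodx ontology: %d terms, %d is_a edges, %d root(s)\n",
              length(x$terms), sum(lengths(x$parents)), length(x$roots)))
  invisible(x)
}

#' Resolve a term id to its primary id
#'
#' Follows `alt_id` and `replaced_by` aliases. Unknown ids return `NA`
#' unless `error = TRUE`.
#' @param graph a `phenodx_ontology`
#' @param terms character vector of ids
#' @param error error on unresolvable ids instead of returning `NA`?
#' @return character vector of primary ids (NA where unresolved)
#' @export
resolve_terms <- function(graph, terms, error = FALSE) {
  out <- ifelse(terms %in% graph$terms, terms,
                unname(graph$alias[terms]))
  if (error && anyNA(out)) {
    stop_input("unknown term id: ", terms[is.na(out)][1])
  }
  out
}

#' Ancestor closure of a term
#'
#' Transitive closure over is_a edges toward the roots.
#' @inheritParams resolve_terms
#' @param term a single term id (aliases resolve)
#' @param include_self include the term itself?
#' @return character vector of term ids
#' @export
ancestors <- function(graph, term, include_self = FALSE) {
  t <- resolve_terms(graph, term, error = TRUE)
  a <- graph$ancestors[[t]]
  if (include_self) sort_c(c(t, a)) else a
}

# union of ancestor closures (incl. the terms themselves) for a term set
propagate_terms <- function(graph, terms) {
  t <- unique(terms)
  sort_c(unique(c(t, unlist(graph$ancestors[t], use.names = FALSE))))
}

#' Annotation-frequency information content
#'
#' For each ontology term, `freq(t)` counts the knowledge-base diseases
#' annotated to `t` or to any of its descendants (the standard Resnik
#' construction: each disease's annotation set is propagated to all
#' ancestors before counting). Information content is
#' `ic(t) = -ln(max(freq(t), 1) / N)` in nats, where `N` is the number of
#' diseases; the pseudo-floor of 1 keeps unannotated terms finitely
#' scorable at the rarest observed level.
#'
#' @param graph a `phenodx_ontology`
#' @param kb a `phenodx_kb` (see [build_kb()])
#' @return an object of class `phenodx_ic`: list with `ic` (named numeric
#'   over every graph term), `freq`, `n_diseases`, `max_ic`.
#' @export
compute_ic <- function(graph, kb) {
  ids <- kb_disease_ids(kb)
  if (!length(ids)) stop_input("knowledge base has no diseases")
  counts <- stats::setNames(integer(length(graph$terms)), graph$terms)
  for (d in ids) {
    terms <- resolve_terms(graph, kb_disease_terms(kb, d))
    terms <- terms[!is.na(terms)]
    closure <- propagate_terms(graph, terms)
    counts[closure] <- counts[closure] + 1L
  }
  n <- length(ids)
  ic <- -log(pmax(counts, 1L) / n)
  structure(list(ic = ic, freq = counts, n_diseases = n,
                 max_ic = max(ic)),
            class = "phenodx_ic")
}

#' Most informative common ancestor of two terms
#'
#' The shared ancestor (self included) with maximal information content;
#' its IC is the Resnik similarity of the pair. Ties break on the
#' lexicographically smallest term id. In a multi-root graph two terms may
#' share no ancestor, in which case the sentinel `(NA, 0)` is returned.
#'
#' @param graph a `phenodx_ontology`
#' @param ic a `phenodx_ic`
#' @param t1,t2 term ids (aliases resolve)
#' @return list with `term` (id or NA) and `ic` (numeric)
#' @export
mica <- function(graph, ic, t1, t2) {
  a <- ancestors(graph, t1, include_self = TRUE)
  b <- ancestors(graph, t2, include_self = TRUE)
  common <- intersect(a, b)
  if (!length(common)) return(list(term = NA_character_, ic = 0))
  v <- ic$ic[common]
  best <- common[order(-v, common, method = "radix")][1]
  list(term = best, ic = unname(ic$ic[[best]]))
}

# IC of the MICA for one term against a vector of terms (vectorised)
mica_ic_row <- function(graph, ic, t, others) {
  a <- ancestors(graph, t, include_self = TRUE)
  ica <- ic$ic[a]
  vapply(others, function(s) {
    common <- intersect(a, ancestors(graph, s, include_self = TRUE))
    if (!length(common)) 0 else max(ic$ic[common])
  }, 0)
}

#' TF-IDF-Hierarchy disease-by-term weight matrix
#'
#' Builds the weighted phenotype vector of every knowledge-base disease:
#' the disease's annotation set is propagated to all ancestors (the
#' Hierarchy step), term presence in the propagated set is the binary TF,
#' and each present term is weighted by its annotation information content
#' (the IDF role). The vocabulary is the set of terms with a nonzero
#' weight for at least one disease, in lexicographic order.
#'
#' @inheritParams compute_ic
#' @param ic a `phenodx_ic` computed from the same `kb`
#' @return an object of class `phenodx_weights`: list with `W` (sparse
#'   dgCMatrix, diseases x vocabulary) and `vocabulary`.
#' @export
tfidf_hierarchy_weights <- function(graph, kb, ic) {
  ids <- kb_disease_ids(kb)
  if (ic$n_diseases != length(ids)) {
    stop_input("ic table was computed from a different knowledge base (",
               ic$n_diseases, " vs ", length(ids), " diseases)")
  }
  closures <- lapply(ids, function(d) {
    terms <- resolve_terms(graph, kb_disease_terms(kb, d))
    propagate_terms(graph, terms[!is.na(terms)])
  })
  names(closures) <- ids
  vocab <- sort_c(unique(unlist(closures, use.names = FALSE)))
  vocab <- vocab[ic$ic[vocab] > 0]   # zero-IC terms carry no weight
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (k in seq_along(ids)) {
    terms <- intersect(closures[[k]], vocab)
    if (!length(terms)) next
    cols <- match(terms, vocab)
    i <- c(i, rep.int(k, length(cols))); j <- c(j, cols)
    x <- c(x, unname(ic$ic[terms]))
  }
  W <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(length(ids), length(vocab)),
                            dimnames = list(ids, vocab))
  structure(list(W = W, vocabulary = vocab), class = "phenodx_weights")
}
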