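# Knowledge-base module: disease-phenotype and phenotype-gene associations.

#' Read disease-phenotype annotations (phenotype_annotation dialect)
#'
#' Parses the classic tab-separated annotation format whose first five
#' columns are DB, DB_Object_ID, DB_Name, Qualifier and the ontology term
#' id. The disease identifier is composed as `DB:DB_Object_ID`. Rows with
#' qualifier `NOT` are dropped, term ids are resolved through the alias
#' map, unresolvable rows are skipped with a warning, duplicates collapse.
#'
#' @param x path to a TSV file or a character vector of lines
#' @param graph a `phenodx_ontology` used to resolve term ids
#' @return data.frame with columns `disease_id`, `name`, `term` plus an
#'   attribute `n_skipped` (rows dropped for unresolvable terms)
#' @export
read_hpo_annotations <- function(x, graph) {
  lines <- read_lines_arg(x)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    out <- data.frame(disease_id = character(0), name = character(0),
                      term = character(0), stringsAsFactors = FALSE)
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 5L)
  if (length(short)) {
    stop_input("annotation line ", short[1], " has fewer than 5 columns")
  }
  db <- vapply(parts, `[[`, "", 1L)
  oid <- vapply(parts, `[[`, "", 2L)
  nm <- vapply(parts, `[[`, "", 3L)
  qual <- vapply(parts, `[[`, "", 4L)
  term <- vapply(parts, `[[`, "", 5L)
  keep <- toupper(trimws(qual)) != "NOT"
  db <- db[keep]; oid <- oid[keep]; nm <- nm[keep]; term <- term[keep]
  resolved <- resolve_terms(graph, term)
  n_skipped <- sum(is.na(resolved))
  if (n_skipped > 0L) {
    warning(n_skipped, " annotation row(s) skipped: unresolvable term id(s), e.g. '",
            term[is.na(resolved)][1], "'", call. = FALSE)
  }
  ok <- !is.na(resolved)
  full_id <- paste0(db, ":", oid)
  out <- data.frame(disease_id = full_id[ok],
                    name = nm[ok], term = resolved[ok],
                    stringsAsFactors = FALSE)
  out <- unique(out)
  out <- out[order(out$disease_id, out$term, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

read_lines_arg <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else if (length(x) == 1L && grepl("\n", x)) {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  } else as.character(x)
}

#' Read phenotype-gene associations
#'
#' Two-column TSV, `term_id<TAB>gene` per line; `#` lines are comments.
#' Term ids resolve through the ontology alias map; unresolvable rows are
#' skipped with a warning; duplicates collapse.
#'
#' @inheritParams read_hpo_annotations
#' @return an object of class `phenodx_genemap`: list with `genes_of`
#'   (named list term -> character vector of genes) and `gene_universe`
#'   (sorted union)
#' @export
read_gene_associations <- function(x, graph) {
  lines <- read_lines_arg(x)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(structure(list(genes_of = stats::setNames(list(), character(0)),
                          gene_universe = character(0)),
                     class = "phenodx_genemap"))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 2L)
  if (length(short)) {
    stop_input("gene association line ", short[1], " has fewer than 2 columns")
  }
  term <- vapply(parts, `[[`, "", 1L)
  gene <- vapply(parts, `[[`, "", 2L)
  resolved <- resolve_terms(graph, term)
  if (anyNA(resolved)) {
    warning(sum(is.na(resolved)), " gene association row(s) skipped: ",
            "unresolvable term id(s)", call. = FALSE)
  }
  ok <- !is.na(resolved)
  df <- unique(data.frame(term = resolved[ok], gene = gene[ok],
                          stringsAsFactors = FALSE))
  genes_of <- lapply(split(df$gene, df$term), sort_c)
  genes_of <- genes_of[sort_c(names(genes_of))]
  structure(list(genes_of = genes_of,
                 gene_universe = sort_c(unique(df$gene))),
            class = "phenodx_genemap")
}

#' Build a disease-phenotype knowledge base
#'
#' Combines curated and (optionally) text-mined disease-phenotype
#' associations into the training corpus. In `curated_only` mode the
#' accessors expose curated phenotypes only; `curated_plus_textmined`
#' exposes the union with provenance retained. Diseases whose exposed
#' phenotype set is empty are dropped (they could never be scored).
#'
#' @param curated data.frame as returned by [read_hpo_annotations()]
#' @param text_mined optional data.frame in the same shape
#' @param mode `"curated_only"` or `"curated_plus_textmined"`
#' @param genes optional data.frame with columns `disease_id`, `gene`
#' @return object of class `phenodx_kb`
#' @export
build_kb <- function(curated, text_mined = NULL,
                     mode = c("curated_only", "curated_plus_textmined"),
                     genes = NULL) {
  mode <- match.arg(mode)
  diseases <- new.env(parent = emptyenv())
  add <- function(df, provenance) {
    if (is.null(df) || !nrow(df)) return()
    for (i in seq_len(nrow(df))) {
      id <- df$disease_id[i]
      rec <- get0(id, envir = diseases) %||%
        list(name = df$name[i], curated = character(0),
             text_mined = character(0), genes = character(0))
      rec[[provenance]] <- c(rec[[provenance]], df$term[i])
      if (!nzchar(rec$name) && nzchar(df$name[i])) rec$name <- df$name[i]
      assign(id, rec, envir = diseases)
    }
  }
  add(curated, "curated")
  add(text_mined, "text_mined")
  if (!is.null(genes) && nrow(genes)) {
    for (i in seq_len(nrow(genes))) {
      id <- genes$disease_id[i]
      rec <- get0(id, envir = diseases)
      if (!is.null(rec)) {
        rec$genes <- c(rec$genes, genes$gene[i])
        assign(id, rec, envir = diseases)
      }
    }
  }
  ids <- sort_c(ls(diseases))
  recs <- lapply(ids, function(id) {
    r <- get(id, envir = diseases)
    r$curated <- sort_c(unique(r$curated))
    r$text_mined <- sort_c(unique(r$text_mined))
    r$genes <- sort_c(unique(r$genes))
    r
  })
  names(recs) <- ids
  exposed <- vapply(recs, function(r) {
    length(if (mode == "curated_only") r$curated
           else union(r$curated, r$text_mined)) > 0L
  }, TRUE)
  n_dropped <- sum(!exposed)
  if (n_dropped > 0L) {
    message(n_dropped, " disease(s) dropped: no exposed phenotypes in mode '",
            mode, "'")
  }
  recs <- recs[exposed]
  kb <- structure(list(diseases = recs, mode = mode,
                       n_dropped = n_dropped),
                  class = "phenodx_kb")
  kb
}

#' @export
print.phenodx_kb <- function(x, ...) {
  cat(sprintf("phenodx knowledge base: %d diseases, %d terms exposed (mode %s)\n",
              length(x$diseases), length(kb_term_universe(x)), x$mode))
  invisible(x)
}

#' Knowledge-base accessors
#'
#' `kb_disease_ids` lists disease ids; `kb_disease_terms` returns the
#' phenotype set a disease exposes under the KB's mode;
#' `kb_term_universe` is the union of exposed sets; `kb_disease_genes`
#' returns a disease's gene set, derived as the union over its exposed
#' phenotypes' gene sets when a gene map is supplied.
#'
#' @param kb a `phenodx_kb`
#' @param disease_id a disease identifier present in `kb`
#' @param gm optional `phenodx_genemap`
#' @return character vectors
#' @export
kb_disease_ids <- function(kb) names(kb$diseases)

#' @rdname kb_disease_ids
#' @export
kb_disease_terms <- function(kb, disease_id) {
  rec <- kb$diseases[[disease_id]]
  if (is.null(rec)) stop_input("unknown disease id: ", disease_id)
  if (kb$mode == "curated_only") rec$curated
  else sort_c(union(rec$curated, rec$text_mined))
}

#' @rdname kb_disease_ids
#' @export
kb_term_universe <- function(kb) {
  sort_c(unique(unlist(lapply(kb_disease_ids(kb),
                              function(d) kb_disease_terms(kb, d)),
                       use.names = FALSE)))
}

#' @rdname kb_disease_ids
#' @export
kb_disease_genes <- function(kb, disease_id, gm = NULL) {
  rec <- kb$diseases[[disease_id]]
  if (is.null(rec)) stop_input("unknown disease id: ", disease_id)
  if (is.null(gm)) return(rec$genes)
  sort_c(unique(c(rec$genes,
                  unlist(gm$genes_of[kb_disease_terms(kb, disease_id)],
                         use.names = FALSE))))
}

#' Disease and query phenotype vectors
#'
#' `disease_vector` projects one disease's row out of the weight matrix.
#' `query_vector` builds the comparable vector for an arbitrary term list:
#' terms are resolved, propagated to their ancestors, weighted by IC and
#' restricted to the shared vocabulary. Unresolvable query terms are
#' dropped; the count is attached as attribute `n_dropped`.
#'
#' @param kb a `phenodx_kb`
#' @param disease_id disease present in `kb`
#' @param wm a `phenodx_weights` built over `kb`
#' @return named numeric vector over `wm$vocabulary`
#' @export
disease_vector <- function(kb, disease_id, wm) {
  if (!disease_id %in% rownames(wm$W)) {
    stop_input("unknown disease id: ", disease_id)
  }
  v <- as.numeric(wm$W[disease_id, ])
  names(v) <- wm$vocabulary
  v
}

#' @rdname disease_vector
#' @param terms character vector of query term ids
#' @param graph a `phenodx_ontology`
#' @param ic a `phenodx_ic`
#' @param vocabulary ordered term vocabulary shared with the disease vectors
#' @export
query_vector <- function(terms, graph, ic, vocabulary) {
  resolved <- resolve_terms(graph, terms)
  n_dropped <- sum(is.na(resolved))
  resolved <- unique(resolved[!is.na(resolved)])
  if (!length(resolved)) stop_input("no query term resolves in the ontology")
  closure <- propagate_terms(graph, resolved)
  v <- stats::setNames(numeric(length(vocabulary)), vocabulary)
  hit <- intersect(closure, vocabulary)
  v[hit] <- ic$ic[hit]
  attr(v, "n_dropped") <- n_dropped
  v
}
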