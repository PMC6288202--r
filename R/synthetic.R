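# Synthetic-data module: fixture generator for ontologies, knowledge
# bases, gene maps, and EMR-like patient cohorts.

#' Specification for synthetic fixtures
#'
#' Defaults are desk-scale: a 300-term DAG, 50 diseases annotated with
#' 5-12 leaf-biased terms each, a 200-gene pool with up to 10 genes per
#' term, and cohort noise matching the training-patient generator
#' (dropout 0.2, Poisson(2) noise) -- large enough to exercise sparsity
#' and the hierarchy, small enough for seconds-level tests.
#'
#' @param n_terms,depth,branching ontology shape
#' @param n_diseases number of diseases
#' @param terms_per_disease integer (min, max) annotated terms per disease
#' @param n_genes gene pool size
#' @param genes_per_term integer (min, max) genes per phenotype term
#' @param dropout,noise_rate,patients_per_disease cohort parameters
#' @param seed integer master seed
#' @return list of class `phenodx_synthspec`
#' @export
synthetic_spec <- function(n_terms = 300L, depth = 6L, branching = 4L,
                           n_diseases = 50L, terms_per_disease = c(5L, 12L),
                           n_genes = 200L, genes_per_term = c(1L, 10L),
                           dropout = 0.2, noise_rate = 2,
                           patients_per_disease = 10L, seed = 1L) {
  spec <- list(n_terms = as.integer(n_terms), depth = as.integer(depth),
               branching = as.integer(branching),
               n_diseases = as.integer(n_diseases),
               terms_per_disease = as.integer(terms_per_disease),
               n_genes = as.integer(n_genes),
               genes_per_term = as.integer(genes_per_term),
               dropout = dropout, noise_rate = noise_rate,
               patients_per_disease = as.integer(patients_per_disease),
               seed = as.integer(seed))
  if (any(unlist(spec[c("n_terms", "depth", "branching", "n_diseases",
                        "n_genes", "patients_per_disease")]) < 1L)) {
    stop_input("all synthetic spec counts must be positive")
  }
  assert_scalar_number(spec$dropout, "dropout", 0, 1 - 1e-12)
  assert_scalar_number(spec$noise_rate, "noise_rate", 0)
  structure(spec, class = "phenodx_synthspec")
}

synth_term_id <- function(i) sprintf("SP:%07d", i)
synth_disease_id <- function(i) sprintf("SD:%06d", i)

#' Generate a random rooted DAG ontology
#'
#' Terms are laid out level by level under a single root; every non-root
#' term gets one parent drawn uniformly from the previous level, plus a
#' second parent with probability 0.2, giving a genuine DAG (diamonds
#' included). Returns both the parsed graph and OBO text that round-trips
#' through [parse_obo()].
#'
#' @param spec a [synthetic_spec()]
#' @return list with `graph` (a `phenodx_ontology`) and `obo` (character
#'   vector of OBO lines)
#' @export
make_toy_ontology <- function(spec) {
  n <- spec$n_terms
  if (n < 1L) stop_input("n_terms must be >= 1")
  capacity <- sum(spec$branching^(0:spec$depth))
  if (capacity < n) {
    stop_input("infeasible spec: branching^depth levels hold ", capacity,
               " terms < ", n, " requested")
  }
  with_seed(derive_seed(spec$seed, "ontology"), {
    ids <- synth_term_id(seq_len(n))
    level <- integer(n); level[1] <- 0L
    # fill levels: level L holds at most branching^L terms
    cur <- 1L
    for (i in seq_len(n)[-1]) {
      if (sum(level[seq_len(i - 1L)] == cur) >= spec$branching^cur) {
        cur <- cur + 1L
      }
      level[i] <- cur
    }
    parents <- stats::setNames(vector("list", n), ids)
    for (i in seq_len(n)[-1]) {
      prev <- which(level == level[i] - 1L)
      p1 <- if (length(prev) == 1L) prev else sample(prev, 1L)
      ps <- p1
      if (length(prev) > 1L && stats::runif(1) < 0.2) {
        p2 <- sample(setdiff(prev, p1), 1L)
        ps <- c(ps, p2)
      }
      parents[[i]] <- ids[ps]
    }
    obo <- character(0)
    for (i in seq_len(n)) {
      obo <- c(obo, "[Term]", paste0("id: ", ids[i]),
               paste0("name: synthetic term ", i),
               paste0("is_a: ", parents[[i]]), "")
    }
    list(graph = build_ontology(ids,
                                stats::setNames(paste("synthetic term",
                                                      seq_len(n)), ids),
                                parents),
         obo = obo)
  })
}

#' Emit OBO text for an ontology graph
#' @param graph a `phenodx_ontology`
#' @return character vector of OBO lines
#' @export
emit_obo <- function(graph) {
  out <- character(0)
  for (t in graph$terms) {
    out <- c(out, "[Term]", paste0("id: ", t),
             paste0("name: ", graph$name[[t]]),
             paste0("is_a: ", graph$parents[[t]]), "")
  }
  out
}

#' Generate a synthetic disease-phenotype knowledge base
#'
#' Each disease draws a uniform(min, max) number of distinct non-root
#' terms with probability proportional to `1/(1 + n_descendants)` --
#' leaf-biased, mirroring real annotation practice where specific terms
#' are annotated and ancestors are implied. With `disjoint_support = TRUE`
#' the terms are partitioned so annotation sets are pairwise disjoint
#' (for separability tests). `text_mined_per_disease > 0` adds a
#' text-mined annotation layer.
#'
#' @param graph a `phenodx_ontology`
#' @param spec a [synthetic_spec()]
#' @param disjoint_support force pairwise-disjoint annotation sets?
#' @param text_mined_per_disease extra text-mined terms per disease
#' @param mode KB exposure mode passed to [build_kb()]
#' @return a `phenodx_kb`
#' @export
make_toy_kb <- function(graph, spec, disjoint_support = FALSE,
                        text_mined_per_disease = 0L,
                        mode = "curated_only") {
  lo <- spec$terms_per_disease[1]; hi <- spec$terms_per_disease[2]
  pool <- setdiff(graph$terms, graph$roots)
  if (hi > length(pool)) {
    stop_input("terms_per_disease max (", hi, ") exceeds available non-root terms (",
               length(pool), ")")
  }
  if (disjoint_support && spec$n_diseases * hi > length(pool)) {
    stop_input("disjoint support infeasible: need ", spec$n_diseases * hi,
               " terms, have ", length(pool))
  }
  n_desc <- count_descendants(graph)
  w <- 1 / (1 + n_desc[pool])
  with_seed(derive_seed(spec$seed, "kb"), {
    remaining <- pool
    rows <- list(); tm_rows <- list()
    for (i in seq_len(spec$n_diseases)) {
      d <- synth_disease_id(i)
      k <- if (lo == hi) lo else sample(seq.int(lo, hi), 1L)
      src <- if (disjoint_support) remaining else pool
      terms <- sample(src, k, prob = (1 / (1 + n_desc[src])))
      if (disjoint_support) remaining <- setdiff(remaining, terms)
      rows[[i]] <- data.frame(disease_id = d,
                              name = paste("synthetic disease", i),
                              term = terms, stringsAsFactors = FALSE)
      if (text_mined_per_disease > 0L) {
        extra_pool <- setdiff(pool, terms)
        extra <- sample(extra_pool,
                        min(text_mined_per_disease, length(extra_pool)))
        tm_rows[[i]] <- data.frame(disease_id = d,
                                   name = paste("synthetic disease", i),
                                   term = extra, stringsAsFactors = FALSE)
      }
    }
    build_kb(do.call(rbind, rows),
             text_mined = if (length(tm_rows)) do.call(rbind, tm_rows),
             mode = mode)
  })
}

count_descendants <- function(graph) {
  n_desc <- stats::setNames(integer(length(graph$terms)), graph$terms)
  desc <- stats::setNames(vector("list", length(graph$terms)), graph$terms)
  for (t in rev(graph$topo)) {
    ch <- graph$children[[t]]
    desc[[t]] <- unique(c(ch, unlist(desc[ch], use.names = FALSE)))
    n_desc[t] <- length(desc[[t]])
  }
  n_desc
}

#' Generate a synthetic phenotype-gene map
#'
#' Every ontology term draws a uniform(min, max) number of genes from a
#' shared pool; deterministic under the spec seed.
#'
#' @inheritParams make_toy_kb
#' @return a `phenodx_genemap`
#' @export
make_gene_map <- function(graph, spec) {
  lo <- spec$genes_per_term[1]; hi <- spec$genes_per_term[2]
  genes <- sprintf("GENE%04d", seq_len(spec$n_genes))
  with_seed(derive_seed(spec$seed, "genes"), {
    genes_of <- lapply(graph$terms, function(t) {
      k <- if (lo == hi) lo else sample(seq.int(lo, hi), 1L)
      sort_c(sample(genes, min(k, length(genes))))
    })
    names(genes_of) <- graph$terms
    structure(list(genes_of = genes_of,
                   gene_universe = sort_c(unique(unlist(genes_of)))),
              class = "phenodx_genemap")
  })
}

#' Generate an EMR-like test cohort
#'
#' Reuses the training-patient mechanics (term dropout + Poisson noise)
#' but labels records `synthetic_test`. When `target_mean_terms` is set,
#' dropout is auto-tuned so the expected record size approximates the
#' target (for example 17 terms, the mean symptom count of real metabolic
#' EMR records); an unattainable target falls back to dropout 0 with a
#' warning.
#'
#' @param kb a `phenodx_kb`
#' @param spec a [synthetic_spec()]
#' @param patients_per_disease override of `spec$patients_per_disease`
#' @param target_mean_terms optional target mean record size
#' @return list of `phenodx_patient`
#' @export
make_patient_cohort <- function(kb, spec, patients_per_disease = NULL,
                                target_mean_terms = NULL) {
  dropout <- spec$dropout
  if (!is.null(target_mean_terms)) {
    mean_size <- mean(vapply(kb_disease_ids(kb),
                             function(d) length(kb_disease_terms(kb, d)), 0))
    # E[record size] = (1 - dropout) * mean_size + noise_rate
    d <- 1 - (target_mean_terms - spec$noise_rate) / mean_size
    if (d < 0) {
      warning("target_mean_terms exceeds the mean annotation size; using dropout 0",
              call. = FALSE)
      dropout <- 0
    } else {
      dropout <- min(d, 1 - 1e-9)
    }
  }
  generate_training_patients(
    kb, per_disease = patients_per_disease %||% spec$patients_per_disease,
    dropout = dropout, noise_rate = spec$noise_rate,
    seed = derive_seed(spec$seed, "cohort"), source = "synthetic_test")
}

#' Write / read a fixture bundle
#'
#' `write_fixture_bundle` writes `ontology.obo`, `annotations.tab`
#' (5-column annotation dialect), `annotations_textmined.tab` (when the KB
#' carries a text-mined layer), `genes.tsv`, `patients.json`, and
#' `manifest.json` with content hashes; `read_fixture_bundle` loads the
#' files back through the package's own readers, reproducing equal
#' objects.
#'
#' @param path directory to create
#' @param graph a `phenodx_ontology`
#' @param kb a `phenodx_kb`
#' @param gm optional `phenodx_genemap`
#' @param cohort optional list of `phenodx_patient`
#' @param spec optional [synthetic_spec()] recorded in the manifest
#' @return the manifest (invisibly for write)
#' @export
write_fixture_bundle <- function(path, graph, kb, gm = NULL, cohort = NULL,
                                 spec = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  p_obo <- file.path(path, "ontology.obo")
  writeLines(emit_obo(graph), p_obo)

  ann_lines <- function(provenance) {
    unlist(lapply(kb_disease_ids(kb), function(d) {
      rec <- kb$diseases[[d]]
      terms <- rec[[provenance]]
      if (!length(terms)) return(character(0))
      parts <- strsplit(d, ":", fixed = TRUE)[[1]]
      paste(parts[1], paste(parts[-1], collapse = ":"), rec$name, "",
            terms, sep = "\t")
    }), use.names = FALSE)
  }
  p_ann <- file.path(path, "annotations.tab")
  writeLines(c("#DB\tDB_Object_ID\tDB_Name\tQualifier\tHPO_ID",
               ann_lines("curated")), p_ann)
  tm <- ann_lines("text_mined")
  p_tm <- file.path(path, "annotations_textmined.tab")
  has_tm <- length(tm) > 0L
  if (has_tm) {
    writeLines(c("#DB\tDB_Object_ID\tDB_Name\tQualifier\tHPO_ID", tm), p_tm)
  }

  files <- list(ontology = "ontology.obo", annotations = "annotations.tab")
  if (has_tm) files$text_mined <- "annotations_textmined.tab"
  if (!is.null(gm)) {
    p_gene <- file.path(path, "genes.tsv")
    lines <- unlist(lapply(names(gm$genes_of), function(t) {
      paste(t, gm$genes_of[[t]], sep = "\t")
    }), use.names = FALSE)
    writeLines(lines, p_gene)
    files$genes <- "genes.tsv"
  }
  if (!is.null(cohort)) {
    p_pat <- file.path(path, "patients.json")
    jsonlite::write_json(lapply(cohort, function(p) {
      list(patient_id = p$patient_id, phenotypes = as.list(p$phenotypes),
           true_disease = p$true_disease, source = p$source)
    }), p_pat, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files$patients <- "patients.json"
  }
  hashes <- lapply(files, function(f) digest::digest(file = file.path(path, f)))
  manifest <- list(files = files, hashes = hashes, mode = kb$mode,
                   spec = if (!is.null(spec)) unclass(spec))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' @rdname write_fixture_bundle
#' @export
read_fixture_bundle <- function(path) {
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"))
  graph <- parse_obo(file.path(path, manifest$files$ontology))
  curated <- read_hpo_annotations(file.path(path, manifest$files$annotations),
                                  graph)
  text_mined <- if (!is.null(manifest$files$text_mined)) {
    read_hpo_annotations(file.path(path, manifest$files$text_mined), graph)
  }
  kb <- build_kb(curated, text_mined = text_mined,
                 mode = manifest$mode %||% "curated_only")
  gm <- if (!is.null(manifest$files$genes)) {
    read_gene_associations(file.path(path, manifest$files$genes), graph)
  }
  cohort <- if (!is.null(manifest$files$patients)) {
    lapply(jsonlite::read_json(file.path(path, manifest$files$patients)),
           function(p) patient_record(p$patient_id,
                                      unlist(p$phenotypes),
                                      p$true_disease %||% NA_character_,
                                      p$source))
  }
  list(graph = graph, kb = kb, gm = gm, cohort = cohort, manifest = manifest)
}
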