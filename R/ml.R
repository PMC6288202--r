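# Machine-learning models: synthetic training patients, feature
# construction, ensemble training and ranking.

#' Construct a patient record
#'
#' @param patient_id unique identifier
#' @param phenotypes character vector of term ids (deduplicated)
#' @param true_disease optional disease id label
#' @param source one of `synthetic_train`, `synthetic_test`, `emr`
#' @return object of class `phenodx_patient`
#' @export
patient_record <- function(patient_id, phenotypes, true_disease = NA_character_,
                           source = c("synthetic_train", "synthetic_test", "emr")) {
  source <- match.arg(source)
  phenotypes <- unique(as.character(phenotypes))
  if (!length(phenotypes)) stop_input("patient must have >= 1 phenotype")
  structure(list(patient_id = patient_id, phenotypes = phenotypes,
                 true_disease = true_disease, source = source),
            class = "phenodx_patient")
}

#' Simulate training patients from a knowledge base
#'
#' For every disease, `per_disease` patients are drawn: each annotated
#' term is kept independently with probability `1 - dropout`, then
#' `k ~ Poisson(noise_rate)` noise terms are added, drawn uniformly from
#' the KB term universe minus the disease's own set. A patient that loses
#' every term gets one uniformly chosen annotated term back, so records
#' are never empty. Fully reproducible from `seed`.
#'
#' @param kb a `phenodx_kb`
#' @param per_disease patients per disease (default 10, the full-scale
#'   corpus ratio)
#' @param dropout per-term drop probability in \[0,1)
#' @param noise_rate Poisson mean of added noise terms
#' @param seed integer seed
#' @param source record source tag
#' @return list of `phenodx_patient`
#' @export
generate_training_patients <- function(kb, per_disease = 10L, dropout = 0.2,
                                       noise_rate = 2, seed = 1L,
                                       source = "synthetic_train") {
  assert_scalar_number(dropout, "dropout", 0, 1 - 1e-12)
  assert_scalar_number(noise_rate, "noise_rate", 0)
  if (per_disease < 1L) stop_input("per_disease must be >= 1")
  ids <- kb_disease_ids(kb)
  if (!length(ids)) stop_input("knowledge base has no diseases")
  universe <- kb_term_universe(kb)
  with_seed(seed, {
    out <- vector("list", length(ids) * per_disease)
    n <- 0L
    for (d in ids) {
      dset <- kb_disease_terms(kb, d)
      pool <- setdiff(universe, dset)
      for (j in seq_len(per_disease)) {
        keep <- dset[stats::runif(length(dset)) >= dropout]
        if (!length(keep)) keep <- sample(dset, 1L)
        k <- stats::rpois(1L, noise_rate)
        noise <- if (k > 0L && length(pool)) {
          sample(pool, min(k, length(pool)))
        } else character(0)
        n <- n + 1L
        out[[n]] <- patient_record(
          sprintf("%s|p%03d", d, j), c(keep, noise),
          true_disease = d, source = source)
      }
    }
    out[seq_len(n)]
  })
}

#' Build the patient feature matrix
#'
#' Each patient becomes one row: their phenotype list is propagated and
#' IC-weighted over the shared vocabulary exactly like a query vector.
#' Patients with no resolvable term are dropped with a warning.
#'
#' @param patients list of `phenodx_patient`
#' @param graph a `phenodx_ontology`
#' @param ic a `phenodx_ic`
#' @param vocabulary shared ordered term vocabulary
#' @return object of class `phenodx_features`: list with `X` (dense
#'   matrix patients x vocabulary), `labels`, `patient_ids`, `vocabulary`
#' @export
build_features <- function(patients, graph, ic, vocabulary) {
  rows <- vector("list", length(patients))
  labels <- character(length(patients)); pids <- character(length(patients))
  ok <- logical(length(patients))
  for (i in seq_along(patients)) {
    p <- patients[[i]]
    v <- tryCatch(query_vector(p$phenotypes, graph, ic, vocabulary),
                  error = function(e) NULL)
    if (is.null(v)) next
    rows[[i]] <- as.numeric(v)
    labels[i] <- p$true_disease %||% NA_character_
    pids[i] <- p$patient_id
    ok[i] <- TRUE
  }
  if (!any(ok)) stop_input("no patient has resolvable phenotypes")
  if (any(!ok)) {
    warning(sum(!ok), " patient(s) dropped: no resolvable phenotype",
            call. = FALSE)
  }
  X <- do.call(rbind, rows[ok])
  dimnames(X) <- list(pids[ok], vocabulary)
  structure(list(X = X, labels = labels[ok], patient_ids = pids[ok],
                 vocabulary = vocabulary),
            class = "phenodx_features")
}

#' Train a classifier ensemble
#'
#' Fits every requested backend on a stratified train split and weighs
#' each member by its top-1 accuracy on the held-out validation split
#' (weights normalized across members; uniform when
#' `validation_fraction = 0`). A failing backend is dropped with a
#' warning; if all fail, training errors.
#'
#' @param fm a `phenodx_features` with labels
#' @param specs list of [classifier_spec()]
#' @param validation_fraction fraction of rows held out per label
#' @param seed integer seed for the split
#' @param model model tag for downstream rankings (`"CPML"` or `"APML"`)
#' @return object of class `phenodx_ensemble`
#' @export
train_ensemble <- function(fm, specs, validation_fraction = 0.2, seed = 1L,
                           model = "CPML") {
  if (!length(specs)) stop_input("at least one classifier spec required")
  assert_scalar_number(validation_fraction, "validation_fraction", 0, 0.9)
  labels <- fm$labels
  if (anyNA(labels)) stop_input("all feature rows must carry a label")
  label_set <- sort_c(unique(labels))
  n <- nrow(fm$X)

  if (validation_fraction > 0) {
    tab <- table(labels)
    if (any(tab < 2L)) {
      stop_input("every label needs >= 2 rows when validation_fraction > 0")
    }
    val_idx <- with_seed(derive_seed(seed, "split"), {
      unlist(lapply(split(seq_len(n), labels), function(rows) {
        nv <- max(1L, floor(length(rows) * validation_fraction))
        sample(rows, nv)
      }), use.names = FALSE)
    })
    train_idx <- setdiff(seq_len(n), val_idx)
  } else {
    train_idx <- seq_len(n); val_idx <- integer(0)
  }

  Xtr <- fm$X[train_idx, , drop = FALSE]
  ytr <- factor(labels[train_idx], levels = label_set)

  members <- list(); accs <- numeric(0)
  for (spec in specs) {
    member <- tryCatch(fit_backend(spec, Xtr, ytr, label_set),
                       error = function(e) {
                         warning("backend '", spec$algorithm, "' failed: ",
                                 conditionMessage(e), call. = FALSE)
                         NULL
                       })
    if (is.null(member)) next
    acc <- if (length(val_idx)) {
      P <- predict_member(member, fm$X[val_idx, , drop = FALSE])
      pred <- label_set[max.col(P, ties.method = "first")]
      mean(pred == labels[val_idx])
    } else NA_real_
    members[[length(members) + 1L]] <- member
    accs <- c(accs, acc)
  }
  if (!length(members)) stop_input("all classifier backends failed")

  weights <- if (length(val_idx)) {
    if (sum(accs) == 0) rep(1 / length(accs), length(accs))
    else accs / sum(accs)
  } else rep(1 / length(members), length(members))

  structure(list(members = members, weights = weights,
                 validation_accuracy = accs, label_set = label_set,
                 vocabulary = fm$vocabulary, model = model, seed = seed),
            class = "phenodx_ensemble")
}

#' @export
print.phenodx_ensemble <- function(x, ...) {
  cat(sprintf("phenodx %s ensemble: %d member(s), %d labels, %d features\n",
              x$model, length(x$members), length(x$label_set),
              length(x$vocabulary)))
  for (i in seq_along(x$members)) {
    cat(sprintf("  %-22s weight %.3f  val.acc %s\n",
                x$members[[i]]$spec$algorithm, x$weights[i],
                ifelse(is.na(x$validation_accuracy[i]), "-",
                       sprintf("%.3f", x$validation_accuracy[i]))))
  }
  invisible(x)
}

#' Rank candidate diseases with a trained ensemble
#'
#' Builds the query feature row over the ensemble's vocabulary, collects
#' every member's label distribution, combines them by Bayesian averaging
#' with the member weights and sorts.
#'
#' @param query character vector of query term ids
#' @param ens a `phenodx_ensemble`
#' @param graph a `phenodx_ontology`
#' @param ic a `phenodx_ic`
#' @return a `phenodx_ranking`
#' @export
rank_ml <- function(query, ens, graph, ic) {
  v <- query_vector(query, graph, ic, ens$vocabulary)
  X <- matrix(as.numeric(v), 1, dimnames = list(NULL, ens$vocabulary))
  dists <- lapply(ens$members, function(m) {
    p <- predict_member(m, X)[1, ]
    attr(p, "normalized") <- TRUE
    p
  })
  combined <- bayesian_average(dists, ens$weights)
  ranked_result(names(combined), combined,
                query_terms = unique(query), model = ens$model)
}

#' @rdname rank_ml
#' @param queries list of query term vectors, ranked in one prediction
#'   pass (much faster than repeated [rank_ml()] calls for cohorts)
#' @export
rank_ml_batch <- function(queries, ens, graph, ic) {
  rows <- lapply(queries, function(q) {
    as.numeric(query_vector(q, graph, ic, ens$vocabulary))
  })
  X <- do.call(rbind, rows)
  colnames(X) <- ens$vocabulary
  Ps <- lapply(ens$members, function(m) predict_member(m, X))
  w <- ens$weights / sum(ens$weights)
  combined <- Reduce(`+`, Map(function(P, wk) P * wk, Ps, w))
  lapply(seq_along(queries), function(i) {
    ranked_result(colnames(combined), combined[i, ],
                  query_terms = unique(queries[[i]]), model = ens$model)
  })
}

#' Persist / restore a trained ensemble
#'
#' Writes a directory with `manifest.json` (specs, weights, labels,
#' vocabulary hash, seed) and one opaque blob per member.
#'
#' @param ens a `phenodx_ensemble`
#' @param path directory to create
#' @export
save_ensemble <- function(ens, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    model = ens$model, seed = ens$seed,
    label_set = ens$label_set,
    vocabulary_hash = digest::digest(ens$vocabulary),
    weights = ens$weights,
    validation_accuracy = ens$validation_accuracy,
    members = lapply(ens$members, function(m) {
      list(algorithm = m$spec$algorithm,
           hyperparameters = m$spec$hyperparameters,
           seed = m$spec$seed)
    }))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  saveRDS(ens, file.path(path, "ensemble.rds"))
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  readRDS(file.path(path, "ensemble.rds"))
}
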