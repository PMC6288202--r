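# Bayesian-averaging combiner shared by all four ranking models.

#' Normalize raw candidate scores to a distribution
#'
#' Similarity scores are not probabilities; before averaging, each
#' classifier's scores are min-max rescaled to \[0,1\] and then divided by
#' their sum. This preserves each classifier's ranking and needs no
#' temperature choice. A constant score vector becomes the uniform
#' distribution.
#'
#' @param raw named numeric vector (candidate id -> score), all finite
#' @return named numeric distribution (non-negative, sums to 1), with
#'   attribute `normalized = TRUE`
#' @export
normalize_scores <- function(raw) {
  if (!length(raw)) stop_input("cannot normalize an empty score map")
  if (any(!is.finite(raw))) stop_input("scores must all be finite")
  rng <- range(raw)
  if (rng[1] == rng[2]) {
    out <- stats::setNames(rep(1 / length(raw), length(raw)), names(raw))
  } else {
    scaled <- (raw - rng[1]) / (rng[2] - rng[1])
    out <- scaled / sum(scaled)
  }
  attr(out, "normalized") <- TRUE
  out
}

#' Combine member distributions by weighted (Bayesian) averaging
#'
#' Convex combination of per-classifier candidate-score distributions:
#' member weights are renormalized to sum to one and the combined score of
#' candidate d is the weighted mean of the members' scores for d. All
#' members must be distributions over the same candidate set.
#'
#' @param members list of named numeric distributions (see
#'   [normalize_scores()])
#' @param weights numeric vector of non-negative member weights, not all
#'   zero; defaults to uniform
#' @return combined named numeric distribution
#' @export
bayesian_average <- function(members, weights = NULL) {
  if (!length(members)) stop_input("no member distributions supplied")
  if (is.null(weights)) weights <- rep(1, length(members))
  if (length(weights) != length(members)) {
    stop_input("weights length must match number of members")
  }
  if (any(weights < 0) || all(weights == 0)) {
    stop_input("weights must be non-negative and not all zero")
  }
  ref <- sort_c(names(members[[1]]))
  for (m in members) {
    if (!identical(sort_c(names(m)), ref)) {
      stop_input("member distributions are over different candidate sets")
    }
  }
  w <- weights / sum(weights)
  out <- stats::setNames(numeric(length(ref)), ref)
  for (k in seq_along(members)) {
    out <- out + w[k] * members[[k]][ref]
  }
  attr(out, "normalized") <- TRUE
  out
}
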