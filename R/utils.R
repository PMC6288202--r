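# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library code never perturbs the
#' caller's RNG stream. All stochastic operations in the package route
#' through this.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single non-missing integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# derive a child seed deterministically, kept below 2^31
derive_seed <- function(seed, salt) {
  h <- digest::digest(list(as.integer(seed), salt), algo = "xxhash32")
  as.integer(strtoi(substr(h, 1, 7), base = 16L))
}

stop_input <- function(...) stop(..., call. = FALSE)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop_input(sprintf("%s must be a single number in [%s, %s]",
                       name, format(lower), format(upper)))
  }
  invisible(x)
}

# order scores descending, ties broken by lexicographic id (C collation,
# so results do not depend on the session locale)
order_ranked <- function(ids, scores) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  order(-scores, ids, method = "radix")
}

sort_c <- function(x) sort(x, method = "radix")
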