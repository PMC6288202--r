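# Classifier backends for the machine-learning models.
#
# Every backend satisfies one contract: fit on (X, y) and, for any feature
# row, return a non-negative score per label summing to 1. Logistic
# regression is backed by glmnet and kNN by FNN; naive Bayes, random
# forest, extra trees and the small neural network are implemented here
# (feature columns take only the values 0 or ic(term), so tree splits are
# exact binary presence splits).

BACKEND_ALGORITHMS <- c("logistic_regression", "knn", "random_forest",
                        "extra_trees", "naive_bayes", "deep_neural_network")

#' Specify a classifier ensemble member
#'
#' @param algorithm one of `logistic_regression`, `knn`, `random_forest`,
#'   `extra_trees`, `naive_bayes`, `deep_neural_network`
#' @param hyperparameters named list overriding backend defaults:
#'   `lambda` (ridge penalty, logistic), `k` (neighbours), `ntree` and
#'   `min_node` (forests), `laplace` (naive Bayes), `hidden`, `epochs`,
#'   `learning_rate` (neural network)
#' @param seed integer seed for this member's private RNG stream
#' @return object of class `phenodx_classifier_spec`
#' @export
classifier_spec <- function(algorithm, hyperparameters = list(), seed = 1L) {
  algorithm <- match.arg(algorithm, BACKEND_ALGORITHMS)
  structure(list(algorithm = algorithm, hyperparameters = hyperparameters,
                 seed = as.integer(seed)),
            class = "phenodx_classifier_spec")
}

#' Default ensemble member specifications
#'
#' The six classifiers of the full machine-learning model, each with its
#' own derived seed.
#' @param seed base integer seed
#' @param algorithms subset of backend names (default all six)
#' @return list of `phenodx_classifier_spec`
#' @export
default_classifier_specs <- function(seed = 1L,
                                     algorithms = BACKEND_ALGORITHMS) {
  lapply(algorithms, function(a) {
    classifier_spec(a, seed = derive_seed(seed, a))
  })
}

fit_backend <- function(spec, X, y, label_set) {
  hp <- spec$hyperparameters
  fitter <- switch(spec$algorithm,
    logistic_regression = fit_logistic,
    knn = fit_knn,
    random_forest = function(X, y, hp) fit_forest(X, y, hp, extra = FALSE),
    extra_trees = function(X, y, hp) fit_forest(X, y, hp, extra = TRUE),
    naive_bayes = fit_nb,
    deep_neural_network = fit_mlp)
  model <- with_seed(spec$seed, fitter(X, y, hp))
  structure(list(spec = spec, model = model, label_set = label_set),
            class = "phenodx_member")
}

# rows x label_set matrix, each row a distribution
predict_member <- function(member, X) {
  P <- switch(member$spec$algorithm,
    logistic_regression = predict_logistic(member$model, X),
    knn = predict_knn(member$model, X),
    random_forest = ,
    extra_trees = predict_forest(member$model, X),
    naive_bayes = predict_nb(member$model, X),
    deep_neural_network = predict_mlp(member$model, X))
  out <- matrix(0, nrow(X), length(member$label_set),
                dimnames = list(rownames(X), member$label_set))
  out[, colnames(P)] <- P
  rs <- rowSums(out)
  flat <- rs <= 0
  if (any(flat)) out[flat, ] <- 1 / ncol(out)
  out[!flat, ] <- out[!flat, , drop = FALSE] / rs[!flat]
  out
}

# --- logistic regression (ridge multinomial via glmnet) ------------------

fit_logistic <- function(X, y, hp) {
  y <- droplevels(factor(y))
  # let glmnet build its own decreasing lambda path (a short custom path
  # makes the ridge coordinate descent diverge); predict at the path end
  # or at a user-supplied penalty inside the path
  fit <- withCallingHandlers(
    glmnet::glmnet(X, y, family = "multinomial", alpha = 0,
                   nlambda = hp$nlambda %||% 30L,
                   lambda.min.ratio = hp$lambda_min_ratio %||% 0.01,
                   standardize = FALSE),
    warning = function(w) {
      # desk-scale corpora always trip glmnet's small-class advisory
      if (grepl("fewer than 8", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  lambda <- hp$lambda %||% min(fit$lambda)
  list(fit = fit, lambda = lambda, levels = levels(y))
}

predict_logistic <- function(model, X) {
  P <- predict(model$fit, X, s = model$lambda, type = "response")[, , 1]
  if (is.null(dim(P))) P <- matrix(P, nrow = 1,
                                   dimnames = list(NULL, model$levels))
  P
}

# --- k-nearest neighbours (FNN) ------------------------------------------

fit_knn <- function(X, y, hp) {
  list(X = X, y = factor(y), k = hp$k %||% 5L)
}

predict_knn <- function(model, X) {
  k <- min(model$k, nrow(model$X))
  nn <- FNN::get.knnx(model$X, X, k = k)
  lv <- levels(model$y)
  P <- matrix(0, nrow(X), length(lv), dimnames = list(NULL, lv))
  w <- 1 / (nn$nn.dist + 1e-6)   # inverse-distance vote weights
  for (i in seq_len(nrow(X))) {
    lab <- model$y[nn$nn.index[i, ]]
    for (j in seq_len(k)) P[i, lab[j]] <- P[i, lab[j]] + w[i, j]
  }
  P / rowSums(P)
}

# --- Bernoulli naive Bayes ----------------------------------------------

fit_nb <- function(X, y, hp) {
  laplace <- hp$laplace %||% 1
  B <- X > 0
  y <- droplevels(factor(y))
  lv <- levels(y)
  nclass <- as.numeric(table(y))
  theta <- matrix(0, length(lv), ncol(X), dimnames = list(lv, colnames(X)))
  for (li in seq_along(lv)) {
    rows <- which(y == lv[li])
    theta[li, ] <- (colSums(B[rows, , drop = FALSE]) + laplace) /
      (length(rows) + 2 * laplace)
  }
  list(log_theta = log(theta), log_1m_theta = log(1 - theta),
       log_prior = log(nclass / sum(nclass)), levels = lv)
}

predict_nb <- function(model, X) {
  B <- (X > 0) * 1
  logp <- B %*% t(model$log_theta) + (1 - B) %*% t(model$log_1m_theta)
  logp <- sweep(logp, 2, model$log_prior, `+`)
  m <- apply(logp, 1, max)
  P <- exp(logp - m)
  P <- P / rowSums(P)
  colnames(P) <- model$levels
  P
}

# --- random forest / extra trees over binary presence splits -------------

# Grows one CART-style tree on binary features with Gini split search over
# `mtry` randomly drawn candidates. Nodes are rows of flat vectors; leaf
# distributions are class frequencies.
grow_tree <- function(B, yidx, n_labels, mtry, min_node, max_depth) {
  feat <- integer(0); left <- integer(0); right <- integer(0)
  dist <- list()
  new_node <- function() {
    feat[[length(feat) + 1L]] <<- NA_integer_
    left[[length(left) + 1L]] <<- 0L
    right[[length(right) + 1L]] <<- 0L
    dist[[length(dist) + 1L]] <<- NULL
    length(feat)
  }
  build <- function(rows, depth) {
    id <- new_node()
    counts <- tabulate(yidx[rows], n_labels)
    n <- length(rows)
    if (n < min_node || depth >= max_depth || sum(counts > 0) <= 1L) {
      dist[[id]] <<- counts / n
      return(id)
    }
    cand <- sample.int(ncol(B), min(mtry, ncol(B)))
    M <- B[rows, cand, drop = FALSE]
    n1 <- colSums(M)
    valid <- which(n1 > 0 & n1 < n)
    if (!length(valid)) {
      dist[[id]] <<- counts / n
      return(id)
    }
    # class counts on the presence side, per candidate feature
    Y <- matrix(0, n, n_labels); Y[cbind(seq_len(n), yidx[rows])] <- 1
    C1 <- crossprod(M[, valid, drop = FALSE], Y)       # |valid| x labels
    C0 <- matrix(counts, nrow(C1), n_labels, byrow = TRUE) - C1
    nn1 <- n1[valid]; nn0 <- n - nn1
    gini <- nn1 * (1 - rowSums(C1^2) / nn1^2) +
            nn0 * (1 - rowSums(C0^2) / nn0^2)
    best <- which.min(gini)
    f <- cand[valid[best]]
    go <- B[rows, f]
    feat[id] <<- f
    l <- build(rows[!go], depth + 1L); left[id] <<- l
    r <- build(rows[go], depth + 1L); right[id] <<- r
    id
  }
  build(seq_along(yidx), 0L)
  list(feat = feat, left = left, right = right, dist = dist)
}

fit_forest <- function(X, y, hp, extra = FALSE) {
  ntree <- hp$ntree %||% 50L
  min_node <- hp$min_node %||% 2L
  max_depth <- hp$max_depth %||% 25L
  y <- droplevels(factor(y))
  lv <- levels(y)
  yidx <- as.integer(y)
  B <- X > 0
  mtry <- hp$mtry %||% max(1L, floor(sqrt(ncol(X))))
  if (extra) mtry <- max(1L, floor(mtry / 2))  # extra randomisation
  trees <- lapply(seq_len(ntree), function(t) {
    rows <- if (extra) seq_len(nrow(B)) else
      sample.int(nrow(B), nrow(B), replace = TRUE)
    grow_tree(B[rows, , drop = FALSE], yidx[rows], length(lv),
              mtry, min_node, max_depth)
  })
  list(trees = trees, levels = lv)
}

predict_forest <- function(model, X) {
  B <- X > 0
  lv <- model$levels
  acc <- matrix(0, nrow(X), length(lv), dimnames = list(NULL, lv))
  for (tree in model$trees) {
    route <- function(node, rows) {
      if (is.na(tree$feat[node])) {
        acc[rows, ] <<- acc[rows, , drop = FALSE] +
          matrix(tree$dist[[node]], length(rows), length(lv), byrow = TRUE)
        return(invisible())
      }
      go <- B[rows, tree$feat[node]]
      if (any(!go)) route(tree$left[node], rows[!go])
      if (any(go)) route(tree$right[node], rows[go])
    }
    route(1L, seq_len(nrow(B)))
  }
  acc / length(model$trees)
}

# --- small feed-forward neural network ----------------------------------

# One hidden tanh layer sized min(hidden, n_features), softmax output,
# full-batch Adam on the cross-entropy. Desk-scale by design.
fit_mlp <- function(X, y, hp) {
  y <- droplevels(factor(y))
  lv <- levels(y)
  n <- nrow(X); p <- ncol(X); L <- length(lv)
  H <- min(hp$hidden %||% 256L, p)
  epochs <- hp$epochs %||% 150L
  lr <- hp$learning_rate %||% 0.01
  W1 <- matrix(stats::rnorm(p * H, sd = 1 / sqrt(p)), p, H)
  b1 <- numeric(H)
  W2 <- matrix(stats::rnorm(H * L, sd = 1 / sqrt(H)), H, L)
  b2 <- numeric(L)
  Y <- matrix(0, n, L); Y[cbind(seq_len(n), as.integer(y))] <- 1
  # Adam state
  ms <- list(W1 = W1 * 0, b1 = b1 * 0, W2 = W2 * 0, b2 = b2 * 0)
  vs <- ms
  b1a <- 0.9; b2a <- 0.999; eps <- 1e-8
  for (it in seq_len(epochs)) {
    A1 <- tanh(sweep(X %*% W1, 2, b1, `+`))
    Z2 <- sweep(A1 %*% W2, 2, b2, `+`)
    Z2 <- Z2 - apply(Z2, 1, max)
    P <- exp(Z2); P <- P / rowSums(P)
    D2 <- (P - Y) / n
    gW2 <- crossprod(A1, D2); gb2 <- colSums(D2)
    D1 <- (D2 %*% t(W2)) * (1 - A1^2)
    gW1 <- crossprod(X, D1); gb1 <- colSums(D1)
    g <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
    for (nm in names(g)) {
      ms[[nm]] <- b1a * ms[[nm]] + (1 - b1a) * g[[nm]]
      vs[[nm]] <- b2a * vs[[nm]] + (1 - b2a) * g[[nm]]^2
      mhat <- ms[[nm]] / (1 - b1a^it)
      vhat <- vs[[nm]] / (1 - b2a^it)
      delta <- lr * mhat / (sqrt(vhat) + eps)
      if (nm == "W1") W1 <- W1 - delta
      if (nm == "b1") b1 <- b1 - delta
      if (nm == "W2") W2 <- W2 - delta
      if (nm == "b2") b2 <- b2 - delta
    }
  }
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, levels = lv)
}

predict_mlp <- function(model, X) {
  A1 <- tanh(sweep(X %*% model$W1, 2, model$b1, `+`))
  Z2 <- sweep(A1 %*% model$W2, 2, model$b2, `+`)
  Z2 <- Z2 - apply(Z2, 1, max)
  P <- exp(Z2); P <- P / rowSums(P)
  colnames(P) <- model$levels
  P
}
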