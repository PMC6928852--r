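# Shared label handling: AAMI data keeps the fixed N,V,S,F,Q order; other
# label sets (unit-test toys) fall back to sorted unique values.
class_levels <- function(y) {
  if (is.factor(y)) return(levels(y))
  u <- unique(as.character(y))
  aami <- aami_classes("five_class")
  if (all(u %in% aami)) aami[aami %in% u] else sort(u)
}

entropy_bits <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

as_feature_matrix <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

# Best binary split of one sorted feature by class-entropy gain.
# Returns NULL when no candidate improves on the parent entropy.
best_split_1d <- function(xs, ymat_sorted) {
  n <- nrow(ymat_sorted)
  if (n < 2) return(NULL)
  cum <- apply(ymat_sorted, 2, cumsum)
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = n)
  total <- cum[n, ]
  cand <- which(diff(xs) > 0)            # split between i and i+1
  if (!length(cand)) return(NULL)
  left <- cum[cand, , drop = FALSE]
  right <- rep(1, length(cand)) %o% total - left
  nl <- rowSums(left); nr <- n - nl
  ent <- function(m, tot) {
    p <- m / pmax(tot, 1)
    rowSums(ifelse(p > 0, -p * log2(p), 0))
  }
  parent <- entropy_bits(total)
  child <- (nl * ent(left, nl) + nr * ent(right, nr)) / n
  gain <- parent - child
  best <- which.max(gain)
  if (gain[best] <= 1e-12) return(NULL)
  i <- cand[best]
  list(threshold = (xs[i] + xs[i + 1]) / 2, gain = gain[best],
       left_entropy = ent(left[best, , drop = FALSE], nl[best]),
       right_entropy = ent(right[best, , drop = FALSE], nr[best]),
       n_left = nl[best], n_right = nr[best],
       k_left = sum(left[best, ] > 0), k_right = sum(right[best, ] > 0),
       parent_entropy = parent, k_parent = sum(total > 0))
}

#' Entropy/MDL supervised discretization
#'
#' Per-feature recursive binary splitting on class-entropy gain with the
#' minimum-description-length stopping criterion: a candidate cut is kept
#' only when its information gain exceeds
#' `(log2(N-1) + log2(3^k - 2) - k*Ent(S) + k1*Ent(S1) + k2*Ent(S2)) / N`.
#' Features where no cut is ever accepted end up with an empty cut list
#' (a single bin, i.e. uninformative).
#'
#' @param X Numeric feature matrix or data.frame (instances x features).
#' @param y Class labels (at least two distinct classes).
#' @return A `discretization_map`: list with `cuts` (one increasing numeric
#'   vector per feature) and `feature_names`.
#' @export
mdl_discretize <- function(X, y) {
  X <- as_feature_matrix(X)
  y <- as.character(y)
  lev <- class_levels(y)
  if (length(unique(y)) < 2) stop("degenerate labels: need at least 2 classes")
  ymat <- outer(y, lev, "==") * 1

  cuts_for <- function(ord_x, ord_y) {
    n <- length(ord_x)
    sp <- best_split_1d(ord_x, ord_y)
    if (is.null(sp)) return(numeric())
    k <- sp$k_parent
    delta <- log2(3^k - 2) - (k * sp$parent_entropy -
                              sp$k_left * sp$left_entropy -
                              sp$k_right * sp$right_entropy)
    if (sp$gain <= (log2(n - 1) + delta) / n) return(numeric())
    lhs <- ord_x <= sp$threshold
    c(cuts_for(ord_x[lhs], ord_y[lhs, , drop = FALSE]),
      sp$threshold,
      cuts_for(ord_x[!lhs], ord_y[!lhs, , drop = FALSE]))
  }

  cuts <- lapply(seq_len(ncol(X)), function(j) {
    o <- order(X[, j])
    sort(cuts_for(X[o, j], ymat[o, , drop = FALSE]))
  })
  structure(list(cuts = cuts, feature_names = colnames(X)),
            class = "discretization_map")
}

#' @rdname mdl_discretize
#' @param map A `discretization_map`.
#' @return (`apply_discretization`) Integer matrix of bin indices, one
#'   column per feature, values in `1..(length(cuts) + 1)`.
#' @export
apply_discretization <- function(map, X) {
  X <- as_feature_matrix(X)
  out <- vapply(seq_len(ncol(X)), function(j)
    findInterval(X[, j], map$cuts[[j]]) + 1L,
    integer(nrow(X)))
  matrix(out, nrow = nrow(X))
}

#' Train a naive Bayes classifier
#'
#' With `discretize = TRUE` (the configuration used throughout this
#' package) features are first binned by [mdl_discretize()] and class
#' likelihoods are Laplace-smoothed per-bin frequencies; the posterior is
#' the normalized product of the per-feature likelihoods and the class
#' prior. With `discretize = FALSE` a per-feature Gaussian model is used
#' instead (no kernel estimator).
#'
#' @param X Numeric feature matrix (instances x features).
#' @param y Class labels.
#' @param discretize Use supervised discretization (default `TRUE`).
#' @return A `trained_model` of kind `"naive_bayes"`.
#' @export
train_naive_bayes <- function(X, y, discretize = TRUE) {
  X <- as_feature_matrix(X)
  y <- as.character(y)
  lev <- class_levels(y)
  if (length(unique(y)) < 1) stop("degenerate labels")
  priors <- stats::setNames(as.numeric(table(factor(y, lev))) / length(y), lev)

  if (discretize && length(unique(y)) >= 2) {
    map <- mdl_discretize(X, y)
    B <- apply_discretization(map, X)
    tables <- lapply(seq_len(ncol(X)), function(j) {
      nb <- length(map$cuts[[j]]) + 1L
      cnt <- matrix(0, nrow = length(lev), ncol = nb,
                    dimnames = list(lev, NULL))
      tab <- table(factor(y, lev), factor(B[, j], seq_len(nb)))
      cnt[, ] <- as.numeric(tab)
      log((cnt + 1) / (rowSums(cnt) + nb))    # Laplace smoothing
    })
    model <- list(kind = "naive_bayes", mode = "discrete", map = map,
                  tables = tables, class_order = lev, priors = priors)
  } else {
    mu <- matrix(unlist(lapply(lev, function(k)
      colMeans(X[y == k, , drop = FALSE]))), length(lev), ncol(X),
      byrow = TRUE)
    sig <- matrix(unlist(lapply(lev, function(k) {
      s <- apply(X[y == k, , drop = FALSE], 2, stats::sd)
      pmax(ifelse(is.na(s), 0, s), 1e-9)
    })), length(lev), ncol(X), byrow = TRUE)
    model <- list(kind = "naive_bayes", mode = "gaussian", mu = mu, sig = sig,
                  class_order = lev, priors = priors)
  }
  structure(model, class = c("nb_model", "trained_model"))
}

#' Train a (regularized) Gaussian discriminant classifier
#'
#' Linear (`kind = "lda"`, pooled covariance) or quadratic (`kind = "qda"`,
#' per-class covariance) discriminant analysis. `ridge * I` is added to
#' every covariance matrix before inversion to keep near-singular estimates
#' invertible; the default `1e-6` matches common toolbox practice.
#'
#' @param X Numeric feature matrix.
#' @param y Class labels; every class needs at least 2 instances.
#' @param kind `"lda"` or `"qda"`.
#' @param ridge Diagonal regularization added to covariances.
#' @return A `trained_model` of the requested kind.
#' @export
train_discriminant <- function(X, y, kind = c("lda", "qda"), ridge = 1e-6) {
  kind <- match.arg(kind)
  X <- as_feature_matrix(X)
  y <- as.character(y)
  lev <- class_levels(y)
  nk <- table(factor(y, lev))
  if (any(nk < 2))
    stop("every class needs at least 2 instances for covariance estimation")
  d <- ncol(X)
  priors <- stats::setNames(as.numeric(nk) / length(y), lev)
  mu <- matrix(unlist(lapply(lev, function(k)
    colMeans(X[y == k, , drop = FALSE]))), length(lev), d, byrow = TRUE)
  covs <- lapply(lev, function(k) stats::cov(X[y == k, , drop = FALSE]))
  names(covs) <- lev
  if (kind == "lda") {
    pooled <- Reduce(`+`, lapply(lev, function(k) (nk[[k]] - 1) * covs[[k]])) /
      (length(y) - length(lev))
    covs <- stats::setNames(rep(list(pooled), length(lev)), lev)
  }
  prec <- lapply(covs, function(S) {
    S <- S + diag(ridge, d)
    ch <- chol(S)
    list(inv = chol2inv(ch), logdet = 2 * sum(log(diag(ch))))
  })
  structure(list(kind = kind, mu = mu, prec = prec,
                 class_order = lev, priors = priors, ridge = ridge),
            class = c("da_model", "trained_model"))
}

# --- information-gain decision tree ----------------------------------------

grow_tree <- function(X, y_idx, idx, lev, min_objects, ymat) {
  counts <- colSums(ymat[idx, , drop = FALSE])
  leaf <- function() list(leaf = TRUE,
                          posterior = (counts + 1) / (sum(counts) + length(lev)))
  if (length(idx) < min_objects || sum(counts > 0) < 2) return(leaf())
  best <- NULL
  for (j in seq_len(ncol(X))) {
    o <- idx[order(X[idx, j])]
    sp <- best_split_1d(X[o, j], ymat[o, , drop = FALSE])
    if (!is.null(sp) && (is.null(best) || sp$gain > best$gain)) {
      best <- sp
      best$feature <- j
    }
  }
  if (is.null(best)) return(leaf())
  lhs <- X[idx, best$feature] <= best$threshold
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       left = grow_tree(X, y_idx, idx[lhs], lev, min_objects, ymat),
       right = grow_tree(X, y_idx, idx[!lhs], lev, min_objects, ymat))
}

# Consolidated growth: each class-balanced subsample proposes its best
# (feature, threshold); the majority feature wins and the median of that
# feature's proposed thresholds is used; every subsample is partitioned
# identically. Stopping follows the full-data node size.
grow_consolidated <- function(X, idx_full, subs, lev, min_objects, ymat) {
  counts <- colSums(ymat[idx_full, , drop = FALSE])
  leaf <- function() list(leaf = TRUE,
                          posterior = (counts + 1) / (sum(counts) + length(lev)))
  if (length(idx_full) < min_objects || sum(counts > 0) < 2) return(leaf())
  proposals <- lapply(subs, function(s) {
    if (length(s) < 2) return(NULL)
    best <- NULL
    for (j in seq_len(ncol(X))) {
      o <- s[order(X[s, j])]
      sp <- best_split_1d(X[o, j], ymat[o, , drop = FALSE])
      if (!is.null(sp) && (is.null(best) || sp$gain > best$gain)) {
        best <- sp
        best$feature <- j
      }
    }
    best
  })
  feats <- vapply(proposals, function(p) if (is.null(p)) NA_integer_
                  else p$feature, integer(1))
  if (all(is.na(feats))) return(leaf())
  tab <- table(feats)
  top <- as.integer(names(tab)[tab == max(tab)])
  winner <- min(top)                                # ties: smallest index
  thr <- stats::median(vapply(
    proposals[!is.na(feats) & feats == winner], `[[`, numeric(1), "threshold"))
  lhs_full <- X[idx_full, winner] <= thr
  subs_l <- lapply(subs, function(s) s[X[s, winner] <= thr])
  subs_r <- lapply(subs, function(s) s[X[s, winner] > thr])
  list(leaf = FALSE, feature = winner, threshold = thr,
       left = grow_consolidated(X, idx_full[lhs_full], subs_l, lev,
                                min_objects, ymat),
       right = grow_consolidated(X, idx_full[!lhs_full], subs_r, lev,
                                 min_objects, ymat))
}

#' Train an information-gain decision tree (plain or consolidated)
#'
#' An axis-aligned binary tree in the C4.5 family: each split maximizes the
#' class-entropy reduction, nodes with fewer than `min_objects` instances or
#' no positive-gain split become leaves, and leaf posteriors are
#' Laplace-smoothed class frequencies. With `consolidated = TRUE` the tree
#' structure is voted by `n_subsamples` class-balanced bootstrap subsamples
#' (majority feature, median threshold) and the final leaf posteriors come
#' from the full training data routed through the consolidated structure —
#' the consolidation counteracts class imbalance without giving up a single
#' interpretable tree.
#'
#' @param X Numeric feature matrix.
#' @param y Class labels.
#' @param min_objects Minimum instances for a node to be split (default
#'   1000, the capacity control used at full-database scale).
#' @param consolidated Build the subsample-voted variant.
#' @param n_subsamples Number of class-balanced bootstrap subsamples.
#' @param seed Seed for the subsample draws.
#' @return A `trained_model` of kind `"tree"` or `"consolidated_tree"`.
#' @export
train_tree <- function(X, y, min_objects = 1000, consolidated = FALSE,
                       n_subsamples = 10, seed = 1) {
  stopifnot(min_objects >= 1)
  X <- as_feature_matrix(X)
  y <- as.character(y)
  lev <- class_levels(y)
  ymat <- outer(y, lev, "==") * 1
  n <- nrow(X)
  priors <- stats::setNames(as.numeric(table(factor(y, lev))) / n, lev)

  if (!consolidated) {
    root <- grow_tree(X, y, seq_len(n), lev, min_objects, ymat)
    kind <- "tree"
  } else {
    per_class <- ceiling(n / length(lev))
    subs <- with_local_seed(seed, {
      lapply(seq_len(n_subsamples), function(i)
        unlist(lapply(lev, function(k) {
          pool <- which(y == k)
          if (!length(pool)) return(integer())
          sample(pool, per_class, replace = TRUE)
        })))
    })
    root <- grow_consolidated(X, seq_len(n), subs, lev, min_objects, ymat)
    kind <- "consolidated_tree"
  }
  structure(list(kind = kind, root = root, class_order = lev, priors = priors,
                 min_objects = min_objects),
            class = c("tree_model", "trained_model"))
}

# --- posterior prediction ---------------------------------------------------

softmax_rows <- function(logp) {
  m <- apply(logp, 1, max)
  e <- exp(logp - m)
  e / rowSums(e)
}

#' Class posterior probabilities of a trained model
#'
#' @param object A `trained_model`.
#' @param X Numeric feature matrix.
#' @param ... Unused.
#' @return Matrix (instances x classes) of posteriors; rows sum to 1.
#' @export
posterior <- function(object, X, ...) UseMethod("posterior")

#' @export
posterior.nb_model <- function(object, X, ...) {
  X <- as_feature_matrix(X)
  lev <- object$class_order
  logp <- matrix(log(pmax(object$priors, 1e-300)), nrow(X), length(lev),
                 byrow = TRUE)
  if (object$mode == "discrete") {
    B <- apply_discretization(object$map, X)
    for (j in seq_len(ncol(X))) {
      nb <- ncol(object$tables[[j]])
      b <- pmin(pmax(B[, j], 1L), nb)
      logp <- logp + t(object$tables[[j]][, b, drop = FALSE])
    }
  } else {
    for (k in seq_along(lev))
      logp[, k] <- logp[, k] + rowSums(stats::dnorm(
        X, mean = rep(object$mu[k, ], each = nrow(X)),
        sd = rep(object$sig[k, ], each = nrow(X)), log = TRUE))
  }
  out <- softmax_rows(logp)
  colnames(out) <- lev
  out
}

#' @export
posterior.da_model <- function(object, X, ...) {
  X <- as_feature_matrix(X)
  lev <- object$class_order
  logp <- vapply(seq_along(lev), function(k) {
    d <- sweep(X, 2, object$mu[k, ])
    maha <- rowSums((d %*% object$prec[[k]]$inv) * d)
    log(object$priors[k]) - 0.5 * (object$prec[[k]]$logdet + maha)
  }, numeric(nrow(X)))
  out <- softmax_rows(matrix(logp, nrow = nrow(X)))
  colnames(out) <- lev
  out
}

#' @export
posterior.tree_model <- function(object, X, ...) {
  X <- as_feature_matrix(X)
  out <- matrix(NA_real_, nrow(X), length(object$class_order))
  route <- function(node, idx) {
    if (!length(idx)) return()
    if (node$leaf) {
      out[idx, ] <<- rep(node$posterior, each = length(idx))
      return()
    }
    lhs <- X[idx, node$feature] <= node$threshold
    route(node$left, idx[lhs])
    route(node$right, idx[!lhs])
  }
  route(object$root, seq_len(nrow(X)))
  colnames(out) <- object$class_order
  out
}

#' Posterior matrices from several classifiers
#'
#' @param models List of `trained_model`s sharing a class order.
#' @param X Numeric feature matrix.
#' @return A `posterior_set`: list of posterior matrices plus the shared
#'   `class_order`.
#' @export
predict_posteriors <- function(models, X) {
  orders <- lapply(models, `[[`, "class_order")
  if (!all(vapply(orders, identical, logical(1), orders[[1]])))
    stop("class-order mismatch across models")
  structure(list(per_classifier = lapply(models, function(m) posterior(m, X)),
                 class_order = orders[[1]]),
            class = "posterior_set")
}

#' Combine classifier posteriors with the product rule
#'
#' The product-rule fusion of R classifiers assigns each instance to the
#' class maximizing `P(w_k)^-(R-1) * prod_i P(w_k | x_i)`: under the
#' assumption that the classifiers' representations are conditionally
#' independent, the product of posteriors over-counts the prior R times, so
#' one factor is kept and R-1 divided back out. Posteriors are floored at
#' `floor` before the product so that a single classifier emitting an exact
#' zero cannot veto a class outright. Ties break by the fixed class order.
#'
#' @param posteriors A `posterior_set` from [predict_posteriors()].
#' @param priors Strictly positive per-class priors summing to 1 (named by
#'   class); typically the training-set class frequencies.
#' @param floor Lower bound applied to each posterior entry (default 1e-6).
#' @return Character vector of predicted class labels.
#' @export
product_rule_combine <- function(posteriors, priors, floor = 1e-6) {
  stopifnot(inherits(posteriors, "posterior_set"), floor >= 0)
  lev <- posteriors$class_order
  priors <- priors[lev]
  if (any(priors <= 0)) stop("priors must be strictly positive")
  R <- length(posteriors$per_classifier)
  n <- nrow(posteriors$per_classifier[[1]])
  score <- matrix(-(R - 1) * log(priors), n, length(lev), byrow = TRUE)
  for (P in posteriors$per_classifier)
    score <- score + log(pmax(P[, lev, drop = FALSE], floor))
  lev[max.col(score, ties.method = "first")]
}

#' Classifier line-ups of the four voting methods
#'
#' The four ensembles evaluated in this package, each fusing three
#' probabilistic classifiers with the product rule: method-1 = tree + LDA +
#' naive Bayes; method-2 = tree + QDA + naive Bayes; method-3 =
#' consolidated tree + QDA + naive Bayes; method-4 = consolidated tree +
#' LDA + naive Bayes.
#'
#' @param combo_id One of `"method1".."method4"`.
#' @return Character vector of classifier kinds.
#' @export
make_voting_ensemble <- function(combo_id) {
  combos <- list(
    method1 = c("tree", "lda", "naive_bayes"),
    method2 = c("tree", "qda", "naive_bayes"),
    method3 = c("consolidated_tree", "qda", "naive_bayes"),
    method4 = c("consolidated_tree", "lda", "naive_bayes"))
  if (!combo_id %in% names(combos))
    stop("unknown voting method: ", combo_id)
  combos[[combo_id]]
}

#' Train a product-rule voting ensemble
#'
#' Fits every constituent classifier of the chosen method on the same
#' training data with the package's standard hyperparameters (supervised
#' discretization for naive Bayes, ridge 1e-6 for the discriminants,
#' `min_objects` capacity control for the trees) and records the training
#' class frequencies as the fusion priors.
#'
#' @param X Numeric feature matrix (typically 36 columns).
#' @param y AAMI class labels.
#' @param method `"method1".."method4"`, see [make_voting_ensemble()].
#' @param min_objects Tree capacity control (default 1000).
#' @param ridge Discriminant regularization (default 1e-6).
#' @param n_subsamples Consolidated-tree subsample count.
#' @param seed Seed for the consolidated-tree subsampling.
#' @return A `voting_ensemble` with fields `models`, `class_order`,
#'   `priors`, `method`.
#' @export
train_voting_ensemble <- function(X, y, method = "method1",
                                  min_objects = 1000, ridge = 1e-6,
                                  n_subsamples = 10, seed = 1) {
  kinds <- make_voting_ensemble(method)
  models <- lapply(kinds, function(kind) {
    switch(kind,
      naive_bayes = train_naive_bayes(X, y, discretize = TRUE),
      lda = train_discriminant(X, y, kind = "lda", ridge = ridge),
      qda = train_discriminant(X, y, kind = "qda", ridge = ridge),
      tree = train_tree(X, y, min_objects = min_objects),
      consolidated_tree = train_tree(X, y, min_objects = min_objects,
                                     consolidated = TRUE,
                                     n_subsamples = n_subsamples,
                                     seed = seed))
  })
  structure(list(models = models, class_order = models[[1]]$class_order,
                 priors = models[[1]]$priors, method = method),
            class = "voting_ensemble")
}

#' @rdname train_voting_ensemble
#' @param ensemble A `voting_ensemble`.
#' @param floor Posterior floor for the product rule.
#' @return (`predict_voting_ensemble`) Character vector of predicted labels.
#' @export
predict_voting_ensemble <- function(ensemble, X, floor = 1e-6) {
  stopifnot(inherits(ensemble, "voting_ensemble"))
  ps <- predict_posteriors(ensemble$models, X)
  product_rule_combine(ps, ensemble$priors, floor = floor)
}
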