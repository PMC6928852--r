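make_two_gaussians <- function(n, mu = 3, sd = 1, seed = 1) {
  set.seed(seed)
  x <- c(rnorm(n / 2, -mu, sd), rnorm(n / 2, mu, sd))
  y <- rep(c("A", "B"), each = n / 2)
  list(X = matrix(x, ncol = 1), y = y)
}

test_that("MDL discretization finds the separating cut and nothing spurious", {
  # constant feature: zero gain everywhere, no cuts
  X <- cbind(const = rep(1, 100), x = c(rnorm(50, -2), rnorm(50, 2)))
  y <- rep(c("A", "B"), each = 50)
  map <- mdl_discretize(X, y)
  expect_length(map$cuts[[1]], 0)

  # perfectly separated at 0: exactly one cut near 0, matching the
  # exhaustive entropy-gain scan
  set.seed(2)
  x <- c(runif(200, -3, -0.1), runif(200, 0.1, 3))
  y2 <- rep(c("neg", "pos"), each = 200)
  map2 <- mdl_discretize(matrix(x, ncol = 1), y2)
  expect_length(map2$cuts[[1]], 1)
  oracle <- brute_best_split(x, y2)
  expect_equal(map2$cuts[[1]], oracle$threshold)
  expect_lt(abs(map2$cuts[[1]]), 0.15)

  # cut lists are strictly increasing
  set.seed(3)
  X3 <- matrix(rnorm(900), ncol = 3)
  y3 <- sample(c("A", "B", "C"), 300, replace = TRUE,
               prob = c(0.5, 0.3, 0.2))
  X3[, 1] <- X3[, 1] + 2 * (y3 == "B") - 2 * (y3 == "C")
  map3 <- mdl_discretize(X3, y3)
  for (cuts in map3$cuts)
    if (length(cuts) > 1) expect_true(all(diff(cuts) > 0))

  expect_error(mdl_discretize(X3, rep("A", 300)), "degenerate")
})

test_that("discretized naive Bayes learns separable classes", {
  d <- make_two_gaussians(2000, seed = 7)
  ho <- make_two_gaussians(1000, seed = 8)
  nb <- train_naive_bayes(d$X, d$y, discretize = TRUE)
  post <- posterior(nb, ho$X)
  expect_equal(unname(rowSums(post)), rep(1, 1000), tolerance = 1e-9)
  acc <- mean(colnames(post)[max.col(post)] == ho$y)
  expect_gt(acc, 0.95)
})

test_that("single-class naive Bayes is certain", {
  X <- matrix(rnorm(20), ncol = 2)
  nb <- train_naive_bayes(X, rep("N", 10))
  post <- posterior(nb, matrix(rnorm(6), ncol = 2))
  expect_equal(unname(post[, "N"]), rep(1, 3))
})

test_that("LDA places the boundary at the midpoint of symmetric classes", {
  set.seed(5)
  n <- 400
  X <- rbind(matrix(rnorm(n, -2), ncol = 2), matrix(rnorm(n, 2), ncol = 2))
  y <- rep(c("A", "B"), each = n / 2)
  m <- train_discriminant(X, y, kind = "lda")
  # posterior at the midpoint of the class means is 1/2 each
  mid <- matrix(colMeans(m$mu), nrow = 1)
  expect_equal(unname(posterior(m, mid)[1, ]), c(0.5, 0.5), tolerance = 0.02)
  # symmetric probes classify by side
  probes <- matrix(c(-1, -1, 1, 1), 2, byrow = TRUE)
  post <- posterior(m, probes)
  expect_gt(post[1, "A"], 0.5)
  expect_gt(post[2, "B"], 0.5)
})

test_that("discriminant posteriors agree with an independent implementation", {
  skip_if_not_installed("MASS")
  set.seed(12)
  X <- rbind(matrix(rnorm(300, 0), ncol = 3),
             matrix(rnorm(300, 3), ncol = 3))
  y <- rep(c("A", "B"), each = 100)
  ours <- train_discriminant(X, y, kind = "lda", ridge = 0)
  ref <- MASS::lda(X, grouping = y)
  Xnew <- rbind(matrix(rnorm(60, 0), ncol = 3), matrix(rnorm(60, 3), ncol = 3))
  p_ours <- posterior(ours, Xnew)
  p_ref <- predict(ref, Xnew)$posterior
  expect_equal(unname(p_ours), unname(p_ref[, colnames(p_ours)]),
               tolerance = 1e-4)

  ours_q <- train_discriminant(X, y, kind = "qda", ridge = 0)
  ref_q <- MASS::qda(X, grouping = y)
  expect_equal(unname(posterior(ours_q, Xnew)),
               unname(predict(ref_q, Xnew)$posterior[, ours_q$class_order]),
               tolerance = 1e-4)
})

test_that("QDA approaches the numerically integrated Bayes rate", {
  mu1 <- c(0, 0); mu2 <- c(2, 1)
  s1 <- c(1, 1); s2 <- c(2, 0.5)   # axis-aligned sds
  set.seed(17)
  n <- 5000
  X <- rbind(cbind(rnorm(n / 2, mu1[1], s1[1]), rnorm(n / 2, mu1[2], s1[2])),
             cbind(rnorm(n / 2, mu2[1], s2[1]), rnorm(n / 2, mu2[2], s2[2])))
  y <- rep(c("A", "B"), each = n / 2)
  m <- train_discriminant(X, y, kind = "qda")

  # Bayes accuracy by grid quadrature over the two known densities
  gx <- seq(-7, 9, by = 0.04); gy <- seq(-6, 7, by = 0.04)
  f1 <- outer(stats::dnorm(gx, mu1[1], s1[1]), stats::dnorm(gy, mu1[2], s1[2]))
  f2 <- outer(stats::dnorm(gx, mu2[1], s2[1]), stats::dnorm(gy, mu2[2], s2[2]))
  bayes <- sum(pmax(0.5 * f1, 0.5 * f2)) * 0.04^2

  set.seed(18)
  nh <- 4000
  Xh <- rbind(cbind(rnorm(nh / 2, mu1[1], s1[1]), rnorm(nh / 2, mu1[2], s1[2])),
              cbind(rnorm(nh / 2, mu2[1], s2[1]), rnorm(nh / 2, mu2[2], s2[2])))
  yh <- rep(c("A", "B"), each = nh / 2)
  acc <- mean(colnames(posterior(m, Xh))[max.col(posterior(m, Xh))] == yh)
  expect_lt(abs(acc - bayes), 0.02)

  expect_error(train_discriminant(matrix(rnorm(6), ncol = 2),
                                  c("A", "A", "B"), kind = "qda"),
               "at least 2")
})

test_that("tree splits match the exhaustive gain scan", {
  # perfectly separated 1-D data: root threshold between the closest
  # opposite-class points
  set.seed(21)
  x <- c(runif(30, -4, -1), runif(30, 1, 4))
  y <- rep(c("L", "Rg"), each = 30)
  tr <- train_tree(matrix(x, ncol = 1), y, min_objects = 1)
  expect_false(tr$root$leaf)
  expect_gt(tr$root$threshold, max(x[y == "L"]))
  expect_lt(tr$root$threshold, min(x[y == "Rg"]))

  # random data: root (feature, threshold) equals brute force
  set.seed(22)
  X <- matrix(rnorm(200), ncol = 2)
  y2 <- ifelse(X[, 1] + 0.3 * rnorm(100) > 0, "P", "Nn")
  tr2 <- train_tree(X, y2, min_objects = 5)
  o1 <- brute_best_split(X[, 1], y2)
  o2 <- brute_best_split(X[, 2], y2)
  best_feature <- if (o1$gain >= o2$gain) 1L else 2L
  expect_identical(tr2$root$feature, best_feature)
  expect_equal(tr2$root$threshold,
               (if (best_feature == 1) o1 else o2)$threshold)
})

test_that("an oversized min_objects yields a prior-predicting single leaf", {
  set.seed(23)
  X <- matrix(rnorm(60), ncol = 2)
  y <- sample(c("A", "B", "C"), 30, replace = TRUE)
  tr <- train_tree(X, y, min_objects = 1000)
  expect_true(tr$root$leaf)
  post <- posterior(tr, X[1:3, , drop = FALSE])
  counts <- table(factor(y, tr$class_order))
  laplace <- (as.numeric(counts) + 1) / (30 + 3)
  expect_equal(unname(post[1, ]), laplace)
})

test_that("consolidated trees are deterministic and learn separable data", {
  set.seed(25)
  n <- 300
  X <- cbind(c(rnorm(n / 2, -2), rnorm(n / 2, 2)), rnorm(n))
  y <- rep(c("A", "B"), each = n / 2)
  t1 <- train_tree(X, y, min_objects = 20, consolidated = TRUE, seed = 4)
  t2 <- train_tree(X, y, min_objects = 20, consolidated = TRUE, seed = 4)
  expect_identical(t1, t2)
  expect_identical(t1$kind, "consolidated_tree")
  pred <- colnames(posterior(t1, X))[max.col(posterior(t1, X))]
  expect_gt(mean(pred == y), 0.9)
})

test_that("posterior sets are well-formed and consistent with the models", {
  d <- make_two_gaussians(400, seed = 31)
  models <- list(train_naive_bayes(d$X, d$y),
                 train_discriminant(d$X, d$y, kind = "lda"))
  ps <- predict_posteriors(models, d$X)
  expect_length(ps$per_classifier, 2)
  for (P in ps$per_classifier)
    expect_equal(unname(rowSums(P)), rep(1, 400), tolerance = 1e-9)
  expect_equal(ps$per_classifier[[2]], posterior(models[[2]], d$X))

  single <- predict_posteriors(models[1], d$X)
  expect_length(single$per_classifier, 1)

  bad <- train_naive_bayes(d$X, rep(c("X1", "X2"), each = 200))
  expect_error(predict_posteriors(list(models[[1]], bad), d$X), "mismatch")
})

test_that("product rule reduces, combines and floors correctly", {
  lev <- c("A", "B")
  mk <- function(m) structure(list(per_classifier = list(m), class_order = lev),
                              class = "posterior_set")
  # R = 1: plain argmax (prior exponent zero)
  P <- matrix(c(0.6, 0.3, 0.4, 0.7), 2, dimnames = list(NULL, lev))
  pri <- c(A = 0.2, B = 0.8)
  expect_equal(product_rule_combine(mk(P), pri), c("A", "B"))

  # R = 2, equal priors, hand-evaluated product: 0.4*0.7 > 0.6*0.3
  two <- structure(list(per_classifier = list(
    matrix(c(0.6, 0.4), 1, dimnames = list(NULL, lev)),
    matrix(c(0.3, 0.7), 1, dimnames = list(NULL, lev))),
    class_order = lev), class = "posterior_set")
  expect_equal(product_rule_combine(two, c(A = 0.5, B = 0.5)), "B")

  # a zero posterior with a positive floor is not a veto
  vet <- structure(list(per_classifier = list(
    matrix(c(0, 1), 1, dimnames = list(NULL, lev)),
    matrix(c(0.99, 0.01), 1, dimnames = list(NULL, lev))),
    class_order = lev), class = "posterior_set")
  expect_equal(product_rule_combine(vet, c(A = 0.5, B = 0.5), floor = 1e-6),
               "B")   # A survives flooring but B still wins on the product
  expect_error(product_rule_combine(two, c(A = 0, B = 1)), "positive")
})

test_that("product-rule scores are invariant to rescaling one classifier", {
  set.seed(41)
  lev <- c("A", "B", "C")
  P1 <- matrix(runif(30), 10); P1 <- P1 / rowSums(P1); colnames(P1) <- lev
  P2 <- matrix(runif(30), 10); P2 <- P2 / rowSums(P2); colnames(P2) <- lev
  pri <- c(A = 0.5, B = 0.3, C = 0.2)
  ps <- function(a, b) structure(list(per_classifier = list(a, b),
                                      class_order = lev),
                                 class = "posterior_set")
  base <- product_rule_combine(ps(P1, P2), pri)
  # multiplying a row by a constant and renormalizing changes nothing
  scaled <- P2 * 5; scaled <- scaled / rowSums(scaled)
  expect_equal(product_rule_combine(ps(P1, scaled), pri), base)
  # R identical classifiers + uniform priors = the single argmax
  uni <- c(A = 1, B = 1, C = 1) / 3
  trip <- structure(list(per_classifier = list(P1, P1, P1), class_order = lev),
                    class = "posterior_set")
  expect_equal(product_rule_combine(trip, uni),
               lev[max.col(P1, ties.method = "first")])
})

test_that("voting method line-ups are fixed", {
  expect_equal(make_voting_ensemble("method1"), c("tree", "lda", "naive_bayes"))
  expect_equal(make_voting_ensemble("method2"), c("tree", "qda", "naive_bayes"))
  expect_equal(make_voting_ensemble("method3"),
               c("consolidated_tree", "qda", "naive_bayes"))
  expect_equal(make_voting_ensemble("method4"),
               c("consolidated_tree", "lda", "naive_bayes"))
  expect_error(make_voting_ensemble("method5"), "unknown")
})

test_that("the ensemble is at least as sensitive as its weakest member", {
  # three separable 2-D classes with imbalance
  set.seed(51)
  n <- c(N = 600, V = 90, S = 60)
  X <- rbind(cbind(rnorm(n[1], 0), rnorm(n[1], 0)),
             cbind(rnorm(n[2], 4), rnorm(n[2], 0)),
             cbind(rnorm(n[3], 0), rnorm(n[3], 4)))
  y <- rep(names(n), n)
  ens <- train_voting_ensemble(X, y, method = "method1", min_objects = 30)
  set.seed(52)
  Xh <- rbind(cbind(rnorm(200, 0), rnorm(200, 0)),
              cbind(rnorm(40, 4), rnorm(40, 0)),
              cbind(rnorm(30, 0), rnorm(30, 4)))
  yh <- rep(names(n), c(200, 40, 30))
  macro_sen <- function(pred) {
    mean(vapply(unique(yh), function(k) mean(pred[yh == k] == k), numeric(1)))
  }
  sens <- vapply(ens$models, function(m) {
    P <- posterior(m, Xh)
    macro_sen(colnames(P)[max.col(P, ties.method = "first")])
  }, numeric(1))
  comb <- macro_sen(predict_voting_ensemble(ens, Xh))
  expect_true(all(sens > 1 / 3))          # every member beats chance
  expect_gte(comb, min(sens) - 1e-9)      # fusion not worse than the worst
})
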