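test_that("PCA agrees with a direct SVD oracle and ranks outliers", {
  set.seed(101)
  for (i in 1:10) {
    X <- scale(matrix(rnorm(6 * 4), 6, 4), scale = FALSE)
    m <- fit_pca(X, n_components = 3)
    sv <- svd(X)
    for (a in 1:3) {
      expect_same_up_to_sign(m$T_pred[, a], sv$u[, a] * sv$d[a], tol = 1e-8)
      expect_same_up_to_sign(m$P[, a], sv$v[, a], tol = 1e-8)
    }
    expect_true(all(diff(m$explained_variance) <= 1e-12))
  }
  # rank-1 matrix: one component explains everything
  t1 <- rnorm(8); p1 <- rnorm(5)
  m1 <- fit_pca(tcrossprod(t1, p1), n_components = 2)
  expect_equal(m1$explained_variance[1], 1, tolerance = 1e-12)
  expect_same_up_to_sign(m1$P[, 1], p1 / sqrt(sum(p1^2)), tol = 1e-8)
  # a sample 10 sd off in one bucket has the largest score distance
  X <- matrix(rnorm(20 * 10), 20, 10)
  X[7, 3] <- X[7, 3] + 10
  mo <- fit_pca(scale(X, scale = FALSE), n_components = 3)
  expect_equal(which.max(mo$score_distance), 7L)
  expect_error(fit_pca(X, n_components = 19), "n_components")
})

test_that("PLS fits exact linear responses and degenerates to least squares", {
  set.seed(7)
  X <- matrix(rnorm(20 * 5), 20, 5)
  beta <- rnorm(5)
  y <- drop(X %*% beta)
  m <- fit_pls(scale(X, scale = FALSE), y, n_components = 5)
  expect_gt(m$R2Y, 1 - 1e-8)
  # one-column X, one component == simple least squares up to centering
  x1 <- matrix(rnorm(15), 15, 1)
  y1 <- 2.5 * x1[, 1] + rnorm(15, sd = 0.3)
  x1c <- scale(x1, scale = FALSE); y1c <- y1 - mean(y1)
  m1 <- fit_pls(x1c, y1, n_components = 1)
  ols <- lm.fit(x1c, y1c)$coefficients
  expect_equal(drop(predict(m1, x1c)), mean(y1) + drop(x1c) * ols,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(fit_pls(x1c, rep(1, 15)), "constant response")
})

test_that("PLS separates a planted two-class design on component 1", {
  tc <- toy_two_class(effect = 3, seed = 5)
  m <- fit_pls(tc$X, ifelse(tc$y > 0, "a", "b"), n_components = 2)
  t1 <- m$T_pred[, 1]
  expect_true(max(t1[tc$y == -1]) < min(t1[tc$y == 1]) ||
              min(t1[tc$y == -1]) > max(t1[tc$y == 1]))
})

test_that("OPLS with zero orthogonal components equals one-component PLS", {
  tc <- toy_two_class(seed = 2)
  mo <- fit_opls(tc$X, tc$y, n_orthogonal = 0)
  mp <- fit_pls(tc$X, tc$y, n_components = 1)
  expect_same_up_to_sign(mo$T_pred[, 1], mp$T_pred[, 1], tol = 1e-10)
})

test_that("orthogonal scores are uncorrelated with the response", {
  for (seed in 1:5) {
    tc <- toy_two_class(seed = seed, orth_strength = 3)
    m <- fit_opls(tc$X, tc$y, n_orthogonal = 2)
    for (k in seq_len(m$n_orthogonal))
      expect_lt(abs(cor(m$T_orth[, k], tc$y)), 1e-8)
  }
  expect_error(fit_opls(toy_two_class()$X, toy_two_class()$y,
                        n_orthogonal = 18), "n_orthogonal")
  expect_error(fit_opls(toy_two_class()$X, rep("a", 20)), "two classes")
})

test_that("removing structured orthogonal variation sharpens the predictive score", {
  tc <- toy_two_class(n_per = 10, p = 50, effect = 1, seed = 8,
                      orth_strength = 6)
  pls1 <- fit_pls(tc$X, tc$y, n_components = 1)
  opls <- fit_opls(tc$X, tc$y, n_orthogonal = 1)
  expect_gt(abs(cor(opls$T_pred[, 1], tc$y)),
            abs(cor(pls1$T_pred[, 1], tc$y)))
})

test_that("leave-one-out Q2Y nails noise-free responses and is order-invariant", {
  set.seed(31)
  X <- matrix(rnorm(30 * 4), 30, 4)
  y <- drop(X %*% c(1, -2, 0.5, 1))
  cv <- q2y_loo(X, y, kind = "pls", n_components = 4, scaling = "center")
  expect_gt(cv$q2y, 0.99)
  expect_lte(cv$q2y, 1)

  tc <- toy_two_class(seed = 4)
  cv1 <- q2y_loo(tc$Xraw, tc$y, kind = "opls", n_orthogonal = 1)
  perm <- sample(length(tc$y))
  cv2 <- q2y_loo(tc$Xraw[perm, ], tc$y[perm], kind = "opls", n_orthogonal = 1)
  expect_equal(cv1$q2y, cv2$q2y, tolerance = 1e-10)

  # losing an entire class in a fold is rejected
  yy <- c("a", rep("b", 9))
  expect_error(q2y_loo(matrix(rnorm(100), 10), yy, kind = "opls"),
               "loses an entire class")
})

test_that("Q2Y never exceeds R2Y across planted designs", {
  for (seed in 1:6) {
    tc <- toy_two_class(effect = 1.5, seed = seed)
    m <- fit_opls(scale(tc$Xraw), tc$y, n_orthogonal = 1)
    cv <- q2y_loo(tc$Xraw, tc$y, kind = "opls", n_orthogonal = 1)
    expect_lte(cv$q2y, m$R2Y + 1e-10)
  }
})

test_that("null-data Q2Y concentrates at or below zero", {
  set.seed(99)
  q <- replicate(40, {
    X <- matrix(rnorm(16 * 40), 16, 40)
    y <- rep(c(-1, 1), each = 8)
    q2y_loo(X, y, kind = "opls", n_orthogonal = 1)$q2y
  })
  expect_gte(mean(q <= 0), 0.5)
  expect_lt(mean(q), 0.05)
  expect_lt(max(q), 0.6)
})

test_that("CV-ANOVA matches the F-distribution oracle", {
  n <- 20; A <- 3
  p <- cv_anova(press = 1, ss = 10, n = n, n_components = A)
  Fo <- ((10 - 1) / A) / (1 / (n - A - 1))
  expect_equal(as.numeric(p), pf(Fo, A, n - A - 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # perfect cross-validated prediction: overwhelming evidence
  pp <- cv_anova(press = 1e-14, ss = 10, n = n, n_components = A)
  expect_lt(as.numeric(pp), 1e-6)
  expect_true(attr(pp, "zero_residual"))
  # no predictive ability at all: p = 1
  expect_equal(as.numeric(cv_anova(press = 12, ss = 10, n = n,
                                   n_components = A)), 1)
})

test_that("permutation test is seeded, degenerate-safe, and finds real effects", {
  tc <- toy_two_class(effect = 2.5, seed = 12)
  r1 <- suppressWarnings(permutation_test(tc$Xraw, tc$y, kind = "opls",
                                          n_orthogonal = 1,
                                          n_permutations = 99, seed = 5))
  r2 <- suppressWarnings(permutation_test(tc$Xraw, tc$y, kind = "opls",
                                          n_orthogonal = 1,
                                          n_permutations = 99, seed = 5))
  expect_identical(r1$permuted_Q2Y, r2$permuted_Q2Y)
  expect_true(r1$passes)
  expect_lt(r1$p_value, 0.05)
  expect_length(r1$permuted_Q2Y, 99)

  # constant X carries no information: all Q2Y equal, never accepted
  Xc <- matrix(5, 12, 8)
  rc <- suppressWarnings(permutation_test(Xc, rep(c(-1, 1), 6), kind = "opls",
                                          n_orthogonal = 0,
                                          n_permutations = 99, seed = 1))
  expect_false(rc$passes)
  expect_true(all(rc$permuted_Q2Y == rc$observed_Q2Y))
  expect_warning(permutation_test(tc$Xraw, tc$y, kind = "opls",
                                  n_permutations = 50, seed = 1),
                 "unstable")
})

test_that("correlation loadings match the textbook Pearson oracle", {
  y <- c(-1, -1, -1, 1, 1, 1)
  X <- cbind(y, -y, c(2, 1, 3, 7, 6, 9), rep(4, 6))
  colnames(X) <- NULL
  prof <- correlation_loadings(X, y)
  expect_equal(prof$r[1], 1, tolerance = 1e-12)
  expect_equal(prof$r[2], -1, tolerance = 1e-12)
  expect_equal(prof$r[3], cor(X[, 3], y), tolerance = 1e-12)
  expect_equal(prof$covariance[3], cov(X[, 3], y), tolerance = 1e-12)
  expect_equal(prof$r[4], 0)                      # zero variance: flagged 0
  expect_true(prof$flagged[4])
})

test_that("discriminant selection is inclusive at 0.5 and breaks ties low", {
  lib <- load_library()
  centers <- c(2.4085, 2.4105, 1.9205, 1.3305)
  mkprof <- function(r) {
    p <- data.frame(center = centers, covariance = r, r = r, flagged = FALSE)
    class(p) <- c("loading_profile", "data.frame")
    p
  }
  out <- suppressWarnings(
    select_discriminant(mkprof(c(-0.7, 0.7, 0.5, 0.2)), lib))
  succ <- out[out$metabolite == "Succinate", ]
  expect_equal(succ$r, -0.7)                       # tie on |R|: lower ppm wins
  expect_true(succ$selected)
  expect_true(out$selected[out$metabolite == "Acetate"])  # 0.5 inclusive
  expect_false(out$selected[out$metabolite == "Lactate"])
  expect_equal(out$metabolite[1:2], c("Succinate", "Acetate"))
  none <- suppressWarnings(select_discriminant(mkprof(c(0.1, 0.2, -0.3, 0.4)), lib))
  expect_equal(sum(none$selected), 0L)
})
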