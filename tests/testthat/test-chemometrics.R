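test_that("PCA matches an eigendecomposition oracle on random data", {
  set.seed(42)
  X <- matrix(rnorm(60), 10, 6,
              dimnames = list(paste0("s", 1:10), paste0("v", 1:6)))
  fit <- pca_fit(X, 5)
  eg <- eigen(cov(X), symmetric = TRUE)
  expect_equal(fit$explained, (eg$values / sum(eg$values))[1:5],
               tolerance = 1e-8)
  for (k in 1:5) {
    v <- eg$vectors[, k]
    expect_lt(min(max(abs(fit$loadings[, k] - v)),
                  max(abs(fit$loadings[, k] + v))), 1e-8)
  }
  # scores orthogonal, explained fractions non-increasing in [0,1]
  g <- crossprod(fit$scores)
  expect_lt(max(abs(g - diag(diag(g)))), 1e-8)
  expect_true(all(diff(fit$explained) <= 1e-12))
  expect_true(all(fit$explained >= 0 & fit$explained <= 1))
  expect_lte(sum(fit$explained), 1 + 1e-12)
})

test_that("PCA degenerate geometries give exact variance fractions", {
  line <- cbind(x = 1:6, y = 2 * (1:6) - 3)
  rownames(line) <- paste0("s", 1:6)
  expect_equal(pca_fit(line, 1)$explained, 1.0, tolerance = 1e-12)
  iso <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  dimnames(iso) <- list(paste0("s", 1:4), c("x", "y"))
  expect_equal(pca_fit(iso, 2)$explained, c(0.5, 0.5), tolerance = 1e-12)
  expect_error(pca_fit(iso, 4), "K must be at most")
})

test_that("PCA and PLS are equivariant to variable permutation", {
  set.seed(11)
  X <- scale(matrix(rnorm(80), 10, 8))
  colnames(X) <- paste0("v", 1:8); rownames(X) <- paste0("s", 1:10)
  y <- rnorm(10); y <- y - mean(y)
  perm <- sample(8)
  p1 <- pca_fit(X, 3); p2 <- pca_fit(X[, perm], 3)
  expect_equal(p2$loadings, p1$loadings[perm, ], tolerance = 1e-10)
  f1 <- pls_fit(X, y, 3); f2 <- pls_fit(X[, perm], y, 3)
  expect_equal(f2$B, f1$B[perm], tolerance = 1e-10)
})

test_that("NIPALS PLS satisfies its structural identities", {
  set.seed(7)
  X <- scale(matrix(rnorm(120), 12, 10))
  colnames(X) <- paste0("v", 1:10); rownames(X) <- paste0("s", 1:12)
  y <- rnorm(12); y <- y - mean(y)
  fit <- pls_fit(X, y, 4)
  # scores mutually orthogonal
  g <- crossprod(fit$T)
  expect_lt(max(abs(g - diag(diag(g)))), 1e-8)
  # first weight vector proportional to X'y
  w1 <- crossprod(X, y)
  expect_equal(fit$W[, 1], drop(w1 / sqrt(sum(w1^2))), tolerance = 1e-12)
  # coefficient identity: training predictions from (T,q) equal X B
  expect_equal(drop(fit$T %*% fit$q), drop(X %*% fit$B), tolerance = 1e-10)
})

test_that("full-rank PLS equals pseudoinverse least squares", {
  set.seed(19)
  X <- scale(matrix(rnorm(12 * 5), 12, 5))
  colnames(X) <- paste0("v", 1:5); rownames(X) <- paste0("s", 1:12)
  y <- rnorm(12); y <- y - mean(y)
  fit <- pls_fit(X, y, 5)
  expect_equal(fit$B, drop(pinv_solve(X, y)), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("PLS handles perfect and degenerate responses", {
  set.seed(23)
  # orthogonal columns so a single LV captures one column's response fully
  X <- qr.Q(qr(matrix(rnorm(40), 10, 4)))
  colnames(X) <- paste0("v", 1:4); rownames(X) <- paste0("s", 1:10)
  # y equal to one column: R2Y = 1 at one LV, dominant weight there
  fit <- pls_fit(X, X[, 2], 1)
  expect_equal(fit$r2y[1], 1.0, tolerance = 1e-10)
  expect_identical(unname(which.max(abs(fit$B))), 2L)
  # y orthogonal to the column space: early stop at 0 LVs
  y_perp <- residuals(lm(rnorm(10) ~ X))
  y_perp <- y_perp / sqrt(sum(y_perp^2))
  expect_warning(f0 <- pls_fit(X, y_perp, 2), "no covariance")
  expect_identical(f0$n_lv, 0L)
})

test_that("PLS-DA prediction thresholds at zero with first-class ties", {
  sep <- separated_data()
  model <- plsda_fit(sep$X, sep$labels, classes = c("A", "B"), A = 2)
  pred <- plsda_predict(model, sep$X)
  expect_equal(nmc(sep$labels, pred$class), 0)
  # explicit sign cases on a hand-built model
  model$pls$B <- rep(0, ncol(sep$X))
  model$y_mean <- 0
  tied <- plsda_predict(model, sep$X[1:2, ])
  expect_true(all(tied$score == 0))
  expect_true(all(tied$class == "A"))      # tie -> first-listed class
  expect_error(plsda_predict(model, sep$X[, 1:3]), "variable mismatch")
})

test_that("figures of merit follow their definitions", {
  expect_equal(nmc(c(1, 1, -1), c(1, -1, -1)), 1)
  expect_equal(nmc(c(1, 1), c(1, 1)), 0)
  expect_equal(nmc(c(1, -1, 1), c(-1, 1, -1)), 3)
  expect_error(nmc(c(1, -1), c(1, 2)), "unknown label")
  expect_equal(ccr(c(1, 1, -1, -1), c(1, 1, -1, 1)), 0.75)

  expect_equal(auroc(c(1, 1, -1, -1), c(0.9, 0.8, 0.3, 0.2), positive = 1),
               1.0)
  expect_equal(auroc(c(1, -1, 1, -1), c(0.9, 0.8, 0.3, 0.2), positive = 1),
               0.75)
  expect_error(auroc(c(1, 1), c(0.5, 0.2), positive = 1), "both classes")
})

test_that("AUROC equals the pair-counting oracle, ties included", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(6:15, 1)
    labels <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("a", "b")
    score <- sample(seq(0, 1, 0.25), n, replace = TRUE)  # forces ties
    expect_equal(auroc(labels, score, positive = "a"),
                 auroc_pairs(labels, score, "a"))
  }
})

test_that("DQ2 clips overshooting residuals and dominates Q2", {
  y <- c(1, 1, -1, -1)
  expect_equal(dq2(y, c(1.5, 2, -2, -1.1)), 1.0)
  # predictions at the training mean give DQ2 = 0 for balanced classes
  expect_equal(dq2(y, rep(0, 4), y_train_mean = 0), 0.0)
  expect_error(dq2(c(1, 0), c(0.5, 0.2)), "encoded")
  set.seed(13)
  for (i in 1:25) {
    y <- sample(c(-1, 1), 10, replace = TRUE)
    yhat <- rnorm(10, y, 1.2)
    expect_gte(dq2(y, yhat), q2(y, yhat, mean(y)))
  }
})

test_that("Q2 matches a hand-computed worked case and its limits", {
  y <- c(1, 2, 3, 4); yhat <- c(1.1, 1.9, 3.2, 3.9)
  # PRESS = 0.01+0.01+0.04+0.01 = 0.07; TSS about mean 2.5 = 5
  expect_equal(q2(y, yhat, 2.5), 1 - 0.07 / 5)
  expect_equal(q2(y, y, mean(y)), 1.0)
  expect_equal(q2(y, rep(mean(y), 4), mean(y)), 0.0)
  expect_error(q2(c(2, 2), c(2, 2), 2), "zero total")
})
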