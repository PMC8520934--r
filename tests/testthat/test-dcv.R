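dcv_fixture <- function(seed = 7, effect_size = 2) {
  sim <- generate_stool_metabolome(dyad_config(seed = seed,
                                               effect_size = effect_size))
  keep <- sim$metadata$diet_period %in% c("BM", "FBM")
  list(X = ft_vals(sim$table)[keep, ],
       labels = sim$metadata$diet_period[keep],
       truth = sim$truth)
}

test_that("every sample is predicted exactly once per repetition", {
  fx <- dcv_fixture()
  res <- rdcv(fx$X, fx$labels, dcv_config(n_repetitions = 4, seed = 3),
              classes = c("BM", "FBM"))
  expect_equal(dim(res$folds), c(4, nrow(fx$X)))
  for (r in 1:4) {
    # outer folds partition all samples
    expect_true(all(res$folds[r, ] %in% 1:5))
    expect_true(all(is.finite(res$scores[r, ])))
    # stratification: each fold has members of both classes' pools
    expect_true(all(table(res$folds[r, ]) >= 3))
  }
  # rank matrix columns are permutations of 1..p
  p <- ncol(fx$X)
  for (k in seq_len(ncol(res$rank_matrix))) {
    expect_identical(sort(res$rank_matrix[, k]), seq_len(p))
  }
})

test_that("rDCV is reproducible under a seed and classifies separated data", {
  # lactation vs weaning at a large effect size: well-separated two-class
  # data (n = 32, p = 49)
  sim <- generate_stool_metabolome(dyad_config(seed = 5, effect_size = 3))
  X <- ft_vals(sim$table)
  labels <- ifelse(sim$metadata$day_after_birth <= 175, "early", "late")
  cfg <- dcv_config(n_repetitions = 10, seed = 42)
  a <- rdcv(X, labels, cfg, classes = c("early", "late"))
  b <- rdcv(X, labels, cfg, classes = c("early", "late"))
  expect_identical(a$foms, b$foms)
  expect_identical(a$rank_product, b$rank_product)
  expect_identical(a$scores, b$scores)
  expect_gte(a$summary["mean", "ccr"], 0.95)
})

test_that("null labels give chance-level classification", {
  fx <- dcv_fixture(seed = 8, effect_size = 0)
  set.seed(1)
  labels <- sample(fx$labels)
  res <- rdcv(fx$X, labels, dcv_config(n_repetitions = 50, seed = 2),
              classes = c("BM", "FBM"))
  expect_lt(abs(res$summary["mean", "ccr"] - 0.5),
            3 * res$summary["sd", "ccr"])
})

test_that("mean ccr does not decrease with effect size", {
  cc <- vapply(c(0, 1, 2, 3), function(es) {
    fx <- dcv_fixture(seed = 31, effect_size = es)
    rdcv(fx$X, fx$labels, dcv_config(n_repetitions = 8, seed = 17),
         classes = c("BM", "FBM"))$summary["mean", "ccr"]
  }, numeric(1))
  expect_true(all(diff(cc) >= -0.05))
  expect_gt(cc[4], cc[1])
})

test_that("class-size checks reject infeasible fold counts", {
  fx <- dcv_fixture()
  expect_error(rdcv(fx$X[1:12, ], fx$labels[1:12],
                    dcv_config(outer_folds = 5, seed = 1),
                    classes = c("BM", "FBM")),
               "reduce outer_folds")
})

test_that("rank product matches the direct geometric mean", {
  expect_equal(unname(rank_product(matrix(c(1, 2, 3), 3, 1))), c(1, 2, 3))
  rm <- cbind(c(1, 2, 3), c(1, 3, 2), c(4, 2, 3) * 0 + c(3, 1, 2))
  direct <- apply(rm, 1, function(r) prod(r)^(1 / length(r)))
  expect_equal(unname(rank_product(rm)), direct, tolerance = 1e-10)
  # the worked case: ranks (1,1,4) -> 4^(1/3)
  rm2 <- cbind(c(1, 2, 3, 4), c(1, 2, 4, 3), c(4, 2, 3, 1))
  expect_equal(unname(rank_product(rm2))[1], 4^(1 / 3), tolerance = 1e-10)
  # variable ranked 1 everywhere attains the minimum RP of 1
  rm3 <- cbind(c(1, 2, 3), c(1, 3, 2), c(1, 2, 3))
  expect_equal(unname(rank_product(rm3))[1], 1)
  expect_error(rank_product(cbind(c(1, 2, 2))), "not a permutation")
})

test_that("marker selection takes RP strictly below the mean, sorted", {
  rp <- c(a = 1.2, b = 5.0, c = 5.0)
  sel <- select_markers(rp)
  expect_identical(sel$variable, "a")
  # all equal: strict inequality selects nothing
  expect_equal(nrow(select_markers(c(a = 2, b = 2, c = 2))), 0)
  # sorted ascending with direction annotation
  rp2 <- c(a = 3, b = 1, c = 9, d = 2)
  sel2 <- select_markers(rp2, coef_mean = c(a = -1, b = 2, c = 0, d = -3),
                         classes = c("BM", "FBM"))
  expect_identical(sel2$variable, c("b", "d", "a"))
  expect_identical(sel2$direction, c("BM", "FBM", "FBM"))
})

test_that("outer predictions never use the held-out fold (leakage check)", {
  fx <- dcv_fixture(seed = 21)
  cfg <- dcv_config(seed = 1)
  n <- nrow(fx$X)
  tr <- 1:14; te <- 15:19
  set.seed(99)
  base <- dyadomics:::.outer_fold(fx$X, ifelse(fx$labels == "BM", 1, -1),
                                  tr, te, cfg)
  X2 <- fx$X
  X2[te, ] <- X2[te, ] + 5   # perturb only the held-out rows
  set.seed(99)
  pert <- dyadomics:::.outer_fold(X2, ifelse(fx$labels == "BM", 1, -1),
                                  tr, te, cfg)
  # the fitted model is untouched by the test fold...
  expect_identical(base$B, pert$B)
  expect_identical(base$n_lv, pert$n_lv)
  # ...and only the perturbed fold's predictions move
  expect_false(isTRUE(all.equal(base$score, pert$score)))
})

test_that("permutation p-values follow the add-one convention", {
  fx <- dcv_fixture(seed = 2, effect_size = 4)
  cfg <- dcv_config(n_repetitions = 3, seed = 5)
  obs <- rdcv(fx$X, fx$labels, cfg, classes = c("BM", "FBM"))
  pt <- permutation_test(fx$X, fx$labels, cfg, n_perm = 49, observed = obs)
  expect_equal(nrow(pt$null), 49)
  expect_true(all(pt$p_value >= 1 / 50 & pt$p_value <= 1))
  # overwhelming separation beats every null
  expect_equal(unname(pt$p_value["auroc"]), 1 / 50)
  expect_error(permutation_test(fx$X, fx$labels, cfg, n_perm = 0),
               "n_perm")
})
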