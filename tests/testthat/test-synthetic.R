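test_that("default config reproduces the study shape", {
  sim <- simulate_dyad(dyad_config(seed = 1))
  expect_equal(dim(ft_vals(sim$stool$table)), c(32, 49))
  expect_equal(dim(ft_vals(sim$otu$table)), c(25, 48))
  md <- sim$stool$metadata
  expect_equal(length(unique(md$day_block)), 5)
  expect_equal(as.integer(table(factor(md$diet_period,
                                       c("BM", "FBM", "W")))),
               c(9L, 10L, 13L))
  expect_true(all(md$day_after_birth >= 103 & md$day_after_birth <= 268))
  # milk covers the lactation window only, paired start/end rows
  expect_true(all(sim$milk$metadata$day_after_birth <= 175))
  expect_equal(nrow(sim$milk$table), 2 * 19)
  expect_equal(ncol(sim$milk$table), 39)
})

test_that("generation is bit-identical under the same seed and config", {
  a <- simulate_dyad(dyad_config(seed = 77))
  b <- simulate_dyad(dyad_config(seed = 77))
  expect_identical(ft_vals(a$stool$table), ft_vals(b$stool$table))
  expect_identical(ft_vals(a$otu$table), ft_vals(b$otu$table))
  expect_identical(ft_vals(a$milk$table), ft_vals(b$milk$table))
  c <- generate_stool_metabolome(dyad_config(seed = 78))
  expect_false(identical(ft_vals(a$stool$table), ft_vals(c$table)))
})

test_that("stool generator plants the documented period structure", {
  for (seed in c(3, 14, 159)) {
    sim <- generate_stool_metabolome(dyad_config(seed = seed))
    m <- ft_vals(sim$table)
    cls <- attr(sim$table, "variable_class")
    period <- sim$metadata$diet_period
    # HMOs at the detection floor throughout weaning
    expect_true(all(m[period == "W", cls == "HMO"] <= 1e-3))
    # positive values everywhere
    expect_true(all(m >= 1e-3))
    # SCFAs higher in weaning than breastfeeding (log scale)
    expect_gt(mean(log(m[period == "W", cls == "SCFA"])),
              mean(log(m[period == "BM", cls == "SCFA"])))
    # FBM-only markers peak in FBM
    expect_gt(mean(log(m[period == "FBM", cls == "FBM"])),
              mean(log(m[period != "FBM", cls == "FBM"])))
  }
})

test_that("ground-truth markers are disjoint from nulls with large effects", {
  sim <- generate_stool_metabolome(dyad_config(seed = 6))
  tr <- sim$truth
  expect_length(tr$marker_ids_bm_vs_fbm, 10)
  expect_length(intersect(tr$marker_ids_bm_vs_fbm, tr$null_ids), 0)
  expect_length(intersect(tr$marker_ids_milk_vs_weaning, tr$null_ids), 0)
  # every BM-vs-FBM marker carries at least half the nominal effect size,
  # measured on the generator's own log-scale population parameters: the
  # planted shift is effect_size, the within-period variance is
  # noise_sd^2 plus the variable's squared factor loadings
  L <- tr$factor_loadings
  idx <- match(tr$marker_ids_bm_vs_fbm, colnames(sim$table))
  pooled <- sqrt((rowSums(L[["BM"]][idx, , drop = FALSE]^2) +
                    rowSums(L[["FBM"]][idx, , drop = FALSE]^2)) / 2 + 1)
  expect_true(all(2 / pooled >= 1))  # effect_size 2 => standardized >= 1
})

test_that("OTU tables are closed compositions with the planted community", {
  sim <- generate_stool_metabolome(dyad_config(seed = 9))
  otu <- generate_otu_table(dyad_config(seed = 9), sim$metadata)
  m <- ft_vals(otu$table)
  expect_equal(unname(rowSums(m)), rep(100, 25), tolerance = 1e-6)
  phylum <- otu$truth$phylum
  # Bacteroidetes total stays below 1% on average across several seeds
  for (seed in c(2, 21, 202)) {
    md <- generate_stool_metabolome(dyad_config(seed = seed))$metadata
    o <- generate_otu_table(dyad_config(seed = seed), md)
    tot <- rowSums(ft_vals(o$table)[, o$truth$phylum == "Bacteroidetes"])
    expect_lt(mean(tot), 1)
  }
  # dominant phyla dominate
  expect_gt(mean(rowSums(m[, phylum %in% c("Firmicutes", "Proteobacteria",
                                           "Actinobacteria")])), 95)
  # Bifidobacterium-like genus: high mean, high variance
  bif <- m[, "Bifidobacterium_like"]
  expect_gt(mean(bif), 5)
  expect_gt(sd(log(bif)), sd(log(m[, "Clostridium_like"])))
  expect_error(generate_otu_table(dyad_config(seed = 1,
                                              metagenome_subset = "nope"),
                                  sim$metadata), "not in metadata")
})

test_that("milk generator plants monotone day trends and a suction shift", {
  for (seed in c(4, 44, 444)) {
    sim <- generate_milk_metabolome(dyad_config(seed = seed))
    m <- log(ft_vals(sim$table))
    end <- sim$metadata$suction == "end"
    day <- sim$metadata$day_after_birth[end]
    # planted slope signs hold in simple regression on day, every seed
    slope <- function(v) coef(lm(m[end, v] ~ day))[2]
    expect_gt(slope("FL3_like"), 0)
    expect_true(all(vapply(sim$truth$decreasing, slope, numeric(1)) < 0))
    # end-of-suction lactate sits above start-of-suction, on average
    d <- m[end, "lactate"] - m[!end, "lactate"]
    expect_gt(mean(d), 0)
  }
})

test_that("config validation catches impossible block allocations", {
  expect_error(dyad_config(n_per_block = c(6, 3, 10, 8)),
               "inconsistent")
  expect_error(dyad_config(n_per_block = c(20, 3, 10, 8, 5)),
               "inconsistent")
  expect_error(dyad_config(n_metabolites = 5), "at least")
})

test_that("effect_size = 0 removes period separation of null variables", {
  # two-sample t-tests on BM vs FBM reject ~5% of variables at alpha = 0.05
  set.seed(1)
  rates <- vapply(1:60, function(s) {
    sim <- generate_stool_metabolome(dyad_config(seed = 5000 + s,
                                                 effect_size = 0))
    m <- log(ft_vals(sim$table))
    period <- sim$metadata$diet_period
    keep <- period %in% c("BM", "FBM")
    p <- apply(m[keep, ], 2, function(v)
      t.test(v[period[keep] == "BM"], v[period[keep] == "FBM"])$p.value)
    mean(p < 0.05)
  }, numeric(1))
  expect_gt(mean(rates), 0.01)
  expect_lt(mean(rates), 0.10)
})
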