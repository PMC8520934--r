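test_that("feature table validation rejects duplicates and non-finite cells", {
  expect_error(feature_table(matrix(1:4, 2, 2), c("a", "a"), c("x", "y")),
               "duplicate sample id")
  expect_error(feature_table(matrix(1:4, 2, 2), c("a", "b"), c("x", "x")),
               "duplicate variable id")
  m <- matrix(c(1, NA, 3, 4), 2, 2)
  expect_error(feature_table(m, c("s1", "s2"), c("glucose", "lactate")),
               "missing value at \\(s2, glucose\\)")
})

test_that("read/write round trip is lossless for ids and values", {
  set.seed(3)
  ft <- feature_table(matrix(rexp(12) * 10^sample(-3:3, 12, TRUE), 3, 4),
                      c("s1", "s2", "s3"), paste0("m", 1:4))
  for (ext in c("csv", "tsv")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_feature_table(ft, path)
    back <- read_feature_table(path)
    expect_identical(rownames(back), rownames(ft))
    expect_identical(colnames(back), colnames(ft))
    expect_equal(ft_vals(back), ft_vals(ft), tolerance = 1e-12)
  }
})

test_that("reader reports missing cells with their address and accepts QIIME headers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,lactate,acetate", "s1,1.0,2.0", "s2,NA,3.0"), path)
  expect_error(read_feature_table(path), "missing value at \\(s2, lactate\\)")

  qiime <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#OTU ID\tg1\tg2", "s1\t40\t60", "s2\t70\t30"), qiime)
  tab <- read_feature_table(qiime)
  expect_identical(colnames(tab), c("g1", "g2"))
  expect_equal(unname(ft_vals(tab)[1, ]), c(40, 60))
})

test_that("samples-in-columns orientation transposes on read", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("variable,s1,s2,s3", "met1,1,2,3", "met2,4,5,6"), path)
  tab <- read_feature_table(path, orientation = "samples-in-columns")
  expect_identical(rownames(tab), c("s1", "s2", "s3"))
  expect_equal(unname(ft_vals(tab)[, "met1"]), c(1, 2, 3))
})

test_that("align_blocks intersects samples in first-table order and is idempotent", {
  a <- feature_table(matrix(1:6, 3, 2), c("a", "b", "c"), c("x", "y"))
  b <- feature_table(matrix(1:6, 3, 2), c("b", "c", "d"), c("u", "v"))
  bs <- align_blocks(list(a, b))
  expect_identical(bs$common_samples, c("b", "c"))
  expect_identical(bs$dropped[[1]], "a")
  expect_identical(bs$dropped[[2]], "d")
  # identical sample sets: nothing dropped
  bs2 <- align_blocks(list(a, a))
  expect_identical(bs2$common_samples, c("a", "b", "c"))
  expect_true(all(lengths(bs2$dropped) == 0))
  # idempotence
  bs3 <- align_blocks(bs$blocks)
  expect_identical(bs3$common_samples, bs$common_samples)
  expect_equal(ft_vals(bs3$blocks[[1]]), ft_vals(bs$blocks[[1]]))
  # empty intersection errors
  c2 <- feature_table(matrix(1:2, 1, 2), "zz", c("x", "y"))
  expect_error(align_blocks(list(a, c2)), "no samples common")
})

test_that("synthetic dyad blocks align to the 25 shared samples", {
  sim <- simulate_dyad(dyad_config(seed = 12))
  bs <- align_blocks(list(sim$stool$table, sim$otu$table))
  expect_length(bs$common_samples, 25)
  expect_length(bs$dropped[[1]], 7)
})

test_that("metadata resolves every sample and maps blocks to periods", {
  sim <- generate_stool_metabolome(dyad_config(seed = 5))
  md <- match_metadata(sim$table, sim$metadata)
  expect_identical(md$sample_id, rownames(sim$table))
  expect_identical(diet_period_for_block(c("103-108", "165-175", "262-268")),
                   c("BM", "FBM", "W"))
  expect_error(diet_period_for_block("300-310"), "unknown day block")
  expect_error(match_metadata(sim$table, sim$metadata[-1, ]),
               "no metadata for sample")
})

test_that("result bundles list their files and echo the seed in the manifest", {
  sim <- generate_stool_metabolome(dyad_config(seed = 2))
  keep <- sim$metadata$diet_period %in% c("BM", "FBM")
  res <- rdcv(ft_vals(sim$table)[keep, ], sim$metadata$diet_period[keep],
              dcv_config(n_repetitions = 2, seed = 77),
              classes = c("BM", "FBM"))
  dir <- withr::local_tempdir()
  files <- write_result_bundle(res, dir, extra = list(seed = 77))
  expect_true(all(c("predictions.csv", "rank_products.csv", "markers.csv",
                    "manifest.json") %in% basename(files)))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_identical(manifest$seed, 77L)
  expect_identical(manifest$parameters$n_repetitions, 2L)
})

test_that("bundle numeric tables are byte-identical across same-seed reruns", {
  sim <- generate_stool_metabolome(dyad_config(seed = 2))
  keep <- sim$metadata$diet_period %in% c("BM", "FBM")
  run <- function(dir) {
    res <- rdcv(ft_vals(sim$table)[keep, ], sim$metadata$diet_period[keep],
                dcv_config(n_repetitions = 2, seed = 13),
                classes = c("BM", "FBM"))
    write_result_bundle(res, dir)
  }
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run(d1); run(d2)
  for (f in c("predictions.csv", "rank_products.csv", "foms.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})
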