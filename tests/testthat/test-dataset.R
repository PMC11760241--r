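make_labelled_layers <- function(ids_a, ids_b, ids_lab) {
  la <- encode_layer(omics_matrix(
    matrix(rnorm(length(ids_a) * 3), length(ids_a), 3), "gene_expression",
    ids_a, c("g1", "g2", "g3")))
  lb <- encode_snp(omics_matrix(
    matrix("A", length(ids_b), 2), "snp", ids_b, c("m1", "m2")))
  lt <- label_table(ids_lab, rep(c("x", "y"), length.out = length(ids_lab)))
  list(layers = list(la, lb), labels = lt)
}

test_that("alignment inner-joins shared samples and keeps label order", {
  x <- make_labelled_layers(paste0("s", 1:5), paste0("s", 2:6), paste0("s", 1:6))
  d <- suppressMessages(align_samples(x$layers, x$labels))
  expect_equal(d$sample_ids, paste0("s", 2:5))
  expect_equal(d$layers[[1]]$sample_ids, d$sample_ids)
  expect_equal(d$labels$sample_ids, d$sample_ids)

  same <- make_labelled_layers(paste0("s", 1:4), paste0("s", 1:4),
                               paste0("s", 1:4))
  expect_equal(align_samples(same$layers, same$labels)$sample_ids,
               paste0("s", 1:4))

  disjoint <- make_labelled_layers(paste0("a", 1:4), paste0("b", 1:4),
                                   paste0("a", 1:4))
  expect_error(suppressMessages(align_samples(disjoint$layers,
                                              disjoint$labels)),
               "no sample ID shared")
})

test_that("60/20/20 split is exact, disjoint and stratified", {
  d <- planted_dataset(n = 100, p = 10, seed = 1)$dataset
  plan <- split_dataset(d, c(0.6, 0.2, 0.2), seed = 42)
  expect_length(plan$train_ids, 60)
  expect_length(plan$val_ids, 20)
  expect_length(plan$test_ids, 20)
  all_ids <- c(plan$train_ids, plan$val_ids, plan$test_ids)
  expect_setequal(all_ids, d$sample_ids)
  expect_equal(anyDuplicated(all_ids), 0L)
  # stratification: class proportions preserved within each partition
  lab <- setNames(d$labels$values, d$labels$sample_ids)
  for (part in list(plan$train_ids, plan$val_ids, plan$test_ids))
    expect_equal(unname(table(lab[part]))[1] / length(part), 0.5,
                 tolerance = 0.051)
})

test_that("splits are deterministic in the seed and validate fractions", {
  d <- planted_dataset(n = 50, p = 8, seed = 2)$dataset
  expect_identical(split_dataset(d, seed = 7), split_dataset(d, seed = 7))
  expect_false(identical(split_dataset(d, seed = 7)$train_ids,
                         split_dataset(d, seed = 8)$train_ids))
  expect_error(split_dataset(d, c(0.5, 0.2, 0.2)), "summing to 1")
  expect_error(split_dataset(d, c(0.6, 0.4)), "three positive")
})

test_that("a class smaller than the partition count is rejected", {
  lt <- label_table(paste0("s", 1:10), c(rep("a", 8), "b", "b"))
  layer <- encode_layer(omics_matrix(matrix(rnorm(30), 10, 3),
                                     "gene_expression", paste0("s", 1:10),
                                     c("g1", "g2", "g3")))
  d <- align_samples(list(layer), lt)
  expect_error(split_dataset(d, seed = 1), "fewer samples")
})

test_that("cv folds partition the cohort with sizes within one", {
  d <- planted_dataset(n = 100, p = 10, seed = 3)$dataset
  folds <- make_cv_folds(d, k = 5, seed = 0)
  sizes <- table(folds$assignments)
  expect_equal(unname(sizes), rep(20L, 5), ignore_attr = TRUE)
  expect_setequal(names(folds$assignments), d$sample_ids)
  # stratified: each fold holds 10 per class
  lab <- setNames(d$labels$values, d$labels$sample_ids)
  for (f in 1:5) {
    ids <- names(folds$assignments)[folds$assignments == f]
    expect_equal(unname(table(lab[ids])), c(10L, 10L), ignore_attr = TRUE)
  }
  # uneven n: sizes differ by at most 1
  d2 <- planted_dataset(n = 53, p = 5, seed = 4)$dataset
  f2 <- make_cv_folds(d2, k = 5, seed = 0)
  expect_lte(diff(range(table(f2$assignments))), 1)

  expect_error(make_cv_folds(d, k = 0), "k must be")
  expect_error(make_cv_folds(d, k = 101), "exceeds the number of samples")
})

test_that("plans serialize to JSON and back unchanged", {
  d <- planted_dataset(n = 40, p = 5, seed = 5)$dataset
  plan <- split_dataset(d, seed = 3)
  f <- withr::local_tempfile(fileext = ".json")
  write_plan(plan, f)
  expect_equal(read_plan(f), plan, ignore_attr = TRUE)

  folds <- make_cv_folds(d, k = 4, seed = 3)
  write_plan(folds, f)
  expect_equal(read_plan(f), folds, ignore_attr = TRUE)
})

test_that("dataset_subset reorders every layer and the labels together", {
  d <- planted_dataset(n = 30, p = 6, seed = 6)$dataset
  ids <- rev(d$sample_ids[1:10])
  s <- dataset_subset(d, ids)
  expect_equal(s$sample_ids, ids)
  expect_equal(s$labels$values,
               d$labels$values[match(ids, d$sample_ids)])
  expect_equal(s$layers[[1]]$tensor[3, , ],
               d$layers[[1]]$tensor[match(ids[3], d$sample_ids), , ])
  expect_error(dataset_subset(d, "nope"), "not in dataset")
})
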