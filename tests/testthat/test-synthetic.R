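test_that("planted continuous effects match their nominal size", {
  sp <- synthetic_spec(
    n_samples = 200, class_balance = 0.5,
    layers = list(list(type = "gene_expression", n_features = 1000,
                       n_planted = 10, effect_size = 2, missing_rate = 0)),
    seed = 7)
  gen <- generate_synthetic(sp)
  m <- gen$matrices$gene_expression
  pos <- gen$labels$values == "class1"
  planted <- gen$manifest$planted$gene_expression
  expect_length(planted, 10)
  se <- sqrt(1 / sum(pos) + 1 / sum(!pos))
  for (f in planted) {
    diff <- mean(m$values[pos, f]) - mean(m$values[!pos, f])
    expect_lt(abs(diff - 2), 3 * se)
  }
  # null features carry no shift (pooled check)
  nulls <- setdiff(m$feature_ids, planted)[1:50]
  diffs <- colMeans(m$values[pos, nulls]) - colMeans(m$values[!pos, nulls])
  expect_lt(abs(mean(diffs)), 4 * se / sqrt(50))
})

test_that("identical seeds produce byte-identical files", {
  sp <- synthetic_spec(n_samples = 30, layers = list(
    list(type = "gene_expression", n_features = 20, n_planted = 2,
         effect_size = 1, missing_rate = 0.1),
    list(type = "snp", n_features = 10, n_planted = 2, effect_size = 1,
         missing_rate = 0.05)), seed = 11)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- generate_synthetic(sp, dir = d1)$files
  f2 <- generate_synthetic(sp, dir = d2)$files
  for (i in seq_along(f1))
    expect_identical(readLines(f1[i]), readLines(f2[i]))
  # and a different seed changes the data
  sp2 <- sp; sp2$seed <- 12L
  d3 <- withr::local_tempdir()
  f3 <- generate_synthetic(sp2, dir = d3)$files
  expect_false(identical(readLines(f1[1]), readLines(f3[1])))
})

test_that("generated CSVs round-trip through the readers into the pipeline", {
  sp <- synthetic_spec(n_samples = 40, layers = list(
    list(type = "gene_expression", n_features = 15, n_planted = 2,
         effect_size = 2, missing_rate = 0.1),
    list(type = "snp", n_features = 8, n_planted = 1, effect_size = 1,
         missing_rate = 0.1),
    list(type = "cnv", n_features = 6, n_planted = 1, effect_size = 1,
         missing_rate = 0)), seed = 13)
  dir <- withr::local_tempdir()
  gen <- generate_synthetic(sp, dir = dir)
  layers <- list(
    read_omics_csv(file.path(dir, "gene_expression.csv"), "gene_expression"),
    read_omics_csv(file.path(dir, "snp.csv"), "snp"),
    read_omics_csv(file.path(dir, "cnv.csv"), "cnv"))
  labels <- read_labels(file.path(dir, "labels.csv"), "categorical")
  d <- align_samples(lapply(layers, encode_layer), labels)
  expect_equal(length(d$sample_ids), 40)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  expect_setequal(manifest$planted$gene_expression,
                  gen$manifest$planted$gene_expression)
})

test_that("null data (no planted features) gives chance-level AUC", {
  aucs <- vapply(0:2, function(s) {
    sp <- synthetic_spec(n_samples = 100, layers = list(
      list(type = "gene_expression", n_features = 50, n_planted = 0,
           effect_size = 0, missing_rate = 0)), seed = s)
    sd <- make_synthetic_dataset(sp)
    expect_length(sd$manifest$planted$gene_expression, 0)
    d <- sd$dataset
    plan <- split_dataset(d, c(0.6, 0.2, 0.2), seed = s)
    fit <- fit_baseline("lr", flatten(dataset_subset(d, plan$train_ids)),
                        seed = s)
    te <- dataset_subset(d, plan$test_ids)
    roc_auc(te$labels$values,
            predict(fit, flatten(te))[[paste0(".pred_", fit$classes[2])]])
  }, 0)
  expect_true(all(aucs > 0.2 & aucs < 0.8))
  expect_lt(abs(mean(aucs) - 0.5), 0.2)
})

test_that("categorical layers shift the planted category between classes", {
  sp <- synthetic_spec(n_samples = 400, layers = list(
    list(type = "snp", n_features = 30, n_planted = 5, effect_size = 2,
         missing_rate = 0)), seed = 17)
  gen <- generate_synthetic(sp)
  m <- gen$matrices$snp
  pos <- gen$labels$values == "class1"
  # planted features: the class-1 frequency of some genotype rises by ~0.3
  for (f in gen$manifest$planted$snp) {
    p1 <- table(factor(m$values[pos, f], levels = c("A", "T", "C", "G"))) /
      sum(pos)
    p0 <- table(factor(m$values[!pos, f], levels = c("A", "T", "C", "G"))) /
      sum(!pos)
    expect_gt(max(p1 - p0), 0.15)
  }
})

test_that("infeasible layer configs are rejected", {
  expect_error(synthetic_spec(layers = list(
    list(type = "cnv", n_features = 10, n_planted = 1, effect_size = 1,
         missing_rate = 0.2))), "missing_rate must be 0 for cnv")
  expect_error(synthetic_spec(layers = list(
    list(type = "snp", n_features = 5, n_planted = 9, effect_size = 1,
         missing_rate = 0))))
  expect_error(synthetic_spec(n_samples = 10, class_balance = 1.2))
})

test_that("manifest_check computes precision and recall at k", {
  rep <- structure(tibble::tibble(
    feature = c("p1", "p2", "n1", "n2", "p3"), layer = "l",
    saliency = c(0.9, 0.8, 0.7, 0.6, 0.5), dense_rank = 1:5,
    gene = NA_character_),
    class = c("marker_report", "tbl_df", "tbl", "data.frame"))
  manifest <- list(planted = list(l = c("p1", "p2", "p3")))
  chk <- manifest_check(rep, manifest, k = 3)
  expect_equal(chk$precision_at_k, 2 / 3)
  expect_equal(chk$recall_at_k, 2 / 3)
  perfect <- manifest_check(rep, list(planted = list(l = c("p1", "p2"))), k = 2)
  expect_equal(perfect$precision_at_k, 1)
  expect_equal(perfect$recall_at_k, 1)
  expect_error(manifest_check(rep, manifest, k = 0), "k must be")
  expect_error(manifest_check(rep, list(planted = list(l = "zz")), k = 2),
               "disjoint namespaces")
})

test_that("a random report recovers planted markers at the chance rate", {
  features <- sprintf("g%04d", 1:1000)
  planted <- sample(features, 10)
  manifest <- list(planted = list(gene_expression = planted))
  precisions <- vapply(1:100, function(s) {
    sal <- with_seed(s, runif(1000))
    rep <- structure(tibble::tibble(
      feature = features, layer = "gene_expression", saliency = sal,
      dense_rank = dense_rank_saliency(sal), gene = NA_character_),
      class = c("marker_report", "tbl_df", "tbl", "data.frame"))
    manifest_check(rep, manifest, k = 10)$precision_at_k
  }, 0)
  expect_lt(abs(mean(precisions) - 0.01), 0.02)
})
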