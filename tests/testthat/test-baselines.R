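test_that("flatten concatenates layers with unique layer-qualified names", {
  sd <- tiny_multiomics()
  fl <- flatten(sd$dataset)
  # 30 expression x 1ch + 20 snp x 5ch + 15 cnv x 5ch
  expect_equal(ncol(fl$matrix), 30 + 100 + 75)
  expect_equal(anyDuplicated(fl$feature_names), 0L)
  expect_equal(fl$feature_names, fl$feature_map$name)
  # single 1-channel layer flattens to the squeezed tensor
  one <- planted_dataset(n = 20, p = 6, seed = 1)$dataset
  fl1 <- flatten(one)
  expect_equal(unname(fl1$matrix), one$layers[[1]]$tensor[, , 1],
               ignore_attr = TRUE)
  # name bijection: every column recoverable from (layer, feature, channel)
  expect_equal(paste(fl$feature_map$layer, fl$feature_map$feature,
                     fl$feature_map$channel, sep = ":"),
               fl$feature_names)
})

test_that("all four baselines fit, predict probabilities, and beat chance on signal", {
  sd <- planted_dataset(n = 120, p = 25, n_planted = 5, delta = 2, seed = 2)
  d <- sd$dataset
  plan <- split_dataset(d, c(0.6, 0.2, 0.2), seed = 2)
  fl_tr <- flatten(dataset_subset(d, plan$train_ids))
  d_va <- dataset_subset(d, plan$val_ids)
  fl_va <- flatten(d_va)
  for (kind in c("lr", "svm", "dt", "rf")) {
    fit <- fit_baseline(kind, fl_tr, seed = 2)
    pr <- predict(fit, fl_va)
    probs <- as.matrix(pr[, -1])
    expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)),
                 tolerance = 1e-6)
    auc <- roc_auc(d_va$labels$values, pr[[paste0(".pred_", fit$classes[2])]])
    if (kind %in% c("lr", "svm", "rf"))
      expect_gte(auc, 0.9)
    else expect_gte(auc, 0.6)  # a single tree is weaker but above chance
  }
})

test_that("LR on the separable fixture reaches the oracle bar", {
  sd <- planted_dataset(n = 200, p = 50, n_planted = 5, delta = 2, seed = 4)
  d <- sd$dataset
  plan <- split_dataset(d, c(0.6, 0.2, 0.2), seed = 4)
  fit <- fit_baseline("lr", flatten(dataset_subset(d, plan$train_ids)),
                      seed = 4)
  d_va <- dataset_subset(d, plan$val_ids)
  auc <- roc_auc(d_va$labels$values,
                 predict(fit, flatten(d_va))[[paste0(".pred_",
                                                     fit$classes[2])]])
  expect_gte(auc, 0.95)
})

test_that("RF on permuted labels stays in the null band", {
  aucs <- vapply(0:1, function(s) {
    sd <- planted_dataset(n = 100, p = 30, n_planted = 3, delta = 2, seed = s)
    d <- sd$dataset
    d$labels$values <- with_seed(200 + s, sample(d$labels$values))
    plan <- split_dataset(d, c(0.6, 0.2, 0.2), seed = s)
    fit <- fit_baseline("rf", flatten(dataset_subset(d, plan$train_ids)),
                        params = list(num_trees = 200), seed = s)
    d_te <- dataset_subset(d, plan$test_ids)
    roc_auc(d_te$labels$values,
            predict(fit, flatten(d_te))[[paste0(".pred_", fit$classes[2])]])
  }, 0)
  # 20 held-out samples: a null AUC has sd ~ 0.13, so the band is ~2.3 sd;
  # the tight null band is asserted on the large cross-validated benchmark
  expect_true(all(aucs > 0.2 & aucs < 0.8))
  expect_lt(abs(mean(aucs) - 0.5), 0.25)
})

test_that("degenerate fits are handled: two samples, one per class", {
  x <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(NULL, c("a", "b")))
  fl <- structure(list(sample_ids = c("s1", "s2"), feature_names = c("a", "b"),
                       matrix = x,
                       labels = label_table(c("s1", "s2"), c("u", "v")),
                       feature_map = tibble::tibble(
                         name = c("a", "b"), layer = "l", feature = c("a", "b"),
                         channel = "value")),
                  class = "flat_dataset")
  fit <- fit_baseline("dt", fl, seed = 1)
  pr <- predict(fit, fl)
  expect_equal(dim(pr), c(2L, 3L))
  # single-class labels are rejected
  fl_bad <- fl
  fl_bad$labels <- structure(list(sample_ids = c("s1", "s2"),
                                  task = "categorical",
                                  values = c("u", "u")),
                             class = "label_table")
  expect_error(fit_baseline("lr", fl_bad, seed = 1), "single class")
})

test_that("importances: |coef| for LR, normalised impurity for RF, permutation for SVM", {
  sd <- planted_dataset(n = 100, p = 15, n_planted = 3, delta = 2.5, seed = 6)
  fl <- flatten(sd$dataset)
  planted_cols <- paste0("gene_expression:", sd$manifest$planted[[1]],
                         ":value")

  lr <- fit_baseline("lr", fl, seed = 6)
  imp_lr <- baseline_importance(lr)
  expect_length(imp_lr, ncol(fl$matrix))
  expect_true(all(imp_lr >= 0))
  cf <- as.vector(coef(lr$fit))[-1]
  expect_equal(unname(imp_lr), abs(cf))

  rf <- fit_baseline("rf", fl, params = list(num_trees = 200), seed = 6)
  imp_rf <- baseline_importance(rf)
  expect_equal(sum(imp_rf), 1, tolerance = 1e-9)
  # planted features rank high
  expect_true(all(planted_cols %in%
                    names(sort(imp_rf, decreasing = TRUE))[1:6]))

  svm <- fit_baseline("svm", fl, seed = 6)
  expect_error(baseline_importance(svm), "needs the data")
  imp_svm <- baseline_importance(svm, fl, n_shuffles = 3, seed = 6)
  expect_true(all(imp_svm >= 0))
  expect_gt(mean(imp_svm[planted_cols]), mean(imp_svm))
})
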