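test_that("architecture arity: one branch per layer, concat width is the sum", {
  spec <- fast_spec()
  for (nb in 1:3) {
    shapes <- rep(list(c(30L, 1L)), nb)
    g <- build_model(spec, shapes, seed = 1)
    expect_length(g$params$branches, nb)
    widths <- vapply(g$configs, `[[`, 1L, "rep_width")
    expect_equal(nrow(g$params$fc[[1]]$W), sum(widths))
  }
  expect_error(build_model(spec, list()), "between 1 and 3")
  expect_error(build_model(spec, rep(list(c(10L, 1L)), 4)), "between 1 and 3")
})

test_that("categorical outputs are softmax probabilities summing to one", {
  sd <- tiny_multiomics()
  d <- sd$dataset
  fit <- fit_multicnn(d, spec = fast_spec(max_epochs = 2), seed = 1)
  pr <- predict(fit, d, type = "prob")
  probs <- as.matrix(pr[, -1])
  expect_true(all(probs >= 0 & probs <= 1))
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)), tolerance = 1e-6)
  # output order matches input sample order
  expect_equal(pr$sample_id, d$sample_ids)
})

test_that("prediction is deterministic: duplicates and permutations behave", {
  sd <- tiny_multiomics()
  d <- sd$dataset
  fit <- fit_multicnn(d, spec = fast_spec(max_epochs = 2), seed = 1)
  ids <- d$sample_ids[1:10]
  p1 <- predict(fit, dataset_subset(d, ids))
  # duplicating a sample duplicates its prediction
  pdup <- predict(fit, dataset_subset(d, c(ids, ids[1])))
  expect_equal(unlist(pdup[11, -1]), unlist(p1[1, -1]))
  # permuting inputs permutes outputs identically
  perm <- rev(ids)
  p2 <- predict(fit, dataset_subset(d, perm))
  expect_equal(p2[match(ids, perm), -1], p1[, -1])
})

test_that("training history has one row per completed epoch and a restored best", {
  sd <- tiny_multiomics()
  fit <- fit_multicnn(sd$dataset, spec = fast_spec(max_epochs = 6), seed = 2)
  h <- tidy(fit)
  expect_true(all(c("epoch", "train_loss", "val_loss", "val_metric")
                  %in% names(h)))
  expect_equal(h$epoch, seq_len(nrow(h)))
  expect_lte(nrow(h), 6)
  expect_equal(fit$best_epoch, h$epoch[which.min(h$val_loss)])
})

test_that("seeded training is reproducible", {
  sd <- tiny_multiomics()
  f1 <- fit_multicnn(sd$dataset, spec = fast_spec(max_epochs = 4), seed = 7)
  f2 <- fit_multicnn(sd$dataset, spec = fast_spec(max_epochs = 4), seed = 7)
  expect_equal(f1$history, f2$history, tolerance = 1e-12)
  p1 <- predict(f1, sd$dataset)
  p2 <- predict(f2, sd$dataset)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("the CNN separates a planted-signal fixture like the LR oracle", {
  sd <- planted_dataset(n = 200, p = 100, n_planted = 10, delta = 2, seed = 3)
  d <- sd$dataset
  plan <- split_dataset(d, c(0.6, 0.2, 0.2), seed = 3)
  d_tr <- dataset_subset(d, plan$train_ids)
  d_va <- dataset_subset(d, plan$val_ids)
  # oracle: L2 logistic regression reaches >= 0.95 on the validation split
  lr <- fit_baseline("lr", flatten(d_tr), seed = 3)
  lr_scores <- predict(lr, flatten(d_va))[[paste0(".pred_", lr$classes[2])]]
  expect_gte(roc_auc(d_va$labels$values, lr_scores), 0.95)
  # the CNN must reach it too
  fit <- fit_multicnn(d_tr, d_va, seed = 3)
  scores <- predict(fit, d_va)[[paste0(".pred_", fit$classes[2])]]
  expect_gte(roc_auc(d_va$labels$values, scores), 0.95)
})

test_that("label permutation destroys the signal (null AUC band)", {
  aucs <- vapply(0:1, function(s) {
    sd <- planted_dataset(n = 120, p = 30, n_planted = 3, delta = 2, seed = s)
    d <- sd$dataset
    d$labels$values <- with_seed(s + 100, sample(d$labels$values))
    plan <- split_dataset(d, c(0.6, 0.2, 0.2), seed = s)
    fit <- fit_multicnn(dataset_subset(d, plan$train_ids),
                        dataset_subset(d, plan$val_ids),
                        spec = fast_spec(max_epochs = 6), seed = s)
    te <- dataset_subset(d, plan$test_ids)
    roc_auc(te$labels$values,
            predict(fit, te)[[paste0(".pred_", fit$classes[2])]])
  }, 0)
  # 24 held-out samples per seed: band sized to the null sampling noise; the
  # tight null band is asserted on the large cross-validated benchmark
  expect_true(all(aucs > 0.2 & aucs < 0.8))
})

test_that("feature or channel mismatches are rejected with a useful message", {
  sd <- tiny_multiomics()
  d <- sd$dataset
  fit <- fit_multicnn(d, spec = fast_spec(max_epochs = 2), seed = 1)
  d2 <- d
  d2$layers[[1]]$feature_ids[1] <- "renamed"
  expect_error(predict(fit, d2), "feature mismatch.*missing.*extra")
  d3 <- d
  names(d3$layers)[2] <- "other"
  expect_error(predict(fit, d3), "layer mismatch")
})

test_that("quantitative models regress toward correlated predictions", {
  sp <- synthetic_spec(
    n_samples = 150, task = "quantitative",
    layers = list(list(type = "gene_expression", n_features = 40,
                       n_planted = 8, effect_size = 3, missing_rate = 0)),
    seed = 5)
  sd <- make_synthetic_dataset(sp)
  d <- sd$dataset
  plan <- split_dataset(d, c(0.6, 0.2, 0.2), seed = 5)
  fit <- fit_multicnn(dataset_subset(d, plan$train_ids),
                      dataset_subset(d, plan$val_ids),
                      spec = model_spec(task = "quantitative"),
                      seed = 5)
  te <- dataset_subset(d, plan$test_ids)
  pred <- predict(fit, te)
  expect_equal(names(pred), c("sample_id", ".pred"))
  expect_gt(pcc(te$labels$values, pred$.pred), 0.5)
})
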