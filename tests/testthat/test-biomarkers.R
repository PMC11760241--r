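test_that("saliency gradients vanish for a zero-weight model", {
  sd <- tiny_multiomics()
  d <- sd$dataset
  fit <- fit_multicnn(d, spec = fast_spec(max_epochs = 2), seed = 1)
  zero <- fit
  zero$params <- phenomix:::tree_map(function(x, ...) x * 0, zero$params)
  grads <- saliency_map(zero, d)
  expect_true(all(vapply(grads$gradients, function(g) all(g == 0), TRUE)))
  agg <- aggregate_saliency(grads)
  expect_true(all(agg$saliency == 0))
})

test_that("analytic input gradients match central finite differences", {
  sd <- tiny_multiomics(n = 40)
  d <- sd$dataset
  fit <- fit_multicnn(d, spec = fast_spec(max_epochs = 3), seed = 2)
  target <- 2L
  grads <- saliency_map(fit, d, target = target)
  eps <- 1e-4
  set.seed(30)
  for (i in 1:5) {
    b <- sample(length(d$layers), 1)
    dims <- dim(d$layers[[b]]$tensor)
    at <- c(sample(dims[1], 1), sample(dims[2], 1), sample(dims[3], 1))
    bump <- function(h) {
      d2 <- d
      d2$layers[[b]]$tensor[at[1], at[2], at[3]] <-
        d2$layers[[b]]$tensor[at[1], at[2], at[3]] + h
      phenomix:::predict_logits(fit, d2)[at[1], target]
    }
    fd <- (bump(eps) - bump(-eps)) / (2 * eps)
    expect_equal(grads$gradients[[b]][at[1], at[2], at[3]], fd,
                 tolerance = 1e-3)
  }
})

test_that("aggregation is channel-collapsed, non-negative and order-invariant", {
  sd <- tiny_multiomics()
  d <- sd$dataset
  fit <- fit_multicnn(d, spec = fast_spec(max_epochs = 3), seed = 3)
  agg <- aggregate_saliency(saliency_map(fit, d))
  # one entry per feature, never per channel
  expect_equal(nrow(agg), 30 + 20 + 15)
  expect_true(all(agg$saliency >= 0))
  perm <- dataset_subset(d, rev(d$sample_ids))
  agg2 <- aggregate_saliency(saliency_map(fit, perm))
  expect_equal(agg2$saliency, agg$saliency, tolerance = 1e-12)
})

test_that("dense ranks share ties and have no gaps", {
  expect_equal(dense_rank_saliency(c(a = 0.9, b = 0.7, c = 0.9, d = 0.1)),
               c(a = 1L, b = 2L, c = 1L, d = 3L))
  expect_equal(unname(dense_rank_saliency(c(1, 1, 1))), c(1L, 1L, 1L))
  expect_equal(unname(dense_rank_saliency(5)), 1L)
  expect_error(dense_rank_saliency(numeric()), "empty")
  # rank order equals saliency order
  set.seed(31)
  s <- round(runif(50), 2)
  r <- dense_rank_saliency(s)
  expect_equal(order(r, s), order(-s, s))
  expect_equal(sort(unique(r)), seq_len(length(unique(s))))
})

test_that("top_markers keeps boundary ties and handles thresholds", {
  rep <- structure(tibble::tibble(
    feature = paste0("f", 1:6), layer = "l",
    saliency = c(0.9, 0.8, 0.8, 0.5, 0.5, 0.1),
    dense_rank = c(1L, 2L, 2L, 3L, 3L, 4L), gene = NA_character_),
    class = c("marker_report", "tbl_df", "tbl", "data.frame"))
  expect_equal(nrow(top_markers(rep, k = 2)), 3)   # tie at the boundary
  expect_equal(top_markers(rep, k = 1)$feature, "f1")
  expect_equal(nrow(top_markers(rep, threshold = 0.5)), 5)
  expect_equal(nrow(top_markers(rep, threshold = 2)), 0)
  expect_warning(all_rows <- top_markers(rep, k = 99), "returning all")
  expect_equal(nrow(all_rows), 6)
  expect_error(top_markers(rep, k = 2, threshold = 0.5), "exactly one")
})

test_that("marker reports rank planted features first on a strong fixture", {
  sd <- planted_dataset(n = 150, p = 200, n_planted = 5, delta = 2.5, seed = 8)
  d <- sd$dataset
  fit <- fit_multicnn(d, spec = model_spec(max_epochs = 30, patience = 8),
                      seed = 8)
  rep <- marker_report(fit, d)
  expect_s3_class(rep, "marker_report")
  # sorted by decreasing saliency; ranks consistent with saliency
  expect_true(all(diff(rep$saliency) <= 1e-12))
  expect_equal(order(rep$dense_rank), seq_len(nrow(rep)))
  chk <- manifest_check(rep, sd$manifest, k = 5)
  expect_gte(chk$hits, 4)
})

test_that("markers map to genes with pass-through and min-rank dedup", {
  rep <- structure(tibble::tibble(
    feature = c("cg01", "cg02", "TP53", "snp1"),
    layer = c("dna_methylation", "dna_methylation", "gene_expression", "snp"),
    saliency = c(0.9, 0.7, 0.6, 0.5), dense_rank = 1:4,
    gene = NA_character_),
    class = c("marker_report", "tbl_df", "tbl", "data.frame"))
  ann <- marker_annotation(data.frame(
    marker = c("cg01", "cg02"), chrom = "chr1", start = c(0, 10),
    end = c(5, 15), gene = c("GENE1", "GENE1")))
  out <- map_markers_to_genes(rep, ann)
  # two CpGs collapse onto GENE1 at the better rank
  expect_equal(out$genes$gene, c("GENE1", "TP53"))
  expect_equal(out$genes$dense_rank[out$genes$gene == "GENE1"], 1L)
  # unannotated non-gene marker is reported unmapped
  expect_equal(out$unmapped, "snp1")
})

test_that("baseline importances aggregate channels into feature-level reports", {
  sd <- tiny_multiomics(n = 80)
  fl <- flatten(sd$dataset)
  rf <- fit_baseline("rf", fl, params = list(num_trees = 100), seed = 9)
  rep <- baseline_marker_report(rf, fl)
  expect_equal(nrow(rep), 30 + 20 + 15)  # per feature, channels summed
  expect_true(all(rep$saliency >= 0))
  expect_equal(order(rep$dense_rank), seq_len(nrow(rep)))
})
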