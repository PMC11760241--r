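# Shared fixture builders. Everything is generated in code at test time.

# A small expression omics_matrix with reproducible values.
tiny_expression <- function(n = 6, p = 4, seed = 1, type = "gene_expression") {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("g%03d", seq_len(p))))
  omics_matrix(m, type)
}

tiny_snp <- function(n = 6, p = 4, seed = 2) {
  set.seed(seed)
  m <- matrix(sample(c("A", "T", "C", "G", "missing"), n * p, TRUE), n, p,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("snp%03d", seq_len(p))))
  omics_matrix(m, "snp")
}

tiny_cnv <- function(n = 6, p = 4, seed = 3) {
  set.seed(seed)
  m <- matrix(sample(as.character(-2:2), n * p, TRUE), n, p,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("cnv%03d", seq_len(p))))
  omics_matrix(m, "cnv")
}

# A one-layer separable two-class dataset with planted mean shifts: the
# standard small benchmark for model tests.
planted_dataset <- function(n = 200, p = 50, n_planted = 5, delta = 2,
                            seed = 0) {
  sp <- synthetic_spec(
    n_samples = n, class_balance = 0.5,
    layers = list(list(type = "gene_expression", n_features = p,
                       n_planted = n_planted, effect_size = delta,
                       missing_rate = 0)),
    seed = seed)
  make_synthetic_dataset(sp)
}

# Independent AUC oracle: brute-force Mann-Whitney pair counting.
auc_pair_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Independent exact hypergeometric upper tail via binomial coefficients.
hyper_tail_oracle <- function(overlap, set_size, query_size, universe_size) {
  xs <- overlap:min(set_size, query_size)
  sum(choose(set_size, xs) *
        choose(universe_size - set_size, query_size - xs)) /
    choose(universe_size, query_size)
}

# Tiny three-layer dataset for architecture tests (fast to train).
tiny_multiomics <- function(n = 60, seed = 4) {
  sp <- synthetic_spec(
    n_samples = n, class_balance = 0.5,
    layers = list(
      list(type = "gene_expression", n_features = 30, n_planted = 3,
           effect_size = 2, missing_rate = 0),
      list(type = "snp", n_features = 20, n_planted = 2, effect_size = 2,
           missing_rate = 0),
      list(type = "cnv", n_features = 15, n_planted = 2, effect_size = 2,
           missing_rate = 0)),
    seed = seed)
  make_synthetic_dataset(sp)
}

fast_spec <- function(...) {
  args <- list(conv_layers = list(list(kernel_size = 3, n_filters = 4),
                                  list(kernel_size = 3, n_filters = 8)),
               pool_size = 2, fc_widths = c(16, 8), max_epochs = 8,
               patience = 4, batch_size = 16)
  do.call(model_spec, utils::modifyList(args, list(...)))
}
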