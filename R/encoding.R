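# Per-omics encodings: z-scoring, zero imputation, one-hot SNP/CNV channels,
# CpG annotation filtering.

#' Construct an encoded layer
#'
#' An `encoded_layer` is a samples x features x channels numeric array ready
#' for one model branch, plus the channel labels and the encoding kind.
#' Continuous layers have one channel; one-hot layers have exactly one channel
#' equal to 1 per (sample, feature) position.
#'
#' @param tensor 3-d numeric array (samples, features, channels).
#' @param omics_type Omics type tag.
#' @param sample_ids,feature_ids,channels ID/label vectors matching `tensor`.
#' @param encoding_kind `"zscored_continuous"` or `"onehot"`.
#' @return An `encoded_layer` object.
#' @export
encoded_layer <- function(tensor, omics_type, sample_ids, feature_ids,
                          channels,
                          encoding_kind = c("zscored_continuous", "onehot")) {
  encoding_kind <- match.arg(encoding_kind)
  stopifnot(length(dim(tensor)) == 3,
            dim(tensor)[1] == length(sample_ids),
            dim(tensor)[2] == length(feature_ids),
            dim(tensor)[3] == length(channels))
  if (anyNA(tensor) || any(!is.finite(tensor)))
    stop("encoded tensor must be finite (no missing values after encoding)",
         call. = FALSE)
  structure(
    list(omics_type = omics_type, sample_ids = as.character(sample_ids),
         feature_ids = as.character(feature_ids), tensor = tensor,
         channels = as.character(channels), encoding_kind = encoding_kind),
    class = "encoded_layer")
}

#' @export
print.encoded_layer <- function(x, ...) {
  d <- dim(x$tensor)
  cat(sprintf("<encoded_layer: %s (%s), %d x %d x %d>\n", x$omics_type,
              x$encoding_kind, d[1], d[2], d[3]))
  invisible(x)
}

#' Z-score an expression-like layer and impute missing values to zero
#'
#' Each sample (row) is normalised to zero mean and unit standard deviation
#' using the population standard deviation (divisor n) computed over its
#' observed entries; missing entries are then set to 0, i.e. the post-
#' normalisation per-sample mean. Zero-variance rows map to all-zero scores.
#' Set `axis = "feature"` to normalise per feature (column) instead.
#'
#' @param m An [omics_matrix()] of an expression-like type.
#' @param axis Normalisation axis, `"sample"` (default) or `"feature"`.
#' @return A one-channel [encoded_layer()].
#' @export
zscore_per_sample <- function(m, axis = c("sample", "feature")) {
  stopifnot(inherits(m, "omics_matrix"))
  axis <- match.arg(axis)
  if (!is_expression_type(m$omics_type))
    stop("z-scoring applies to expression-like layers, not ", m$omics_type,
         call. = FALSE)
  x <- m$values
  if (axis == "feature") x <- t(x)
  n_obs <- rowSums(!is.na(x))
  mu <- rowMeans(x, na.rm = TRUE)
  mu[n_obs == 0] <- 0
  cx <- x - mu
  sd_pop <- sqrt(rowSums(cx^2, na.rm = TRUE) / pmax(n_obs, 1))
  keep <- sd_pop > 0
  z <- cx
  z[keep, ] <- cx[keep, , drop = FALSE] / sd_pop[keep]
  z[!keep, ] <- 0
  z[is.na(z)] <- 0
  if (axis == "feature") z <- t(z)
  encoded_layer(array(z, dim = c(dim(z), 1L)), m$omics_type,
                m$sample_ids, m$feature_ids, channels = "value",
                encoding_kind = "zscored_continuous")
}

#' Replace missing expression values with zero
#'
#' Zero imputation on the raw matrix. In the standard pipeline
#' ([zscore_per_sample()]) imputation happens after z-scoring of the observed
#' entries, so the imputed zero is the per-sample mean; this helper covers the
#' raw-matrix form of the same rule.
#'
#' @param m An expression-like [omics_matrix()].
#' @return An [omics_matrix()] with no missing values.
#' @export
impute_expression_missing <- function(m) {
  stopifnot(inherits(m, "omics_matrix"))
  if (!is_expression_type(m$omics_type))
    stop("imputation applies to expression-like layers only; SNP and CNV ",
         "layers are never imputed", call. = FALSE)
  m$values[is.na(m$values)] <- 0
  m
}

onehot_encode <- function(m, vocab) {
  n <- length(m$sample_ids); p <- length(m$feature_ids); k <- length(vocab)
  idx <- match(as.vector(m$values), vocab)
  if (anyNA(idx)) {
    bad <- unique(as.vector(m$values)[is.na(idx)])
    stop("token(s) outside vocabulary: ", toString(sQuote(bad)),
         "; allowed: ", toString(vocab), call. = FALSE)
  }
  tensor <- array(0, dim = c(n, p, k))
  # linear index of the hot channel for every (sample, feature) cell
  cell <- seq_len(n * p)
  tensor[cell + (idx - 1L) * (n * p)] <- 1
  tensor
}

#' One-hot encode a SNP genotype layer
#'
#' Five channels in fixed order A, T, C, G, missing. The missing token is a
#' channel of its own: SNP layers are never imputed.
#'
#' @param m An [omics_matrix()] with `omics_type = "snp"`.
#' @return A five-channel one-hot [encoded_layer()].
#' @export
encode_snp <- function(m) {
  stopifnot(inherits(m, "omics_matrix"))
  if (m$omics_type != "snp") stop("expected a snp layer", call. = FALSE)
  encoded_layer(onehot_encode(m, SNP_TOKENS), "snp", m$sample_ids,
                m$feature_ids, channels = SNP_TOKENS, encoding_kind = "onehot")
}

#' One-hot encode a copy-number layer
#'
#' Five channels in fixed order: homozygous deletion, single-copy deletion,
#' diploid normal, low-level amplification, high-level amplification
#' (numeric aliases -2..2). CNV layers are never imputed.
#'
#' @param m An [omics_matrix()] with `omics_type = "cnv"`.
#' @return A five-channel one-hot [encoded_layer()].
#' @export
encode_cnv <- function(m) {
  stopifnot(inherits(m, "omics_matrix"))
  if (m$omics_type != "cnv") stop("expected a cnv layer", call. = FALSE)
  encoded_layer(onehot_encode(m, CNV_STATES), "cnv", m$sample_ids,
                m$feature_ids, channels = CNV_STATES, encoding_kind = "onehot")
}

#' Restrict a methylation layer to annotated CpG markers
#'
#' Keeps only CpG features present in the marker annotation (i.e. those that
#' fall in promoter regions or genes per the annotation) and reports how many
#' were dropped.
#'
#' @param m An [omics_matrix()] with `omics_type = "dna_methylation"`.
#' @param ann A [marker_annotation()].
#' @return The filtered [omics_matrix()], with attribute `"dropped"` holding
#'   the number of removed features.
#' @export
filter_methylation <- function(m, ann) {
  stopifnot(inherits(m, "omics_matrix"), inherits(ann, "marker_annotation"))
  if (m$omics_type != "dna_methylation")
    stop("expected a dna_methylation layer", call. = FALSE)
  keep <- m$feature_ids %in% ann$marker
  if (!any(keep))
    stop("no methylation feature matches the annotation; check that marker ",
         "IDs agree between the layer and the annotation file", call. = FALSE)
  dropped <- sum(!keep)
  out <- omics_matrix(m$values[, keep, drop = FALSE], m$omics_type,
                      m$sample_ids, m$feature_ids[keep], m$source_tag)
  message(sprintf("filter_methylation: kept %d of %d CpG features (%d dropped)",
                  sum(keep), length(keep), dropped))
  attr(out, "dropped") <- dropped
  out
}

#' Encode any omics layer with its type's standard encoding
#'
#' Dispatches to [zscore_per_sample()] (expression-like), [encode_snp()] or
#' [encode_cnv()].
#'
#' @param m An [omics_matrix()].
#' @param axis Normalisation axis for expression-like layers.
#' @return An [encoded_layer()].
#' @export
encode_layer <- function(m, axis = c("sample", "feature")) {
  stopifnot(inherits(m, "omics_matrix"))
  switch(m$omics_type,
         snp = encode_snp(m),
         cnv = encode_cnv(m),
         zscore_per_sample(m, axis = match.arg(axis)))
}
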