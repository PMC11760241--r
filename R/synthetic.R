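# Synthetic multi-omics generator with planted class-associated features:
# the offline test bed for every pipeline stage. Continuous layers are
# standard normal with a mean shift of delta (in sd units) planted in the
# positive class; categorical SNP/CNV layers draw from per-feature category
# frequencies shared across classes, with a Dirichlet-perturbed,
# delta-scaled frequency shift planted in the positive class.

#' Describe a synthetic multi-omics study
#'
#' The defaults are the package's reference benchmark: 300 samples, balanced
#' two-class phenotype, three layers — expression with 1000 features (10
#' planted at effect size 2), SNP with 500 (5 planted), CNV with 200 (5
#' planted) — and no missingness.
#'
#' @param n_samples Cohort size.
#' @param class_balance Fraction of samples in the positive class
#'   (`"class1"`, the class carrying the planted shift), in (0, 1).
#' @param layers List of per-layer configs:
#'   `list(type, n_features, n_planted, effect_size, missing_rate)`.
#'   `effect_size` is a mean shift in sd units for continuous layers and
#'   scales the category-frequency shift (`0.15 * effect_size`, capped so
#'   frequencies stay below 0.95) for snp/cnv layers.
#' @param task `"categorical"` (default) or `"quantitative"` (labels are then
#'   standard-normal and planted continuous features are correlated with
#'   them; categorical layers carry no quantitative signal).
#' @param seed Integer seed; generation is byte-reproducible given it.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_samples = 300, class_balance = 0.5,
                           layers = list(
                             list(type = "gene_expression", n_features = 1000,
                                  n_planted = 10, effect_size = 2,
                                  missing_rate = 0),
                             list(type = "snp", n_features = 500,
                                  n_planted = 5, effect_size = 2,
                                  missing_rate = 0),
                             list(type = "cnv", n_features = 200,
                                  n_planted = 5, effect_size = 2,
                                  missing_rate = 0)),
                           task = c("categorical", "quantitative"),
                           seed = 0) {
  task <- match.arg(task)
  stopifnot(n_samples >= 4, class_balance > 0, class_balance < 1,
            length(layers) >= 1, length(layers) <= 3)
  layers <- lapply(layers, function(l) {
    l <- utils::modifyList(list(n_planted = 0, effect_size = 1,
                                missing_rate = 0), as.list(l))
    l$type <- match.arg(l$type, OMICS_TYPES)
    stopifnot(l$n_features >= 1, l$n_planted >= 0,
              l$n_planted <= l$n_features,
              l$missing_rate >= 0, l$missing_rate < 1)
    if (l$type == "cnv" && l$missing_rate > 0)
      stop("the five CNV states include no missing category; ",
           "missing_rate must be 0 for cnv layers", call. = FALSE)
    l
  })
  structure(list(n_samples = as.integer(n_samples),
                 class_balance = class_balance, layers = layers, task = task,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

feature_prefix <- c(gene_expression = "gene", mirna_expression = "mir",
                    dna_methylation = "cg", protein_expression = "prot",
                    snp = "snp", cnv = "cnvseg")

# Shift probability mass onto category `a` by eps, scaling the rest down.
shift_freq <- function(p, a, eps) {
  if (p[a] + eps >= 1)
    stop("infeasible frequency shift: base frequency ", round(p[a], 3),
         " + shift ", round(eps, 3), " >= 1", call. = FALSE)
  q <- p * (1 - (p[a] + eps)) / (1 - p[a])
  q[a] <- p[a] + eps
  q
}

#' Generate a synthetic multi-omics study
#'
#' Draws the cohort described by a [synthetic_spec()]; optionally writes the
#' per-layer CSVs (the same dialect [read_omics_csv()] reads), a labels CSV
#' and a JSON ground-truth manifest to `dir`. Identical seeds produce
#' byte-identical files.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Optional output directory (created if needed).
#' @return List with `matrices` (named [omics_matrix()] list), `labels`
#'   (a [label_table()]), `manifest` (per-layer planted feature IDs plus the
#'   spec echoed back), and `files` (paths, when `dir` is given).
#' @export
generate_synthetic <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_samples
  with_seed(spec$seed, {
    sample_ids <- sprintf("S%04d", seq_len(n))
    if (spec$task == "categorical") {
      n1 <- round(n * spec$class_balance)
      if (n1 < 2 || n - n1 < 2)
        stop("class balance leaves fewer than 2 samples in a class",
             call. = FALSE)
      y <- sample(c(rep("class1", n1), rep("class0", n - n1)))
      is_pos <- y == "class1"
      labels <- label_table(sample_ids, y, task = "categorical")
    } else {
      y <- stats::rnorm(n)
      is_pos <- rep(FALSE, n)
      labels <- label_table(sample_ids, y, task = "quantitative")
    }

    matrices <- list(); planted <- list()
    for (l in spec$layers) {
      prefix <- feature_prefix[[l$type]]
      fids <- sprintf("%s%05d", prefix, seq_len(l$n_features))
      pl <- sort(sample.int(l$n_features, l$n_planted))
      if (is_expression_type(l$type)) {
        x <- matrix(stats::rnorm(n * l$n_features), n, l$n_features)
        if (l$n_planted) {
          if (spec$task == "categorical")
            x[is_pos, pl] <- x[is_pos, pl] + l$effect_size
          else
            x[, pl] <- x[, pl] + (l$effect_size / 2) * y
        }
        if (l$missing_rate > 0)
          x[matrix(stats::runif(length(x)) < l$missing_rate, n)] <- NA
        vals <- x
      } else {
        cats <- if (l$type == "snp") c("A", "T", "C", "G") else CNV_STATES
        alpha <- if (l$type == "snp") rep(5, 4) else rep(2, 5)
        eps <- min(0.15 * l$effect_size, 0.4)
        if (l$n_planted > 0 && eps <= 0)
          stop("infeasible frequency shift: effect size must be positive",
               call. = FALSE)
        vals <- matrix("", n, l$n_features)
        for (j in seq_len(l$n_features)) {
          p <- rdirichlet1(alpha)
          if (j %in% pl && spec$task == "categorical") {
            # shift the rarest category up: always feasible for eps <= 0.4
            a <- which.min(p)
            q <- shift_freq(p, a, eps)
            vals[!is_pos, j] <- sample(cats, sum(!is_pos), TRUE, prob = p)
            vals[is_pos, j] <- sample(cats, sum(is_pos), TRUE, prob = q)
          } else {
            vals[, j] <- sample(cats, n, TRUE, prob = p)
          }
        }
        if (l$type == "snp" && l$missing_rate > 0)
          vals[matrix(stats::runif(length(vals)) < l$missing_rate, n)] <-
            "missing"
      }
      m <- omics_matrix(vals, l$type, sample_ids, fids,
                        source_tag = "synthetic")
      matrices[[l$type]] <- m
      planted[[l$type]] <- fids[pl]
    }

    manifest <- list(planted = planted,
                     spec = list(n_samples = n,
                                 class_balance = spec$class_balance,
                                 task = spec$task, seed = spec$seed,
                                 layers = spec$layers))
    files <- NULL
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      files <- character()
      for (nm in names(matrices)) {
        f <- file.path(dir, paste0(nm, ".csv"))
        write_omics_csv(matrices[[nm]], f)
        files <- c(files, f)
      }
      lf <- file.path(dir, "labels.csv")
      utils::write.csv(data.frame(sample_id = labels$sample_ids,
                                  label = labels$values),
                       lf, row.names = FALSE, quote = FALSE)
      mf <- file.path(dir, "manifest.json")
      jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      files <- c(files, lf, mf)
    }
    list(matrices = matrices, labels = labels, manifest = manifest,
         files = files)
  })
}

#' Generate, encode and align a synthetic dataset in one call
#'
#' @param spec A [synthetic_spec()].
#' @return List with `dataset` (an encoded, aligned `multi_omics_dataset`)
#'   and `manifest` (ground truth).
#' @export
make_synthetic_dataset <- function(spec) {
  gen <- generate_synthetic(spec)
  layers <- lapply(gen$matrices, encode_layer)
  list(dataset = align_samples(layers, gen$labels), manifest = gen$manifest)
}

#' Check marker recovery against a ground-truth manifest
#'
#' Precision at k: the fraction of the top-k report features (strictly k rows,
#' ties broken by feature ID) that are planted. Recall at k: the fraction of
#' planted features found in that top k.
#'
#' @param report A `marker_report`.
#' @param manifest The `manifest` element of [generate_synthetic()] output
#'   (or any list with a `planted` field).
#' @param k Cutoff (>= 1).
#' @return A tibble: `k, n_planted, hits, precision_at_k, recall_at_k`.
#' @export
manifest_check <- function(report, manifest, k = 10) {
  stopifnot(inherits(report, "marker_report"))
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  planted <- unique(unlist(manifest$planted, use.names = FALSE))
  if (!length(intersect(planted, report$feature)))
    stop("report and manifest share no feature IDs (disjoint namespaces)",
         call. = FALSE)
  ord <- order(report$dense_rank, report$feature)
  top <- utils::head(report$feature[ord], k)
  hits <- sum(top %in% planted)
  tibble::tibble(k = as.integer(k), n_planted = length(planted),
                 hits = as.integer(hits),
                 precision_at_k = hits / length(top),
                 recall_at_k = hits / length(planted))
}
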