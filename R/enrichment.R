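# Over-representation analysis of marker genes against gene-set collections:
# one-sided hypergeometric tail per set, Benjamini-Hochberg adjustment across
# sets. This is the operation determined by an unranked significant-marker
# list (a ranked-input, running-sum GSEA variant is out of scope).

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the query list overlaps it more than
#' expected by chance when drawing `|query|` genes from the universe:
#' the upper tail `P(X >= overlap)` with
#' `X ~ Hypergeometric(N = |universe|, K = |set & universe|, n = |query|)`.
#' P-values are Benjamini-Hochberg adjusted across the tested sets. Query
#' genes outside the universe are dropped with a warning; sets with no member
#' in the universe are skipped with a warning.
#'
#' @param query Character vector of significant gene IDs.
#' @param sets A `gene_set_collection` from [read_gmt()].
#' @param universe Character vector of all candidate gene IDs (e.g. every
#'   model feature mapped to a gene).
#' @return An `enrichment_result` tibble sorted by ascending p-value:
#'   `set, overlap, set_size, query_size, universe_size, p_value, p_adjust,
#'   genes` (overlapping IDs, comma-separated).
#' @export
over_representation <- function(query, sets, universe) {
  stopifnot(inherits(sets, "gene_set_collection"))
  if (!length(sets)) stop("empty gene-set collection", call. = FALSE)
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped: ",
            toString(utils::head(outside, 5)), call. = FALSE)
    query <- intersect(query, universe)
  }
  if (!length(query))
    stop("no query gene left after restricting to the universe", call. = FALSE)
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]]$genes, universe)
    K <- length(members)
    if (K == 0) {
      warning("set '", nm, "' has no member in the universe; skipped",
              call. = FALSE)
      return(NULL)
    }
    hits <- intersect(query, members)
    ov <- length(hits)
    p <- stats::phyper(ov - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(set = nm, overlap = ov, set_size = K, query_size = n,
                   universe_size = N, p_value = p,
                   genes = paste(sort(hits), collapse = ","))
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out))
    stop("no testable gene set after universe filtering", call. = FALSE)
  out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  out <- dplyr::arrange(out, .data$p_value, .data$set)
  out <- out[c("set", "overlap", "set_size", "query_size", "universe_size",
               "p_value", "p_adjust", "genes")]
  structure(out, class = c("enrichment_result", class(out)))
}

#' Top enriched pathways
#'
#' The first `n` rows by ascending p-value, optionally keeping only rows with
#' adjusted p at or below `alpha` (an empty result is legal, not an error).
#'
#' @param result An `enrichment_result`.
#' @param n Number of rows (>= 1).
#' @param alpha Optional adjusted-p cutoff.
#' @return Subset of `result`.
#' @export
top_pathways <- function(result, n = 10, alpha = NULL) {
  stopifnot(inherits(result, "enrichment_result"), n >= 1)
  out <- result
  if (!is.null(alpha)) out <- out[out$p_adjust <= alpha, ]
  utils::head(out, n)
}
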