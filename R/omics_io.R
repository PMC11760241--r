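# Omics layer IO: CSV layers, label tables, GMT gene sets, marker annotations.

OMICS_TYPES <- c("gene_expression", "mirna_expression", "dna_methylation",
                 "protein_expression", "snp", "cnv")
EXPRESSION_TYPES <- c("gene_expression", "mirna_expression", "dna_methylation",
                      "protein_expression")
SNP_TOKENS <- c("A", "T", "C", "G", "missing")
CNV_STATES <- c("homozygous_deletion", "single_copy_deletion",
                "diploid_normal", "low_level_amplification",
                "high_level_amplification")
CNV_ALIASES <- c("-2" = "homozygous_deletion", "-1" = "single_copy_deletion",
                 "0" = "diploid_normal", "1" = "low_level_amplification",
                 "2" = "high_level_amplification")

is_expression_type <- function(omics_type) omics_type %in% EXPRESSION_TYPES

#' Construct an omics matrix
#'
#' An `omics_matrix` holds one omics layer as a samples-by-features grid with
#' an omics type tag. Expression-like layers (gene/miRNA/protein expression,
#' DNA methylation) store numeric values with `NA` for missing entries; SNP
#' layers store genotype tokens `A/T/C/G/missing`; CNV layers store one of the
#' five copy-number states (`r toString(CNV_STATES)`), with numeric aliases
#' `-2,-1,0,1,2` accepted and normalised on construction.
#'
#' @param values Matrix (samples in rows, features in columns). Numeric for
#'   expression-like types, character tokens for `snp`/`cnv`.
#' @param omics_type One of `r toString(OMICS_TYPES)`.
#' @param sample_ids,feature_ids Unique ID vectors; default to dimnames.
#' @param source_tag Free-text provenance tag.
#' @return An `omics_matrix` object.
#' @export
omics_matrix <- function(values, omics_type,
                         sample_ids = rownames(values),
                         feature_ids = colnames(values),
                         source_tag = "") {
  omics_type <- match.arg(omics_type, OMICS_TYPES)
  if (!is.matrix(values)) values <- as.matrix(values)
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(values) || length(feature_ids) != ncol(values))
    stop("ID lengths do not match matrix dimensions", call. = FALSE)
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup))
    stop("duplicate sample ID(s): ", toString(unique(dup)), call. = FALSE)
  dup <- feature_ids[duplicated(feature_ids)]
  if (length(dup))
    stop("duplicate feature ID(s): ", toString(unique(dup)), call. = FALSE)

  if (is_expression_type(omics_type)) {
    if (!is.numeric(values))
      stop("expression-like layer '", omics_type, "' must be numeric",
           call. = FALSE)
  } else {
    values[] <- normalize_tokens(as.character(values), omics_type)
  }
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(
    list(omics_type = omics_type, sample_ids = sample_ids,
         feature_ids = feature_ids, values = values, source_tag = source_tag),
    class = "omics_matrix")
}

# Canonicalise SNP/CNV tokens; stops on anything outside the vocabulary.
normalize_tokens <- function(x, omics_type) {
  x <- trimws(x)
  if (omics_type == "snp") {
    x[x %in% c("-", "", "NA", "na", "Na")] <- "missing"
    x <- toupper_keep_missing(x)
    bad <- setdiff(unique(x), SNP_TOKENS)
    if (length(bad))
      stop("unknown SNP token(s) ", toString(sQuote(bad)),
           "; allowed: A, T, C, G, missing (or '-')", call. = FALSE)
  } else {
    hit <- x %in% names(CNV_ALIASES)
    x[hit] <- CNV_ALIASES[x[hit]]
    x <- gsub("[ -]", "_", tolower(x))
    x[x == "diploid_normal_copy"] <- "diploid_normal"
    x[x == "low_level_copy_number_amplification"] <- "low_level_amplification"
    x[x == "high_level_copy_number_amplification"] <- "high_level_amplification"
    bad <- setdiff(unique(x), CNV_STATES)
    if (length(bad))
      stop("unknown CNV state(s) ", toString(sQuote(bad)),
           "; allowed: ", toString(CNV_STATES), " or aliases -2..2",
           call. = FALSE)
  }
  x
}

toupper_keep_missing <- function(x) {
  m <- tolower(x) == "missing"
  x <- toupper(x)
  x[m] <- "missing"
  x
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix: %s, %d samples x %d features>\n",
              x$omics_type, length(x$sample_ids), length(x$feature_ids)))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Read one omics layer from CSV
#'
#' The first column holds sample IDs and the header row holds feature IDs
#' (samples in rows, features in columns; use `transpose = TRUE` for the other
#' orientation). Missing expression values may be empty cells or `NA`
#' (case-insensitive); missing genotypes are spelled `missing` or `-`.
#' Sample-ID matching downstream is exact string equality.
#'
#' @param path CSV file path.
#' @param omics_type One of `r toString(OMICS_TYPES)`.
#' @param transpose If `TRUE` the file stores features in rows.
#' @param source_tag Optional provenance tag.
#' @return An [omics_matrix()].
#' @export
read_omics_csv <- function(path, omics_type, transpose = FALSE,
                           source_tag = "") {
  omics_type <- match.arg(omics_type, OMICS_TYPES)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("need a sample-ID column plus >= 1 feature column",
                         call. = FALSE)
  ids <- df[[1]]
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- ids
  if (transpose) mat <- t(mat)
  if (is_expression_type(omics_type)) {
    # read.csv already maps the literal string NA to <NA>; empty cells and any
    # case variant of "na" count as missing too
    miss <- is.na(mat) | trimws(mat) %in% c("", "NA", "na", "Na", "nA")
    num <- suppressWarnings(array(as.numeric(ifelse(miss, NA_character_, mat)),
                                  dim = dim(mat), dimnames = dimnames(mat)))
    bad <- which(is.na(num) & !miss, arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf(
        "non-numeric entry '%s' at sample '%s', feature '%s' in %s",
        mat[bad[1, 1], bad[1, 2]], rownames(mat)[bad[1, 1]],
        colnames(mat)[bad[1, 2]], path), call. = FALSE)
    mat <- num
  }
  omics_matrix(mat, omics_type, source_tag = source_tag)
}

#' Write an omics layer to CSV
#'
#' Inverse of [read_omics_csv()]: round-tripping reproduces IDs and values
#' exactly (missing entries written as empty cells for expression-like layers).
#'
#' @param m An [omics_matrix()].
#' @param path Output CSV path.
#' @param id_column Name for the sample-ID column.
#' @return `path`, invisibly.
#' @export
write_omics_csv <- function(m, path, id_column = "sample_id") {
  stopifnot(inherits(m, "omics_matrix"))
  vals <- m$values
  if (is_expression_type(m$omics_type)) {
    ch <- array(format_full(vals), dim = dim(vals))
    ch[is.na(vals)] <- ""
  } else ch <- vals
  df <- data.frame(m$sample_ids, ch, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(id_column, m$feature_ids)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# full-precision decimal text so CSV round trips are exact
format_full <- function(x) {
  out <- vapply(as.vector(x), function(v)
    if (is.na(v)) NA_character_ else format(v, digits = 17, scientific = TRUE,
                                            trim = TRUE), character(1))
  out
}

#' Read a phenotype label table
#'
#' Expects two columns: sample ID, label. Categorical labels are kept as
#' strings; quantitative labels are parsed as reals.
#'
#' @param path CSV file path.
#' @param task `"categorical"` or `"quantitative"`.
#' @return A `label_table` with fields `sample_ids`, `task`, `values`.
#' @export
read_labels <- function(path, task = c("categorical", "quantitative")) {
  task <- match.arg(task)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(utils::read.csv(path, check.names = FALSE,
                                 colClasses = "character"),
                 error = function(e) stop("empty or unreadable label file: ",
                                          path, call. = FALSE))
  if (nrow(df) == 0) stop("label file has no rows: ", path, call. = FALSE)
  if (ncol(df) < 2) stop("label file needs sample-ID and label columns",
                         call. = FALSE)
  label_table(sample_ids = df[[1]], values = df[[2]], task = task)
}

#' Construct a label table
#'
#' @param sample_ids Unique sample IDs.
#' @param values Class labels (categorical) or numbers (quantitative).
#' @param task `"categorical"` or `"quantitative"`.
#' @return A `label_table` object.
#' @export
label_table <- function(sample_ids, values,
                        task = c("categorical", "quantitative")) {
  task <- match.arg(task)
  sample_ids <- as.character(sample_ids)
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup))
    stop("duplicate sample ID(s) in labels: ", toString(unique(dup)),
         call. = FALSE)
  if (length(values) != length(sample_ids))
    stop("labels and sample IDs differ in length", call. = FALSE)
  miss <- is.na(values) | (is.character(values) & trimws(values) == "")
  if (any(miss))
    stop("missing label for sample(s): ",
         toString(sample_ids[miss][seq_len(min(5, sum(miss)))]), call. = FALSE)
  if (task == "quantitative") {
    num <- suppressWarnings(as.numeric(values))
    if (anyNA(num))
      stop("non-numeric quantitative label '", values[which(is.na(num))[1]],
           "' for sample '", sample_ids[which(is.na(num))[1]], "'",
           call. = FALSE)
    values <- num
  } else {
    values <- as.character(values)
    if (length(unique(values)) < 2)
      stop("categorical task needs >= 2 distinct labels", call. = FALSE)
  }
  structure(list(sample_ids = sample_ids, task = task, values = values),
            class = "label_table")
}

#' @export
print.label_table <- function(x, ...) {
  cat(sprintf("<label_table: %s, %d samples>\n", x$task, length(x$sample_ids)))
  invisible(x)
}

#' Read a GMT gene-set collection
#'
#' Tab-separated lines: set name, description, member gene IDs. Repeated
#' members within a set are deduplicated.
#'
#' @param path GMT file path.
#' @return A `gene_set_collection`: named list of `list(description, genes)`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path, call. = FALSE)
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    if (length(parts) < 3)
      stop("GMT line ", i, " has fewer than 3 fields", call. = FALSE)
    name <- parts[1]
    if (name %in% names(sets))
      stop("duplicate gene-set name '", name, "' at line ", i, call. = FALSE)
    sets[[name]] <- list(description = parts[2],
                         genes = unique(parts[-(1:2)]))
  }
  structure(sets, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection: %d sets, sizes %s>\n", length(x),
              paste(range(vapply(x, function(s) length(s$genes), 1L)),
                    collapse = "-")))
  invisible(x)
}

#' Read a marker-to-gene annotation table
#'
#' BED-like 5-column TSV: marker ID, chromosome, start, end, linked gene.
#' Coordinates are 0-based half-open (`start < end`). An empty file yields an
#' empty annotation; markers absent from it are simply reported unmapped
#' later.
#'
#' @param path TSV file path.
#' @return A `marker_annotation` tibble with columns
#'   `marker, chrom, start, end, gene`.
#' @export
read_marker_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(marker_annotation())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 5))
    stop("annotation line ", which(nf < 5)[1], " has fewer than 5 fields",
         call. = FALSE)
  df <- tibble::tibble(
    marker = vapply(parts, `[`, "", 1), chrom = vapply(parts, `[`, "", 2),
    start = as.numeric(vapply(parts, `[`, "", 3)),
    end = as.numeric(vapply(parts, `[`, "", 4)),
    gene = vapply(parts, `[`, "", 5))
  marker_annotation(df)
}

#' Construct a marker annotation
#'
#' @param records Data frame with columns `marker, chrom, start, end, gene`
#'   (0-based half-open coordinates). Defaults to an empty annotation.
#' @return A `marker_annotation` tibble.
#' @export
marker_annotation <- function(records = NULL) {
  if (is.null(records))
    records <- tibble::tibble(marker = character(), chrom = character(),
                              start = numeric(), end = numeric(),
                              gene = character())
  records <- tibble::as_tibble(records)
  need <- c("marker", "chrom", "start", "end", "gene")
  if (!all(need %in% names(records)))
    stop("annotation needs columns: ", toString(need), call. = FALSE)
  records <- records[need]
  if (anyNA(records$start) || anyNA(records$end))
    stop("non-numeric coordinate in annotation", call. = FALSE)
  bad <- records$start >= records$end
  if (any(bad))
    stop("start >= end for marker(s): ",
         toString(records$marker[bad][seq_len(min(5, sum(bad)))]),
         call. = FALSE)
  dup <- records$marker[duplicated(records$marker)]
  if (length(dup))
    stop("duplicate marker ID(s): ", toString(unique(dup)), call. = FALSE)
  class(records) <- c("marker_annotation", class(records))
  records
}
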