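#' Construct a two-gene expression matrix with cohort labels
#'
#' The canonical input container of the package: `n` samples by two genes
#' (typically a writer/eraser pair such as OGT/OGA), each sample carrying a
#' cohort label in `{"healthy", "cancer", "unknown"}`.
#'
#' @param values Numeric matrix (or coercible data frame) with `n` rows and 2
#'   columns of expression values, in whatever normalized unit the study uses.
#' @param gene_names Character vector of length 2 with distinct gene names;
#'   defaults to the column names of `values`.
#' @param sample_ids Character vector of `n` unique sample identifiers;
#'   defaults to `"sample_1" ... "sample_n"`.
#' @param cohort Character vector of `n` cohort labels. Labels are normalized
#'   case-insensitively: `"healthy"`/`"normal"` map to `"healthy"`,
#'   `"cancer"`/`"tumor"`/`"tumour"` to `"cancer"`, anything else to
#'   `"unknown"`. Defaults to all `"unknown"`.
#' @return An object of class `gene_pair_matrix`: a list with elements
#'   `values`, `gene_names`, `sample_ids`, `cohort`.
#' @examples
#' x <- gene_pair_matrix(cbind(OGT = rnorm(5, 10), OGA = rnorm(5, 10)),
#'                       cohort = rep("healthy", 5))
#' x
#' @export
gene_pair_matrix <- function(values, gene_names = NULL, sample_ids = NULL,
                             cohort = NULL) {
  values <- as.matrix(values)
  if (ncol(values) != 2L)
    stop("'values' must have exactly 2 columns (one per gene)")
  if (nrow(values) < 1L)
    stop("'values' must have at least one row")
  storage.mode(values) <- "double"
  if (!all(is.finite(values)))
    stop("'values' must be finite; filter missing rows before construction")
  if (is.null(gene_names)) gene_names <- colnames(values)
  if (is.null(gene_names)) gene_names <- c("gene1", "gene2")
  gene_names <- as.character(gene_names)
  if (length(gene_names) != 2L || gene_names[1] == gene_names[2])
    stop("'gene_names' must be two distinct names")
  if (is.null(sample_ids))
    sample_ids <- paste0("sample_", seq_len(nrow(values)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(values))
    stop("length of 'sample_ids' must equal the number of rows")
  if (anyDuplicated(sample_ids))
    stop("'sample_ids' must be unique")
  if (is.null(cohort)) cohort <- rep("unknown", nrow(values))
  cohort <- normalize_cohort(cohort)
  if (length(cohort) != nrow(values))
    stop("length of 'cohort' must equal the number of rows")
  colnames(values) <- gene_names
  rownames(values) <- NULL
  structure(
    list(values = values, gene_names = gene_names,
         sample_ids = sample_ids, cohort = cohort),
    class = "gene_pair_matrix"
  )
}

normalize_cohort <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[x %in% c("healthy", "normal")] <- "healthy"
  x[x %in% c("cancer", "tumor", "tumour")] <- "cancer"
  x[!x %in% c("healthy", "cancer")] <- "unknown"
  x
}

#' @export
print.gene_pair_matrix <- function(x, ...) {
  tab <- table(factor(x$cohort, levels = c("healthy", "cancer", "unknown")))
  cat(sprintf("gene_pair_matrix: %d samples x 2 genes (%s, %s)\n",
              nrow(x$values), x$gene_names[1], x$gene_names[2]))
  cat(sprintf("cohorts: healthy=%d cancer=%d unknown=%d\n",
              tab[["healthy"]], tab[["cancer"]], tab[["unknown"]]))
  dropped <- attr(x, "dropped_rows")
  if (!is.null(dropped) && dropped > 0)
    cat(sprintf("(%d rows dropped at read time)\n", dropped))
  invisible(x)
}

#' @export
`[.gene_pair_matrix` <- function(x, i, ...) {
  out <- gene_pair_matrix(x$values[i, , drop = FALSE],
                          gene_names = x$gene_names,
                          sample_ids = x$sample_ids[i],
                          cohort = x$cohort[i])
  out
}

#' Number of samples in a gene_pair_matrix
#' @param x A `gene_pair_matrix`.
#' @return Integer sample count.
#' @export
n_samples <- function(x) {
  stopifnot(inherits(x, "gene_pair_matrix"))
  nrow(x$values)
}

#' Subset a gene_pair_matrix by cohort label
#' @param x A `gene_pair_matrix`.
#' @param label One of `"healthy"`, `"cancer"`, `"unknown"`.
#' @return A `gene_pair_matrix` with only the matching samples.
#' @export
cohort_subset <- function(x, label) {
  label <- match.arg(label, c("healthy", "cancer", "unknown"))
  idx <- which(x$cohort == label)
  if (length(idx) == 0L)
    stop(sprintf("no samples labeled '%s'", label))
  x[idx]
}

detect_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a two-gene expression table
#'
#' Reads a delimited text table (TSV or CSV, auto-detected from the file
#' extension) with a header row, extracts two gene columns plus a cohort
#' label column, drops rows with missing or non-finite expression in either
#' gene, and reports how many rows were dropped.
#'
#' @param path Path to a delimited text file with a header row.
#' @param gene1,gene2 Column names of the two genes.
#' @param cohort_column Column name holding cohort labels; labels are
#'   normalized case-insensitively to `{"healthy", "cancer", "unknown"}`.
#'   `NULL` labels every sample `"unknown"`.
#' @param id_column Optional column of sample identifiers; row numbers are
#'   used when absent.
#' @param delim Field delimiter; `NULL` (default) auto-detects from the
#'   extension (`.csv` comma, otherwise tab).
#' @param log2p1 If `TRUE`, apply `log2(x + 1)` to both gene columns at read
#'   time. Off by default: the scorer is unit-agnostic and consumes
#'   expression values as-is.
#' @return A [gene_pair_matrix] with attribute `dropped_rows` giving the
#'   number of rows removed by the missing-value filter.
#' @export
read_expression_table <- function(path, gene1, gene2, cohort_column = NULL,
                                  id_column = NULL, delim = NULL,
                                  log2p1 = FALSE) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path))
  delim <- detect_delim(path, delim)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""), quote = "\"")
  for (col in c(gene1, gene2, cohort_column, id_column)) {
    if (!col %in% names(df))
      stop(sprintf("column '%s' not found in %s", col, path))
  }
  if (gene1 == gene2) stop("gene1 and gene2 must name distinct columns")
  v1 <- suppressWarnings(as.numeric(df[[gene1]]))
  v2 <- suppressWarnings(as.numeric(df[[gene2]]))
  keep <- is.finite(v1) & is.finite(v2)
  dropped <- sum(!keep)
  if (sum(keep) == 0L)
    stop("no usable rows after removing missing/non-finite expression values")
  ids <- if (is.null(id_column)) paste0("row_", which(keep))
         else as.character(df[[id_column]][keep])
  cohort <- if (is.null(cohort_column)) rep("unknown", sum(keep))
            else df[[cohort_column]][keep]
  vals <- cbind(v1[keep], v2[keep])
  if (log2p1) vals <- log2(vals + 1)
  out <- gene_pair_matrix(vals, gene_names = c(gene1, gene2),
                          sample_ids = ids, cohort = cohort)
  attr(out, "dropped_rows") <- dropped
  out
}

#' Write per-sample regulation scores alongside expression
#'
#' Writes a delimited table with columns `sample_id`, the two gene columns,
#' `cohort`, and `regulation_score`, suitable for re-reading with
#' [read_expression_table()].
#'
#' @param path Output path; delimiter auto-detected from the extension
#'   unless `delim` is given.
#' @param x A [gene_pair_matrix].
#' @param scores Numeric vector of regulation scores in `[0, 1]`, one per
#'   sample (e.g. from [predict.kdereg()]).
#' @param delim Field delimiter override.
#' @return Invisibly, the path written.
#' @export
write_scores_table <- function(path, x, scores, delim = NULL) {
  stopifnot(inherits(x, "gene_pair_matrix"))
  scores <- as.numeric(scores)
  if (n_samples(x) == 0L || length(scores) == 0L)
    stop("cannot write an empty scores table")
  if (length(scores) != n_samples(x))
    stop(sprintf("score count (%d) does not match sample count (%d)",
                 length(scores), n_samples(x)))
  if (any(!is.finite(scores)) || any(scores < 0 | scores > 1))
    stop("scores must be finite and within [0, 1]")
  delim <- detect_delim(path, delim)
  df <- data.frame(sample_id = x$sample_ids,
                   g1 = x$values[, 1], g2 = x$values[, 2],
                   cohort = x$cohort, regulation_score = scores,
                   stringsAsFactors = FALSE)
  names(df)[2:3] <- x$gene_names
  utils::write.table(df, path, sep = delim, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
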