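#' Samples-by-taxa abundance table
#'
#' A light container for a samples x taxa matrix of counts or relative
#' abundances, an optional taxonomy label map (ASV id -> genus-level label),
#' and a flag recording whether rows have been closed to relative abundance.
#'
#' @param mat numeric matrix, samples as rows; rownames are sample ids and
#'   colnames are taxon (ASV) ids. Entries must be nonnegative.
#' @param taxonomy optional named character vector mapping taxon ids to
#'   genus-level labels; unnamed taxa keep their ids as labels.
#' @param is_relative logical; `TRUE` once every row sums to 1.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(mat, taxonomy = NULL, is_relative = FALSE) {
  mat <- as.matrix(mat)
  if (!is.numeric(mat)) stopf("abundance matrix must be numeric")
  if (any(mat < 0)) stopf("abundance matrix has negative entries")
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("S%04d", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("ASV%04d", seq_len(ncol(mat)))
  if (anyDuplicated(colnames(mat))) stopf("taxon ids must be unique")
  if (anyDuplicated(rownames(mat))) stopf("sample ids must be unique")
  if (isTRUE(is_relative)) {
    rs <- rowSums(mat)
    if (any(abs(rs - 1) > 1e-9)) {
      stopf("is_relative = TRUE but row sums deviate from 1 (max |sum - 1| = %.3g)",
            max(abs(rs - 1)))
    }
  }
  tax <- setNames(colnames(mat), colnames(mat))
  if (!is.null(taxonomy)) {
    hit <- intersect(names(taxonomy), colnames(mat))
    tax[hit] <- taxonomy[hit]
  }
  structure(list(abund = mat, taxonomy = tax, is_relative = isTRUE(is_relative)),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d taxa (%s)\n",
              nrow(x$abund), ncol(x$abund),
              if (x$is_relative) "relative" else "raw"))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$abund)

#' Sample and taxon identifiers of an abundance table
#' @param table an [abundance_table].
#' @return character vector of ids.
#' @export
sample_ids <- function(table) rownames(table$abund)

#' @rdname sample_ids
#' @export
taxon_ids <- function(table) colnames(table$abund)

#' Read / write abundance tables as TSV
#'
#' TSV layout: header row, sample id in the first column, one column per
#' taxon. An optional two-column taxonomy TSV (`taxon_id`, `label`) supplies
#' genus-level labels.
#'
#' @param path TSV file path.
#' @param taxonomy_path optional taxonomy map TSV.
#' @param is_relative whether the stored values are already row-closed.
#' @return `read_abundance_tsv()` returns an [abundance_table];
#'   `write_abundance_tsv()` returns `path` invisibly.
#' @export
read_abundance_tsv <- function(path, taxonomy_path = NULL, is_relative = FALSE) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- as.character(df[[1]])
  taxonomy <- NULL
  if (!is.null(taxonomy_path)) {
    tx <- read.delim(taxonomy_path, stringsAsFactors = FALSE)
    taxonomy <- setNames(as.character(tx[[2]]), as.character(tx[[1]]))
  }
  abundance_table(mat, taxonomy = taxonomy, is_relative = is_relative)
}

#' @rdname read_abundance_tsv
#' @param table an [abundance_table].
#' @export
write_abundance_tsv <- function(table, path) {
  df <- data.frame(sample_id = sample_ids(table), table$abund,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_abundance_tsv
#' @export
write_taxonomy_tsv <- function(table, path) {
  df <- data.frame(taxon_id = names(table$taxonomy), label = unname(table$taxonomy),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write cohort tables as TSV
#'
#' Sample id first column; outcome, modifier and covariate columns follow.
#' Missing covariate cells are stored as `NA`.
#'
#' @param path TSV file path.
#' @return `read_cohort_tsv()` returns a data.frame keyed by `sample_id`.
#' @export
read_cohort_tsv <- function(path) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname read_cohort_tsv
#' @param cohort cohort data.frame.
#' @export
write_cohort_tsv <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
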