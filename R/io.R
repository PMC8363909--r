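# TSV I/O for matrices, group labels and annotation tables. Plain
# tab-delimited text with a header row; matrices keep feature ids in the
# first column.

#' Write a numeric matrix as TSV (feature column + sample columns)
#' @param mat matrix with row and column names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(feature = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#' @param path TSV path.
#' @return numeric matrix with feature row names.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write sample-to-group labels as a two-column TSV
#' @param groups named character vector, sample -> group.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_groups_tsv <- function(groups, path) {
  utils::write.table(data.frame(sample = names(groups), group = unname(groups)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample-to-group labels from TSV
#' @param path TSV with `sample` and `group` columns.
#' @return named character vector.
#' @export
read_groups_tsv <- function(path) {
  df <- utils::read.delim(path)
  stats::setNames(as.character(df$group), df$sample)
}
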