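# Plain-text I/O: TSV tables with header, headerless delimited square
# matrices, and two-column node-to-network partition files.

#' Write / read a square matrix as headerless tab-delimited text
#'
#' @param mat Numeric matrix.
#' @param path Output file.
#' @export
write_matrix_tsv <- function(mat, path) {
  write.table(as.matrix(mat), path, sep = "\t", row.names = FALSE,
              col.names = FALSE)
}

#' @rdname write_matrix_tsv
#' @return `read_matrix_tsv` returns the matrix.
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(read.table(path, sep = "\t", header = FALSE))
}

#' Write / read a node-to-network partition as two-column TSV
#'
#' Columns `node_id` (1-based) and `network`; the header row carries the
#' canonical label order via the factor levels.
#'
#' @param partition Factor of network labels.
#' @param path File path.
#' @export
write_partition_tsv <- function(partition, path) {
  df <- data.frame(node_id = seq_along(partition),
                   network = as.character(partition))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' @rdname write_partition_tsv
#' @param levels Optional canonical level order; defaults to order of first
#'   appearance.
#' @return `read_partition_tsv` returns the partition factor.
#' @export
read_partition_tsv <- function(path, levels = NULL) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  df <- df[order(df$node_id), ]
  factor(df$network, levels = levels %||% unique(df$network))
}

#' Write a cluster-label table
#'
#' @param subject_ids Character vector of subject ids.
#' @param labels Integer cluster labels.
#' @param path File path.
#' @export
write_labels_tsv <- function(subject_ids, labels, path) {
  write.table(data.frame(subject_id = subject_ids, cluster = labels),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
}
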