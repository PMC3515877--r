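# Expression matrices: TSV with a header row of sample ids and gene ids in
# the first column.  Represented in R as a numeric matrix with dimnames
# (genes x samples).

#' Read an expression matrix
#'
#' Rows with any missing or non-numeric entry are rejected with an error
#' naming the gene; at least two samples are required (correlation is
#' undefined otherwise); duplicate gene ids are rejected.
#'
#' @param path TSV file: header row of sample ids, first column gene ids.
#' @return Numeric matrix, rownames = gene ids, colnames = sample ids.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(gzfile(path), sep = "\t", header = TRUE,
                          check.names = FALSE, quote = "")
  if (ncol(df) < 3) stop("expression matrix needs >= 2 samples")
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) {
    stop("duplicate gene id: ", genes[duplicated(genes)][1])
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  bad <- rowSums(is.na(m)) > 0
  if (any(bad)) stop("missing values for gene ", genes[bad][1])
  rownames(m) <- genes
  m
}

#' Write an expression matrix
#'
#' @param m Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
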