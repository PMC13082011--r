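# Plain-text readers and writers for the pipeline's interchange formats.
# All coordinate-bearing tables use 1-based closed intervals (the UniProt
# chain convention); headers carry the column names.

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write / read an EBS matrix as TSV
#'
#' Individuals in rows (first column `individual_id`), peptide ids as the
#' remaining column headers.
#'
#' @param ebs numeric matrix with dimnames.
#' @param path file path.
#' @return the path (write) or the matrix (read).
#' @export
write_ebs_matrix <- function(ebs, path) {
  df <- data.frame(individual_id = rownames(ebs), ebs, check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_ebs_matrix
#' @export
read_ebs_matrix <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write / read an expression matrix as TSV (genes in rows)
#' @param expr numeric matrix with dimnames.
#' @param path file path.
#' @export
write_expression_matrix <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write / read protein sequences as FASTA (wrapped at 60 columns)
#' @param sequences named character vector of amino-acid sequences.
#' @param path file path.
#' @export
write_fasta <- function(sequences, path) {
  aa <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
}

#' Write / read a one-id-per-line surface proteome list
#' @param ids character vector of protein ids.
#' @param path file path.
#' @export
write_surface_list <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}

#' @rdname write_surface_list
#' @export
read_surface_list <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  ids <- trimws(readLines(path))
  ids[nzchar(ids)]
}
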