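#' Read and write BED interval tables
#'
#' Plain BED (tab-separated, no header, 0-based half-open). Columns beyond the
#' first three are mapped to `name`, `score`, `strand` when present.
#'
#' @param path File path.
#' @return Tibble with `chrom`, `start`, `end` and any optional columns.
#' @export
read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       comment = "#")
  names(x) <- cols[seq_len(ncol(x))]
  as_tibble(x)
}

#' @rdname read_bed
#' @param x Tibble whose first three columns are `chrom`, `start`, `end`.
#' @export
write_bed <- function(x, path) {
  readr::write_tsv(x, path, col_names = FALSE)
  invisible(path)
}

#' Read a pre-scored candidate guide table
#'
#' Expects the columns `guide_id`, `chrom`, `cut_site`, `strand`,
#' `protospacer`, `efficacy`, `top5`, `top10` (TSV with header).
#'
#' @param path File path.
#' @return Guide tibble.
#' @export
read_guides <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write / read a pair-by-sample count table
#'
#' @param counts Wide count tibble.
#' @param path TSV path.
#' @return The tibble (read) or `path` invisibly (write).
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write a DNAStringSet as FASTQ with constant quality
#'
#' @param reads Named `DNAStringSet`.
#' @param path Output path (`.gz` supported).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
  Biostrings::writeXStringSet(reads, path, format = "fastq",
                              qualities = quals)
  invisible(path)
}

#' Write / read a sparse matrix in MatrixMarket triplet layout
#'
#' Writes `matrix.mtx`, `features.tsv` (row names) and `barcodes.tsv`
#' (column names) into `dir`, the common exchange layout for single-cell
#' matrices.
#'
#' @param mat Matrix (genes/features x cells).
#' @param dir Directory (created if needed).
#' @return `dir` (write) or the sparse matrix with dimnames (read).
#' @export
write_mtx <- function(mat, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- as_sparse(mat)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble(feature = rownames(m)),
                   file.path(dir, "features.tsv"), col_names = FALSE)
  readr::write_tsv(tibble(barcode = colnames(m)),
                   file.path(dir, "barcodes.tsv"), col_names = FALSE)
  invisible(dir)
}

#' @rdname write_mtx
#' @export
read_mtx <- function(dir) {
  m <- as_sparse(Matrix::readMM(file.path(dir, "matrix.mtx")))
  rownames(m) <- readr::read_tsv(file.path(dir, "features.tsv"),
                                 col_names = "feature",
                                 show_col_types = FALSE)$feature
  colnames(m) <- readr::read_tsv(file.path(dir, "barcodes.tsv"),
                                 col_names = "barcode",
                                 show_col_types = FALSE)$barcode
  m
}

#' Serialize / load simulation truth as YAML
#'
#' @param truth Truth tibble (see [simulate_truth()]).
#' @param path YAML path.
#' @return `path` (write) or the truth tibble (read).
#' @export
write_truth <- function(truth, path) {
  yaml::write_yaml(lapply(as.list(truth), unname), path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  as_tibble(yaml::read_yaml(path))
}
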