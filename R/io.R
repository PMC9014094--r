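#' Tab-separated input/output helpers
#'
#' Thin wrappers standardizing the on-disk formats: plain TSV with a
#' header for tables; sparse matrices as triplet TSV (`i`, `j`, `value`,
#' upper storage not assumed) with a companion `.index` file mapping row
#' numbers to animal ids.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname write_tsv
#' @param m a (sparse or dense) square matrix with animal-id dimnames.
#' @export
write_matrix_triplet <- function(m, path) {
  tm <- methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                "generalMatrix"), "TsparseMatrix")
  write_tsv(data.frame(i = tm@i + 1L, j = tm@j + 1L, value = tm@x), path)
  write_tsv(data.frame(row = seq_len(nrow(m)), animal = rownames(m)),
            paste0(path, ".index"))
  invisible(path)
}

#' @rdname write_tsv
#' @param sparse return a sparse (`TRUE`, default) or dense matrix.
#' @export
read_matrix_triplet <- function(path, sparse = TRUE) {
  tr <- read_tsv(path)
  idx <- read_tsv(paste0(path, ".index"))
  n <- nrow(idx)
  m <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$value,
                            dims = c(n, n),
                            dimnames = list(idx$animal, idx$animal))
  if (sparse) m else as.matrix(m)
}
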