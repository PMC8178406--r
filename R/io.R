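# Plain-text readers and writers for the pipeline's interchange formats:
# gene x sample TSV matrices (first column gene_id, header of sample ids),
# sample metadata TSV, MTX triplets for single-cell counts, GMT gene-set
# collections and one-id-per-line gene lists.

#' Write a genes x samples matrix as TSV
#'
#' First column `gene_id`, remaining columns one per sample.
#'
#' @param x Matrix with gene row names and sample column names.
#' @param path Output file.
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genes x samples TSV matrix
#'
#' @param path File written by [write_matrix_tsv()] (first column gene ids).
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read sample metadata TSV
#'
#' Columns `sample_id`, `donor_id`, `chamber`, `disease`, `sex`, `age` (plus
#' any extras).
#'
#' @param metadata Data.frame of per-sample descriptors.
#' @param path File path.
#' @export
write_metadata_tsv <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata_tsv
#' @export
read_metadata_tsv <- function(path) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write single-cell counts as an MTX triplet plus labels
#'
#' Writes `matrix.mtx`, `features.tsv` (gene ids), `barcodes.tsv` (cell ids)
#' and `labels.tsv` (`cell_id`, `cell_type`) into a directory.
#'
#' @param counts Genes x cells matrix (coerced to sparse).
#' @param labels Cell-type label per cell.
#' @param dir Output directory (created if needed).
#' @export
write_mtx_triplet <- function(counts, labels, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- methods::as(Matrix::Matrix(as.matrix(counts), sparse = TRUE),
                   "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  write.table(data.frame(cell_id = colnames(counts), cell_type = labels),
              file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' Read an MTX triplet written by [write_mtx_triplet()]
#'
#' @param dir Directory containing `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv` and optionally `labels.tsv`.
#' @return List with `counts` (sparse genes x cells) and `labels` (or `NULL`).
#' @export
read_mtx_triplet <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                   "CsparseMatrix")
  rownames(m) <- readLines(file.path(dir, "features.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  labels <- NULL
  lab_path <- file.path(dir, "labels.tsv")
  if (file.exists(lab_path)) {
    lab <- read.delim(lab_path, stringsAsFactors = FALSE)
    labels <- setNames(lab$cell_type, lab$cell_id)[colnames(m)]
  }
  list(counts = m, labels = labels)
}

#' Read a GMT gene-set collection
#'
#' Tab-separated lines: set name, description, then member gene ids.
#'
#' @param path GMT file.
#' @return Named list; each element has `name`, `description`, `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("malformed GMT line (need name, description, >= 1 gene)",
           call. = FALSE)
    list(name = f[1], description = f[2], genes = unique(f[-(1:2)]))
  })
  names(sets) <- vapply(sets, `[[`, "", "name")
  if (anyDuplicated(names(sets)))
    stop("duplicate set names in GMT", call. = FALSE)
  sets
}

#' Write a GMT gene-set collection
#'
#' @param collection Named list of character vectors, or of lists with
#'   `name`, `description`, `genes`.
#' @param path Output file.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(nm) {
    s <- collection[[nm]]
    if (is.list(s)) paste(c(s$name, s$description, s$genes), collapse = "\t")
    else paste(c(nm, "na", s), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a one-id-per-line gene list
#'
#' @param genes Character vector of gene ids.
#' @param path File path.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' @rdname write_gene_list
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}
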