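# internal argument checks shared across modules

.check_matrix <- function(x, what, allow_na = FALSE) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix", what), call. = FALSE)
  if (!allow_na && anyNA(x))
    stop(sprintf("'%s' contains missing values", what), call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(sprintf("'%s' must have gene row names and sample column names", what),
         call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop(sprintf("duplicate gene ids in '%s'", what), call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop(sprintf("duplicate sample ids in '%s'", what), call. = FALSE)
  invisible(x)
}

# gene lengths may come named or positionally aligned to the count rows
.align_lengths <- function(gene_lengths, counts) {
  if (!is.numeric(gene_lengths))
    stop("'gene_lengths' must be numeric", call. = FALSE)
  if (!is.null(names(gene_lengths))) {
    missing <- setdiff(rownames(counts), names(gene_lengths))
    if (length(missing))
      stop("missing gene lengths for: ", paste(head(missing, 5), collapse = ", "),
           call. = FALSE)
    gene_lengths <- gene_lengths[rownames(counts)]
  } else if (length(gene_lengths) != nrow(counts)) {
    stop("'gene_lengths' must align with the rows of the count matrix",
         call. = FALSE)
  }
  if (anyNA(gene_lengths) || any(gene_lengths <= 0))
    stop("'gene_lengths' must be positive and complete", call. = FALSE)
  unname(gene_lengths)
}

.check_scalar <- function(x, what, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", what), call. = FALSE)
  bad <- if (strict) x <= lower else x < lower
  if (bad)
    stop(sprintf("'%s' must be %s %s", what, if (strict) ">" else ">=", lower),
         call. = FALSE)
  invisible(x)
}

# geometric-mean-one rescaling used by size factors and depth factors
.geom_standardize <- function(x) x / exp(mean(log(x)))
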