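#' Convert raw counts to FPKM
#'
#' Fragments per kilobase of transcript per million mapped reads:
#' \eqn{FPKM_{gs} = counts_{gs} \cdot 10^9 / (length_g \cdot total_s)} where
#' \eqn{total_s} is the column sum of counts for sample \eqn{s}. Zero counts
#' map to zero FPKM regardless of gene length, and each sample's FPKM vector
#' is invariant to uniform rescaling of its counts (sequencing depth cancels).
#'
#' @param counts Numeric matrix of non-negative gene-level counts,
#'   genes x samples, with gene ids as row names and sample ids as column
#'   names.
#' @param gene_lengths Positive gene lengths in bases, either named by gene id
#'   or positionally aligned with the rows of `counts`.
#' @return Numeric matrix of FPKM values with the dimnames of `counts`.
#' @examples
#' counts <- matrix(c(1000, 0), 2, 1,
#'                  dimnames = list(c("g1", "g2"), "s1"))
#' counts_to_fpkm(counts, c(g1 = 1000, g2 = 500))
#' @export
counts_to_fpkm <- function(counts, gene_lengths) {
  .check_matrix(counts, "counts")
  if (any(counts < 0))
    stop("'counts' must be non-negative", call. = FALSE)
  gene_lengths <- .align_lengths(gene_lengths, counts)
  totals <- colSums(counts)
  if (any(totals <= 0))
    stop("sample(s) with zero total counts: ",
         paste(colnames(counts)[totals <= 0], collapse = ", "), call. = FALSE)
  fpkm <- counts * 1e9 / gene_lengths  # recycles gene lengths down columns
  sweep(fpkm, 2L, totals, "/")
}

#' Percentile-anchored normalization of an expression matrix
#'
#' Rescales every sample so that a fixed percentile of its *nonzero* values
#' equals a fixed constant; the default anchors the 70th percentile at 10, a
#' refinement of upper-quartile normalization. The percentile is computed by
#' linear interpolation between order statistics (the type-7 convention,
#' index \eqn{p(n-1)} on the sorted vector). The operation is idempotent and
#' scale-equivariant: multiplying a sample by any positive constant leaves
#' its normalized vector unchanged.
#'
#' @param expr Numeric matrix of non-negative expression values
#'   (genes x samples).
#' @param percentile Percentile (0-100) of the nonzero values to anchor.
#' @param anchor_value Value the anchor percentile is scaled to.
#' @return Matrix of the same shape with each column rescaled.
#' @export
anchor_normalize <- function(expr, percentile = 70, anchor_value = 10) {
  .check_matrix(expr, "expr")
  .check_scalar(percentile, "percentile", 0, strict = TRUE)
  if (percentile >= 100) stop("'percentile' must be in (0, 100)", call. = FALSE)
  .check_scalar(anchor_value, "anchor_value", 0, strict = TRUE)
  if (any(expr < 0)) stop("'expr' must be non-negative", call. = FALSE)
  q <- apply(expr, 2L, function(x) {
    nz <- x[x > 0]
    if (!length(nz)) NA_real_
    else quantile(nz, probs = percentile / 100, names = FALSE, type = 7)
  })
  if (anyNA(q))
    stop("sample(s) with all-zero expression: ",
         paste(colnames(expr)[is.na(q)], collapse = ", "), call. = FALSE)
  sweep(expr, 2L, anchor_value / q, "*")
}

#' Remove lowly expressed genes
#'
#' A gene is kept when it reaches `min_fpkm` in at least `min_samples`
#' samples of the supplied matrix; everything else is dropped. Applied
#' per pairwise comparison in the pipeline, i.e. on the columns entering a
#' contrast. Gene order is preserved.
#'
#' @param expr Normalized expression matrix (genes x samples).
#' @param min_fpkm Expression threshold a sample must reach to count.
#' @param min_samples Minimum number of samples at or above `min_fpkm`.
#' @return List with `expr` (the filtered matrix) and `kept` (integer row
#'   indices of the surviving genes in the input).
#' @export
expression_filter <- function(expr, min_fpkm = 1, min_samples = 5) {
  .check_matrix(expr, "expr")
  .check_scalar(min_fpkm, "min_fpkm", 0)
  .check_scalar(min_samples, "min_samples", 0)
  kept <- unname(which(rowSums(expr >= min_fpkm) >= min_samples))
  list(expr = expr[kept, , drop = FALSE], kept = kept)
}
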