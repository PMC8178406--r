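# Fisher's exact over-representation of annotation gene sets among genes of
# interest, with the sample odds ratio as enrichment score. The universe is
# always an explicit argument: over-representation p-values are meaningless
# without a stated background.

#' Fisher's exact over-representation of one gene set
#'
#' Tests whether `term_set` is over-represented among `genes_of_interest`
#' within `universe`. With overlap `a`, the one-sided p-value is the
#' hypergeometric upper tail \eqn{P(X \ge a)}; the two-sided p-value is the
#' standard Fisher rule (sum of table probabilities no larger than the
#' observed one). The enrichment score is the sample odds ratio
#' \eqn{(a d)/(b c)}, with the Haldane-Anscombe +0.5 applied to every cell
#' only when a zero cell would otherwise make it undefined.
#'
#' @param genes_of_interest,term_set Character vectors, subsets of
#'   `universe`.
#' @param universe Background gene ids (finite, non-empty).
#' @param alternative `"greater"` (default, over-representation) or
#'   `"two.sided"`.
#' @return List with `table` (2x2), `enrichment_score`, `p_value`,
#'   `overlap` (intersection gene ids) and `score_defined` (FALSE when the
#'   interest set is empty).
#' @export
fisher_enrichment <- function(genes_of_interest, term_set, universe,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  tab <- set_overlap_counts(genes_of_interest, term_set, universe)
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  N <- sum(tab)
  K <- a + c_   # term-set size in the universe
  n <- a + b    # interest-set size
  if (n == 0)
    return(list(table = tab, enrichment_score = NA_real_, p_value = 1,
                overlap = character(0), score_defined = FALSE))
  p <- if (alternative == "greater") {
    phyper(a - 1, K, N - K, n, lower.tail = FALSE)
  } else {
    support <- max(0, n + K - N):min(n, K)
    dens <- dhyper(support, K, N - K, n)
    sum(dens[dens <= dhyper(a, K, N - K, n) * (1 + 1e-7)])
  }
  score <- if (a == 0 || b == 0 || c_ == 0 || d == 0) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else {
    (a * d) / (b * c_)
  }
  list(table = tab, enrichment_score = score, p_value = min(p, 1),
       overlap = intersect(genes_of_interest, term_set),
       score_defined = TRUE)
}

#' Over-representation across a gene-set collection
#'
#' Runs [fisher_enrichment()] for every set in a GMT-style collection,
#' skipping sets with fewer than `min_set_size` members inside the universe,
#' BH-adjusting across the tested sets and sorting by adjusted p then
#' descending enrichment score.
#'
#' @param genes_of_interest Character vector, subset of `universe`.
#' @param collection Named list of gene sets (see [read_gmt()]), or a list
#'   with elements `name`, `description`, `genes` per set.
#' @param universe Background gene ids.
#' @param min_set_size Minimum members within the universe for a set to be
#'   tested.
#' @param alternative Passed to [fisher_enrichment()].
#' @return Data.frame with columns `term`, `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `pvalue`, `padj`, `overlap_genes`.
#' @export
enrich_collection <- function(genes_of_interest, collection, universe,
                              min_set_size = 5,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  sets <- lapply(collection, function(s) if (is.list(s)) s$genes else s)
  sets <- lapply(sets, function(g) intersect(unique(g), universe))
  keep <- vapply(sets, length, 0L) >= min_set_size
  sets <- sets[keep]
  rows <- lapply(names(sets), function(nm) {
    fe <- fisher_enrichment(genes_of_interest, sets[[nm]], universe,
                            alternative)
    data.frame(term = nm,
               a = fe$table[1, 1], b = fe$table[1, 2],
               c = fe$table[2, 1], d = fe$table[2, 2],
               odds_ratio = fe$enrichment_score, pvalue = fe$p_value,
               overlap_genes = paste(sort(fe$overlap), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(term = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0),
                      odds_ratio = numeric(0), pvalue = numeric(0),
                      padj = numeric(0), overlap_genes = character(0),
                      stringsAsFactors = FALSE))
  res$padj <- bh_adjust(res$pvalue)
  res <- res[order(res$padj, -res$odds_ratio), ]
  rownames(res) <- NULL
  res[, c("term", "a", "b", "c", "d", "odds_ratio", "pvalue", "padj",
          "overlap_genes")]
}
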