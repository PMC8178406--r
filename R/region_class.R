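# Assignment of chamber- and axis-enrichment classes from the six pairwise
# chamber contrasts, heart-enrichment calling from a multi-tissue panel, and
# the 2x2 overlap tables that feed over-representation tests.

# the eight enrichment classes as lists of required "winner beats loser"
# directed chamber pairs, in primary-label precedence order (chambers before
# axes, then the fixed order below)
.subregion_rules <- function() {
  rules <- list()
  for (C in c("LV", "RV", "LA", "RA"))
    rules[[C]] <- lapply(setdiff(CHAMBERS, C), function(x) c(C, x))
  rules$Ventricles <- list(c("LV", "LA"), c("RV", "LA"),
                           c("LV", "RA"), c("RV", "RA"))
  rules$Atria <- list(c("LA", "LV"), c("RA", "LV"),
                      c("LA", "RV"), c("RA", "RV"))
  rules$Left <- list(c("LV", "RV"), c("LV", "RA"),
                     c("LA", "RV"), c("LA", "RA"))
  rules$Right <- list(c("RV", "LV"), c("RV", "LA"),
                      c("RA", "LV"), c("RA", "LA"))
  rules
}

.canonical_pairs <- function() {
  apply(combn(CHAMBERS, 2), 2, paste, collapse = "_vs_")
}

#' Assemble a pairwise grid from the six chamber contrasts
#'
#' Collects per-gene fold changes and BH-adjusted p-values of all six
#' unordered chamber pairs into one object, re-orienting each contrast onto
#' a canonical orientation. Results may be supplied in either orientation
#' (`"LV_vs_LA"` or `"LA_vs_LV"`); genes present in only some contrasts get
#' `NA` entries, treated as non-significant by the classifier.
#'
#' @param results Named list of contrast data.frames (as from
#'   [run_contrast()], needing columns `gene_id`, `log2FC`, `padj`), with
#'   names of the form `"<chamber>_vs_<chamber>"` covering all six pairs.
#' @return Object of class `pairwise_grid`: a list with matrices `lfc` and
#'   `padj` (genes x 6 canonical pairs).
#' @export
build_pairwise_grid <- function(results) {
  canon <- .canonical_pairs()
  lfc_cols <- list()
  padj_cols <- list()
  genes <- unique(unlist(lapply(results, function(r) r$gene_id)))
  for (nm in names(results)) {
    parts <- strsplit(nm, "_vs_", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !all(parts %in% CHAMBERS))
      stop("contrast name '", nm, "' is not of the form <chamber>_vs_<chamber>",
           call. = FALSE)
    key <- paste(sort(parts), collapse = "_vs_")
    flip <- !identical(paste(parts, collapse = "_vs_"), key)
    r <- results[[nm]]
    idx <- match(genes, r$gene_id)
    lfc_cols[[key]] <- (if (flip) -1 else 1) * r$log2FC[idx]
    padj_cols[[key]] <- r$padj[idx]
  }
  missing <- setdiff(canon, names(lfc_cols))
  if (length(missing))
    stop("missing pairwise comparison(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  lfc <- do.call(cbind, lfc_cols[canon])
  padj <- do.call(cbind, padj_cols[canon])
  rownames(lfc) <- rownames(padj) <- genes
  structure(list(lfc = lfc, padj = padj), class = "pairwise_grid")
}

#' Classify genes into the eight subregion-enrichment classes
#'
#' A gene is enriched in chamber C when it is upregulated at least
#' `fc_threshold`-fold at BH-adjusted p below `q_threshold` in all three
#' comparisons of C against the remaining chambers. Axis classes require the
#' four cross-axis comparisons (e.g. Ventricles: LV over LA, RV over LA, LV
#' over RA and RV over RA; Atria, Left and Right mirrored). All qualifying
#' classes are reported; the primary label takes chamber classes before axis
#' classes, then the fixed order LV, RV, LA, RA, Ventricles, Atria, Left,
#' Right. Missing or `NaN` adjusted p-values count as non-significant.
#'
#' @param grid A [build_pairwise_grid()] result.
#' @param fc_threshold Minimum fold change (linear scale) in every required
#'   comparison.
#' @param q_threshold BH-adjusted p-value cutoff.
#' @return Data.frame with `gene_id`, `primary_label` (factor over the eight
#'   classes plus `"none"`) and `qualifying_labels` (comma-joined).
#' @export
classify_subregion <- function(grid, fc_threshold = 2, q_threshold = 0.01) {
  if (!inherits(grid, "pairwise_grid"))
    stop("'grid' must be a pairwise_grid", call. = FALSE)
  .check_scalar(fc_threshold, "fc_threshold", 1)
  .check_scalar(q_threshold, "q_threshold", 0, strict = TRUE)
  lfc <- grid$lfc
  padj <- grid$padj
  lth <- log2(fc_threshold)
  sig_dir <- function(a, b) {
    key <- paste(sort(c(a, b)), collapse = "_vs_")
    s <- if (identical(key, paste(a, b, sep = "_vs_"))) 1 else -1
    up <- s * lfc[, key] >= lth & padj[, key] < q_threshold
    up & !is.na(up)
  }
  rules <- .subregion_rules()
  qual <- sapply(rules, function(pairs)
    Reduce(`&`, lapply(pairs, function(p) sig_dir(p[1], p[2]))))
  if (is.null(dim(qual))) qual <- matrix(qual, 1, dimnames = list(NULL, names(rules)))
  primary <- apply(qual, 1, function(row) {
    hit <- names(rules)[row]
    if (length(hit)) hit[1] else "none"
  })
  data.frame(
    gene_id = rownames(lfc),
    primary_label = factor(primary, levels = ENRICHMENT_LEVELS),
    qualifying_labels = apply(qual, 1, function(row)
      paste(names(rules)[row], collapse = ",")),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Call heart-enriched genes from a multi-tissue expression panel
#'
#' A gene is heart-enriched when heart ranks within the `top_k` tissues by
#' expression (competition ranking, ties resolved in heart's favor) and its
#' heart expression reaches `min_fpkm`.
#'
#' @param panel Normalized FPKM matrix, genes x tissues, with a column named
#'   by `heart_col`.
#' @param top_k Maximum allowed heart rank.
#' @param min_fpkm Minimum heart expression.
#' @param heart_col Name of the heart column.
#' @return Named logical vector over genes.
#' @export
call_heart_enriched <- function(panel, top_k = 3, min_fpkm = 1,
                                heart_col = "heart") {
  .check_matrix(panel, "panel")
  hits <- which(colnames(panel) == heart_col)
  if (length(hits) != 1)
    stop("panel must contain exactly one '", heart_col, "' column",
         call. = FALSE)
  heart <- panel[, hits]
  others <- panel[, -hits, drop = FALSE]
  rank_heart <- 1 + rowSums(others > heart)
  setNames(rank_heart <= top_k & heart >= min_fpkm, rownames(panel))
}

#' 2x2 overlap table of two gene sets within a universe
#'
#' @param set_a,set_b Character vectors of gene ids, both subsets of
#'   `universe`.
#' @param universe Character vector defining the background.
#' @return 2x2 integer matrix: rows are membership in `set_a`, columns in
#'   `set_b`, so the cells are (|A n B|, |A \ B|, |B \ A|, |neither|).
#' @export
set_overlap_counts <- function(set_a, set_b, universe) {
  if (!length(universe)) stop("'universe' must be non-empty", call. = FALSE)
  universe <- unique(universe)
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  out <- c(setdiff(set_a, universe), setdiff(set_b, universe))
  if (length(out))
    stop("element(s) outside the universe: ",
         paste(head(out, 5), collapse = ", "), call. = FALSE)
  a <- length(intersect(set_a, set_b))
  matrix(c(a, length(set_a) - a,
           length(set_b) - a,
           length(universe) - length(set_a) - length(set_b) + a),
         nrow = 2, byrow = TRUE,
         dimnames = list(in_A = c("yes", "no"), in_B = c("yes", "no")))
}
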