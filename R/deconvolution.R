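# Reference-based cell-type deconvolution of bulk expression by weighted
# non-negative least squares on a type-mean signature, with a correlation QC
# for the single-cell reference, multi-reference ensembling by reconstruction
# error, and Mann-Whitney group comparisons of the estimated proportions.

# depth-normalized per-type mean profiles; the common construction shared by
# build_signature() and simulate_mixtures()
.reference_type_means <- function(counts, labels, target_depth = 1e4) {
  if (is.null(rownames(counts)))
    stop("reference counts need gene row names", call. = FALSE)
  depth <- Matrix::colSums(counts)
  if (any(depth <= 0))
    stop("reference contains cells with zero total counts", call. = FALSE)
  norm <- counts %*% Matrix::Diagonal(x = target_depth / depth)
  types <- unique(labels)
  ind <- outer(labels, types, "==") * 1
  M <- as.matrix(norm %*% ind) %*% diag(1 / colSums(ind), length(types))
  dimnames(M) <- list(rownames(counts), types)
  M
}

#' Build a cell-type signature matrix from a labeled reference
#'
#' Depth-normalizes every cell to a common total, averages cells within each
#' labeled type, and drops types with fewer than `min_cells_per_type` cells
#' (with a warning). Duplicating cells leaves the signature unchanged.
#'
#' @param sc_counts Genes x cells count matrix (dense or `Matrix` sparse)
#'   with gene row names.
#' @param labels Cell-type label per cell.
#' @param min_cells_per_type Minimum cells a type needs to be retained.
#' @param target_depth Common per-cell total after normalization.
#' @return Genes x cell-types signature matrix.
#' @export
build_signature <- function(sc_counts, labels, min_cells_per_type = 20,
                            target_depth = 1e4) {
  if (length(labels) != ncol(sc_counts))
    stop("'labels' must have one entry per cell", call. = FALSE)
  tab <- table(labels)
  low <- names(tab)[tab < min_cells_per_type]
  if (length(low)) {
    warning("dropping cell type(s) below the cell floor: ",
            paste(low, collapse = ", "), call. = FALSE)
    keep <- !(labels %in% low)
    sc_counts <- sc_counts[, keep, drop = FALSE]
    labels <- labels[keep]
  }
  if (length(unique(labels)) < 2)
    stop("fewer than 2 cell types survive the cell floor", call. = FALSE)
  M <- .reference_type_means(sc_counts, labels, target_depth)
  if (any(colSums(M) == 0))
    stop("signature contains an all-zero cell type column", call. = FALSE)
  M
}

#' Remove reference cells with questionable type assignments
#'
#' A cell is removed when its Pearson correlation to its own type's
#' leave-one-out centroid falls below `min_self_correlation` *and* below its
#' correlation to some other type's centroid. Profiles are depth-normalized
#' before correlating.
#'
#' @param sc_counts Genes x cells counts.
#' @param labels Cell-type label per cell.
#' @param min_self_correlation Self-correlation threshold; `-1` disables
#'   removal.
#' @return List with filtered `counts` and `labels`, plus `removed` (ids of
#'   removed cells) and `removed_fraction`.
#' @export
qc_reference <- function(sc_counts, labels, min_self_correlation = 0.5) {
  if (length(labels) != ncol(sc_counts))
    stop("'labels' must have one entry per cell", call. = FALSE)
  X <- as.matrix(sc_counts)
  depth <- colSums(X)
  if (any(depth <= 0))
    stop("reference contains cells with zero total counts", call. = FALSE)
  X <- sweep(X, 2L, depth / 1e4, "/")
  types <- unique(labels)
  centroids <- sapply(types, function(t)
    rowMeans(X[, labels == t, drop = FALSE]))
  n_per <- table(labels)[types]
  drop <- logical(ncol(X))
  for (i in seq_len(ncol(X))) {
    t <- labels[i]
    nt <- n_per[[t]]
    loo <- if (nt > 1) (centroids[, t] * nt - X[, i]) / (nt - 1)
           else centroids[, t]
    cor_self <- suppressWarnings(cor(X[, i], loo))
    if (is.na(cor_self)) cor_self <- 0
    cor_other <- suppressWarnings(
      max(cor(X[, i], centroids[, setdiff(types, t), drop = FALSE]),
          na.rm = TRUE))
    drop[i] <- cor_self < min_self_correlation & cor_self < cor_other
  }
  lost <- setdiff(types, unique(labels[!drop]))
  if (length(lost))
    warning("QC removed every cell of type(s): ",
            paste(lost, collapse = ", "), call. = FALSE)
  cellnames <- colnames(sc_counts)
  list(counts = sc_counts[, !drop, drop = FALSE], labels = labels[!drop],
       removed = if (is.null(cellnames)) which(drop) else cellnames[drop],
       removed_fraction = mean(drop))
}

# one weighted-NNLS fit of all bulk samples against one signature, on the
# supplied gene space; bulk columns are scaled to sum 1 so residuals are
# comparable across samples and references
.wnnls_fit <- function(bulk, signature, weights = NULL, n_rounds = 3) {
  S <- signature
  qrS <- qr(S)
  if (qrS$rank < ncol(S)) {
    bad <- colnames(S)[qrS$pivot[(qrS$rank + 1):ncol(S)]]
    stop("signature is rank-deficient; collinear type(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, nrow(S))
  if (any(weights < 0)) stop("'weights' must be non-negative", call. = FALSE)
  Ss <- S / mean(colSums(S))   # single joint rescale, no per-column scaling
  n_samp <- ncol(bulk)
  P <- matrix(NA_real_, n_samp, ncol(S),
              dimnames = list(colnames(bulk), colnames(S)))
  fitted <- matrix(NA_real_, nrow(S), n_samp,
                   dimnames = list(rownames(S), colnames(bulk)))
  err <- setNames(numeric(n_samp), colnames(bulk))
  for (j in seq_len(n_samp)) {
    tot <- sum(bulk[, j])
    if (tot <= 0) stop("bulk sample '", colnames(bulk)[j],
                       "' has zero total expression", call. = FALSE)
    bs <- bulk[, j] / tot
    scale_r <- mean(bs)
    w <- weights
    for (round in seq_len(n_rounds)) {
      sw <- sqrt(w)
      p <- pracma::lsqnonneg(Ss * sw, bs * sw)$x
      r <- bs - drop(Ss %*% p)
      w <- weights / (1 + (r / scale_r)^2)
    }
    err[j] <- sqrt(mean(r^2))
    fitted[, j] <- drop(Ss %*% p)
    P[j, ] <- if (sum(p) > 0) p / sum(p) else NA_real_
  }
  list(proportions = P, recon_error = err, fitted = fitted)
}

#' Deconvolve bulk samples against one signature by weighted NNLS
#'
#' For each bulk sample, solves
#' \eqn{\min_p \|W^{1/2}(b - S p)\|, p \ge 0} on the genes shared between
#' bulk and signature, iteratively reweighting genes by
#' \eqn{w \propto 1/(1 + r^2)} (residuals taken relative to the mean of the
#' depth-normalized bulk vector, 3 rounds), then normalizes `p` onto the
#' simplex. The reconstruction error (root-mean-square residual before
#' simplex normalization) is recorded per sample. Proportions are relative
#' mRNA content; no cell-size correction is applied.
#'
#' @param bulk Genes x samples expression matrix (a vector is one sample).
#' @param signature Genes x cell-types signature (see [build_signature()]).
#' @param weights Optional non-negative per-gene weights, named by gene or
#'   aligned to the signature rows; default uniform.
#' @param markers_only If `TRUE`, restrict to genes whose top type mean is at
#'   least twice the second (a simple marker filter).
#' @return Object of class `deconv_result`: list with `proportions`
#'   (samples x types, rows on the simplex) and `recon_error`.
#' @export
wnnls_deconvolve <- function(bulk, signature, weights = NULL,
                             markers_only = FALSE) {
  if (is.null(dim(bulk))) bulk <- cbind(sample_1 = bulk)
  if (is.null(rownames(bulk)) || is.null(rownames(signature)))
    stop("bulk and signature need gene row names", call. = FALSE)
  common <- intersect(rownames(bulk), rownames(signature))
  if (length(common) < ncol(signature))
    stop("fewer shared genes than cell types", call. = FALSE)
  S <- signature[common, , drop = FALSE]
  if (markers_only) {
    ratio <- apply(S, 1, function(x) {
      s <- sort(x, decreasing = TRUE)
      if (s[2] == 0) Inf else s[1] / s[2]
    })
    keep <- ratio >= 2
    if (sum(keep) >= ncol(S)) {
      S <- S[keep, , drop = FALSE]
      common <- common[keep]
    }
  }
  if (!is.null(weights) && !is.null(names(weights)))
    weights <- weights[common]
  fit <- .wnnls_fit(bulk[common, , drop = FALSE], S, weights)
  structure(list(proportions = fit$proportions,
                 recon_error = fit$recon_error,
                 n_genes = length(common)),
            class = "deconv_result")
}

#' Ensemble deconvolution across multiple references
#'
#' Fits each signature separately on the gene space shared by the bulk and
#' all signatures, then searches the reference-weight simplex (grid of step
#' `grid_step`, exhaustive for up to three references, coordinate descent
#' beyond) for the weighting whose combined fitted bulk minimizes the pooled
#' root-mean-square reconstruction error. Reported proportions are the
#' weighted combination of the per-reference estimates; cell types absent
#' from a reference contribute zero from it.
#'
#' @param bulk Genes x samples expression matrix.
#' @param signatures Non-empty list of signature matrices; all pairs must
#'   share at least two cell types.
#' @param grid_step Weight-grid resolution.
#' @return `deconv_result` with additional elements `weights` (per
#'   reference) and `per_reference` (list of per-reference fits).
#' @export
ensemble_deconvolve <- function(bulk, signatures, grid_step = 0.01) {
  if (!is.list(signatures) || !length(signatures))
    stop("'signatures' must be a non-empty list", call. = FALSE)
  if (is.null(names(signatures)))
    names(signatures) <- sprintf("ref_%d", seq_along(signatures))
  if (is.null(dim(bulk))) bulk <- cbind(sample_1 = bulk)
  shared_types <- Reduce(intersect, lapply(signatures, colnames))
  if (length(signatures) > 1 && length(shared_types) < 2)
    stop("references must share at least two cell types", call. = FALSE)
  common <- Reduce(intersect, c(list(rownames(bulk)),
                                lapply(signatures, rownames)))
  if (length(common) < max(vapply(signatures, ncol, 0L)))
    stop("fewer shared genes than cell types", call. = FALSE)
  B <- bulk[common, , drop = FALSE]
  B <- sweep(B, 2L, colSums(B), "/")
  fits <- lapply(signatures, function(S)
    .wnnls_fit(B, S[common, , drop = FALSE]))
  n_ref <- length(fits)
  all_types <- unique(unlist(lapply(signatures, colnames)))
  expand <- function(P) {
    out <- matrix(0, nrow(P), length(all_types),
                  dimnames = list(rownames(P), all_types))
    out[, colnames(P)] <- P
    out
  }
  props <- lapply(fits, function(f) expand(f$proportions))

  pooled_rmse <- function(w) {
    Yhat <- Reduce(`+`, Map(function(f, wi) f$fitted * wi, fits, w))
    sqrt(mean((B - Yhat)^2))
  }
  if (n_ref == 1) {
    w <- 1
  } else {
    grid <- .simplex_grid(n_ref, grid_step)
    if (is.null(grid)) {  # too many references for the exhaustive grid
      w <- rep(1 / n_ref, n_ref)
      steps <- seq(0, 1, by = grid_step)
      for (pass in 1:5) {
        for (i in seq_len(n_ref - 1)) for (j in (i + 1):n_ref) {
          mass <- w[i] + w[j]
          if (mass == 0) next
          cand <- steps[steps <= mass]
          vals <- vapply(cand, function(wi) {
            ww <- w; ww[i] <- wi; ww[j] <- mass - wi
            pooled_rmse(ww)
          }, 0)
          w[i] <- cand[which.min(vals)]
          w[j] <- mass - w[i]
        }
      }
    } else {
      vals <- apply(grid, 1, pooled_rmse)
      w <- grid[which.min(vals), ]
    }
  }
  w <- setNames(as.numeric(w), names(signatures))
  P <- Reduce(`+`, Map(function(Pr, wi) Pr * wi, props, w))
  Yhat <- Reduce(`+`, Map(function(f, wi) f$fitted * wi, fits, w))
  err <- sqrt(colMeans((B - Yhat)^2))
  structure(list(proportions = P, recon_error = err, weights = w,
                 per_reference = fits, n_genes = length(common)),
            class = "deconv_result")
}

# all weight vectors on the simplex with the given step; NULL when the grid
# would be too large (> 3 references)
.simplex_grid <- function(k, step) {
  if (k > 3) return(NULL)
  m <- round(1 / step)
  if (k == 2) {
    i <- 0:m
    cbind(i / m, 1 - i / m)
  } else {
    out <- list()
    idx <- 1
    for (i in 0:m) for (j in 0:(m - i)) {
      out[[idx]] <- c(i / m, j / m, (m - i - j) / m)
      idx <- idx + 1
    }
    do.call(rbind, out)
  }
}

# Mann-Whitney U test; exact null distribution when there are no ties (via
# the Wilcoxon rank-sum distribution), complete enumeration for small tied
# samples, tie-corrected normal approximation otherwise
.mann_whitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && n1 * n2 <= 400) {
    p_greater <- sum(dwilcox(ceiling(U - 1e-9):(n1 * n2), n1, n2))
    p_less <- sum(dwilcox(0:floor(U + 1e-9), n1, n2))
    method <- "exact"
  } else if (ties && choose(N, n1) <= 2e5) {
    cmb <- combn(N, n1)
    U_all <- colSums(matrix(r[cmb], nrow = n1)) - n1 * (n1 + 1) / 2
    p_greater <- mean(U_all >= U - 1e-9)
    p_less <- mean(U_all <= U + 1e-9)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(c(x, y))
    sig2 <- n1 * n2 / 12 *
      ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sig2 <= 0) {
      p_greater <- p_less <- 1
    } else {
      p_greater <- pnorm((U - mu - 0.5) / sqrt(sig2), lower.tail = FALSE)
      p_less <- pnorm((U - mu + 0.5) / sqrt(sig2))
    }
    method <- "normal_approx"
  }
  list(U = U, p_greater = min(1, p_greater), p_less = min(1, p_less),
       p_two_sided = min(1, 2 * min(p_greater, p_less)), method = method)
}

#' Compare estimated cell-type proportions between two sample groups
#'
#' Mann-Whitney U test of one cell type's proportions between the two levels
#' of a metadata grouping (e.g. disease: HFrEF vs NF). The null distribution
#' is exact for small untied samples; see Details in the package vignette.
#'
#' @param result A `deconv_result` (or a samples x types proportion matrix).
#' @param metadata Data.frame with `sample_id` plus the grouping column.
#' @param cell_type Cell-type column to compare.
#' @param group_by Metadata column defining the groups.
#' @param groups Optional two group levels (required when the column has
#'   more than two).
#' @return One-row data.frame with group sizes, medians, `U`, one- and
#'   two-sided p-values and the method used.
#' @export
compare_proportions <- function(result, metadata, cell_type,
                                group_by = "disease", groups = NULL) {
  P <- if (inherits(result, "deconv_result")) result$proportions else result
  if (!cell_type %in% colnames(P))
    stop("unknown cell type '", cell_type, "'", call. = FALSE)
  idx <- match(rownames(P), metadata$sample_id)
  if (anyNA(idx))
    stop("samples absent from metadata: ",
         paste(head(rownames(P)[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  g <- as.character(metadata[[group_by]][idx])
  if (is.null(groups)) groups <- unique(g)
  if (length(groups) != 2)
    stop("'", group_by, "' must yield exactly two groups (use 'groups=')",
         call. = FALSE)
  x <- P[g == groups[1], cell_type]
  y <- P[g == groups[2], cell_type]
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs >= 2 samples", call. = FALSE)
  mw <- .mann_whitney(x, y)
  data.frame(cell_type = cell_type, group_A = groups[1], group_B = groups[2],
             n_A = length(x), n_B = length(y),
             median_A = median(x), median_B = median(y),
             U = mw$U, p_greater = mw$p_greater,
             p_two_sided = mw$p_two_sided, method = mw$method,
             stringsAsFactors = FALSE)
}
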