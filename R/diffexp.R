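# Per-gene negative-binomial Wald tests between two sample groups, with
# median-of-ratios size factors, optional covariate adjustment and BH
# correction. The NB GLM (log link, Var = mu + alpha*mu^2) is fit by IRLS;
# the gene-wise dispersion is estimated by Cox-Reid-adjusted profile maximum
# likelihood, alternating twice with the mean fit, with a method-of-moments
# fallback. At the contrast level the gene-wise estimates are moderated by
# empirical-Bayes shrinkage toward a parametric mean-dispersion trend
# (alpha ~ a0 + a1/mu): with a handful of samples per group the raw
# gene-wise estimator underestimates dispersion often enough to inflate the
# FDR, and shrinkage restores calibration without costing power. No LFC
# shrinkage, independent filtering or outlier handling is attempted.

.DISP_FLOOR <- 1e-8
.DISP_CEIL <- 10

.nb_loglik <- function(y, mu, alpha) {
  if (alpha < 1e-10) sum(stats::dpois(y, mu, log = TRUE))
  else sum(stats::dnbinom(y, mu = mu, size = 1 / alpha, log = TRUE))
}

# one IRLS fit at fixed dispersion; returns coefficients, fitted means and
# the weighted information matrix
.nb_irls <- function(y, X, offset, alpha, beta = NULL,
                     maxit = 25L, tol = 1e-8) {
  if (is.null(beta)) {
    beta <- qr.coef(qr(X), log(pmax(y, 0.5)) - offset)
    beta[is.na(beta)] <- 0
  }
  eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
  mu <- exp(eta)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    wx <- X * w
    beta_new <- tryCatch(solve(crossprod(X, wx), crossprod(wx, z)),
                         error = function(e) NULL)
    if (is.null(beta_new)) break
    beta <- drop(beta_new)
    eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
    mu <- exp(eta)
    ll <- .nb_loglik(y, mu, alpha)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  w <- mu / (1 + alpha * mu)
  list(beta = beta, mu = mu, XtWX = crossprod(X, X * w),
       converged = converged, ll = ll_old)
}

# Cox-Reid adjusted profile log-likelihood of the dispersion at fixed means
.cr_profile <- function(log_alpha, y, mu, X) {
  alpha <- exp(log_alpha)
  w <- mu / (1 + alpha * mu)
  ld <- determinant(crossprod(X, X * w), logarithm = TRUE)$modulus
  .nb_loglik(y, mu, alpha) - 0.5 * as.numeric(ld)
}

.estimate_dispersion <- function(y, mu, X) {
  mom <- sum((y - mu)^2 - mu) / sum(mu^2)
  mom <- min(max(mom, .DISP_FLOOR), .DISP_CEIL)
  opt <- tryCatch(
    optimize(.cr_profile, c(log(.DISP_FLOOR), log(.DISP_CEIL)),
             y = y, mu = mu, X = X, maximum = TRUE, tol = 1e-4),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$objective)) {
    list(alpha = mom, fallback = TRUE)
  } else {
    # keep the better of the profile optimum and the MoM point
    if (.cr_profile(log(mom), y, mu, X) > opt$objective)
      list(alpha = mom, fallback = TRUE)
    else list(alpha = exp(opt$maximum), fallback = FALSE)
  }
}

# design matrix: intercept, group indicator, then covariates (numeric ones
# standardized, categorical ones as treatment contrasts); constant covariates
# are dropped with a warning
.build_design <- function(group_a, covariates) {
  X <- cbind(`(Intercept)` = 1, group = as.numeric(group_a))
  if (!is.null(covariates) && ncol(covariates)) {
    for (nm in colnames(covariates)) {
      v <- covariates[[nm]]
      if (is.numeric(v)) {
        if (sd(v) == 0) {
          warning("covariate '", nm, "' is constant within the design; dropped",
                  call. = FALSE)
          next
        }
        X <- cbind(X, (v - mean(v)) / sd(v))
        colnames(X)[ncol(X)] <- nm
      } else {
        f <- factor(v)
        if (nlevels(f) < 2) {
          warning("covariate '", nm, "' is constant within the design; dropped",
                  call. = FALSE)
          next
        }
        mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
        colnames(mm) <- paste0(nm, levels(f)[-1])
        X <- cbind(X, mm)
      }
    }
  }
  X
}

#' Negative-binomial Wald test for one gene
#'
#' Fits an NB GLM with log link and `log(size_factors)` offsets to a single
#' gene's counts, with the two-group indicator and optional covariates as
#' terms. The Wald statistic is the group coefficient over its standard
#' error, referred to the standard normal; `log2FC` is the group coefficient
#' divided by `ln 2` (side A over side B).
#'
#' @param y Non-negative integer counts across the contrast's samples.
#' @param group_a Logical vector, `TRUE` for samples in side A.
#' @param covariates Optional data.frame of per-sample covariates.
#' @param size_factors Positive per-sample size factors (default all 1).
#' @param dispersion Fix the NB dispersion instead of estimating it
#'   (useful for Poisson-limit checks); `NULL` estimates it.
#' @param dispersion_prior Optional list with `log_mean` and `var`: a
#'   lognormal prior on the dispersion, maximized jointly with the
#'   Cox-Reid-adjusted profile likelihood (used by [run_contrast()] for
#'   trend shrinkage).
#' @return List with `log2FC`, `p_value`, `se_log2FC`, `dispersion`, and a
#'   `status` of `"ok"`, `"untestable"` (all-zero gene, reported with
#'   `log2FC = 0`, `p = 1`) or `"nonconverged"` (fallback estimate).
#' @export
nb_fit_and_test <- function(y, group_a, covariates = NULL,
                            size_factors = NULL, dispersion = NULL,
                            dispersion_prior = NULL) {
  y <- as.numeric(y)
  if (any(y < 0) || anyNA(y)) stop("'y' must be non-negative", call. = FALSE)
  group_a <- as.logical(group_a)
  if (length(group_a) != length(y))
    stop("'group_a' must match 'y' in length", call. = FALSE)
  if (sum(group_a) < 2 || sum(!group_a) < 2)
    stop("each group needs >= 2 samples", call. = FALSE)
  if (is.null(size_factors)) size_factors <- rep(1, length(y))
  if (any(size_factors <= 0))
    stop("'size_factors' must be positive", call. = FALSE)
  if (all(y == 0))
    return(list(log2FC = 0, p_value = 1, se_log2FC = NA_real_,
                dispersion = NA_real_, status = "untestable"))
  X <- .build_design(group_a, covariates)
  offset <- log(size_factors)

  fit <- .nb_irls(y, X, offset, alpha = .DISP_FLOOR)
  fallback <- FALSE
  if (!is.null(dispersion_prior)) {
    post <- function(la)
      .cr_profile(la, y, fit$mu, X) -
        (la - dispersion_prior$log_mean)^2 / (2 * dispersion_prior$var)
    opt <- tryCatch(
      optimize(post, c(log(.DISP_FLOOR), log(.DISP_CEIL)),
               maximum = TRUE, tol = 1e-4),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective)) {
      alpha <- exp(dispersion_prior$log_mean)
      fallback <- TRUE
    } else {
      alpha <- exp(opt$maximum)
    }
    fit <- .nb_irls(y, X, offset, alpha, beta = fit$beta)
  } else if (is.null(dispersion)) {
    alpha <- .DISP_FLOOR
    for (round in 1:2) {
      est <- .estimate_dispersion(y, fit$mu, X)
      alpha <- est$alpha
      fallback <- fallback || est$fallback
      fit <- .nb_irls(y, X, offset, alpha, beta = fit$beta)
    }
  } else {
    alpha <- max(dispersion, .DISP_FLOOR)
    fit <- .nb_irls(y, X, offset, alpha, beta = fit$beta)
  }
  cov <- tryCatch(solve(fit$XtWX), error = function(e) NULL)
  if (is.null(cov) || !fit$converged) {
    se <- if (is.null(cov)) NA_real_ else sqrt(cov[2, 2])
    status <- "nonconverged"
  } else {
    se <- sqrt(cov[2, 2])
    status <- if (fallback) "nonconverged" else "ok"
  }
  se <- unname(se)
  beta_g <- unname(fit$beta[2])
  p <- if (is.na(se) || se == 0) 1 else 2 * pnorm(-abs(beta_g / se))
  list(log2FC = beta_g / log(2), p_value = p, se_log2FC = se / log(2),
       dispersion = alpha, status = status)
}

# parametric mean-dispersion trend alpha(mu) = a0 + a1/mu fit by iterated
# outlier-trimmed least squares, plus the lognormal prior width for
# empirical-Bayes shrinkage of the gene-wise estimates. The expected
# sampling variance of a log dispersion estimate at df residual degrees of
# freedom is approximated by trigamma(df/2); the prior variance is the
# excess spread (MAD-based) of the log residuals around the trend.
.dispersion_trend <- function(alpha, base_mean, df_resid) {
  ok <- is.finite(alpha) & alpha > 10 * .DISP_FLOOR & base_mean > 0
  xs <- 1 / pmax(base_mean, 1e-8)
  co <- c(median(alpha[ok]), 0)
  if (sum(ok) >= 50) {
    fit <- tryCatch(stats::lm(alpha[ok] ~ xs[ok]), error = function(e) NULL)
    if (!is.null(fit)) {
      co_try <- unname(stats::coef(fit))
      for (it in 1:3) {
        tr <- pmax(co_try[1] + co_try[2] * xs, 1e-6)
        lr <- log(pmax(alpha, .DISP_FLOOR)) - log(tr)
        keep <- ok & abs(lr) < 3 * stats::mad(lr[ok]) + 1e-8
        if (sum(keep) < 50) break
        fit <- stats::lm(alpha[keep] ~ xs[keep])
        co_try <- unname(stats::coef(fit))
      }
      if (all(is.finite(co_try))) co <- pmax(co_try, 0)
    }
  }
  trend <- pmax(co[1] + co[2] * xs, 1e-6)
  s2_samp <- trigamma(max(df_resid, 1) / 2)
  lr <- log(pmax(alpha, .DISP_FLOOR)) - log(trend)
  s2_prior <- max(0.0625, stats::mad(lr[ok])^2 - s2_samp)
  list(trend = trend, coef = co, s2_prior = s2_prior)
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling factors computed as the median ratio of each sample's
#' counts to the geometric-mean pseudo-reference, over genes expressed in
#' every sample; falls back to total-count ratios when no such gene exists.
#' Factors are rescaled to geometric mean 1.
#'
#' @param counts Count matrix, genes x samples.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  .check_matrix(counts, "counts")
  everywhere <- rowSums(counts > 0) == ncol(counts)
  if (any(everywhere)) {
    lc <- log(counts[everywhere, , drop = FALSE])
    ref <- rowMeans(lc)
    sf <- apply(lc, 2L, function(x) exp(median(x - ref)))
  } else {
    sf <- colSums(counts)
  }
  setNames(.geom_standardize(sf), colnames(counts))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: on the sorted p-values,
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, mapped back to input order
#' and clipped at 1. `NA` entries propagate as `NA` and do not count toward
#' the family size `m`.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return Adjusted vector of the same length.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("'p_values' must lie in [0, 1]", call. = FALSE)
  q <- rep(NA_real_, length(p_values))
  q[ok] <- p.adjust(p_values[ok], method = "BH")
  q
}

#' Run one pairwise differential-expression contrast
#'
#' The full per-contrast procedure: restrict to the contrast's samples,
#' normalize (FPKM then percentile anchoring), drop lowly expressed genes on
#' those samples, fit every surviving gene's NB GLM on the raw counts with
#' median-of-ratios size-factor offsets, and BH-adjust across the surviving
#' genes. Fold changes are oriented A over B.
#'
#' @param counts Raw count matrix, genes x samples.
#' @param gene_lengths Gene lengths (see [counts_to_fpkm()]).
#' @param metadata Data.frame with a `sample_id` column and any covariate
#'   columns named in `covariates`.
#' @param samples_a,samples_b Disjoint character vectors of sample ids
#'   (each >= 2).
#' @param name Contrast label stored in the result.
#' @param covariates Metadata columns entered as additional GLM terms
#'   (e.g. `c("sex", "age")`).
#' @param percentile,anchor_value Anchoring parameters
#'   (see [anchor_normalize()]).
#' @param min_fpkm,min_samples Expression filter applied to the contrast's
#'   samples (see [expression_filter()]).
#' @param dispersion Optional fixed dispersion passed to [nb_fit_and_test()]
#'   (disables moderation).
#' @param moderate_dispersion Shrink gene-wise dispersions toward a fitted
#'   mean-dispersion trend before the final fit (default; needs >= 50 tested
#'   genes, otherwise the raw gene-wise estimates are used).
#' @return Data.frame with columns `gene_id`, `baseMean_A`, `baseMean_B`,
#'   `log2FC`, `pvalue`, `padj`, `status`, plus a `contrast` attribute.
#' @export
run_contrast <- function(counts, gene_lengths, metadata,
                         samples_a, samples_b, name = "A_vs_B",
                         covariates = character(),
                         percentile = 70, anchor_value = 10,
                         min_fpkm = 1, min_samples = 5, dispersion = NULL,
                         moderate_dispersion = TRUE) {
  .check_matrix(counts, "counts")
  if (length(intersect(samples_a, samples_b)))
    stop("contrast groups must be disjoint", call. = FALSE)
  if (length(samples_a) < 2 || length(samples_b) < 2)
    stop("each contrast group needs >= 2 samples", call. = FALSE)
  samples <- c(samples_a, samples_b)
  missing <- setdiff(samples, colnames(counts))
  if (length(missing))
    stop("samples absent from counts: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!all(samples %in% metadata$sample_id))
    stop("samples absent from metadata", call. = FALSE)

  sub <- counts[, samples, drop = FALSE]
  fpkm <- anchor_normalize(counts_to_fpkm(sub, gene_lengths),
                           percentile, anchor_value)
  filt <- expression_filter(fpkm, min_fpkm, min_samples)
  kept <- filt$kept
  sf <- size_factors(sub)
  group_a <- samples %in% samples_a
  covs <- NULL
  if (length(covariates)) {
    missing_cov <- setdiff(covariates, names(metadata))
    if (length(missing_cov))
      stop("covariate(s) absent from metadata: ",
           paste(missing_cov, collapse = ", "), call. = FALSE)
    meta <- metadata[match(samples, metadata$sample_id), , drop = FALSE]
    covs <- meta[, covariates, drop = FALSE]
  }

  norm_counts <- sweep(sub, 2L, sf, "/")
  res <- data.frame(
    gene_id = rownames(sub)[kept],
    baseMean_A = rowMeans(norm_counts[kept, group_a, drop = FALSE]),
    baseMean_B = rowMeans(norm_counts[kept, !group_a, drop = FALSE]),
    log2FC = NA_real_, pvalue = NA_real_, padj = NA_real_,
    status = NA_character_, row.names = NULL,
    stringsAsFactors = FALSE
  )
  alpha_g <- rep(NA_real_, length(kept))
  for (i in seq_along(kept)) {
    fit <- nb_fit_and_test(sub[kept[i], ], group_a, covariates = covs,
                           size_factors = sf, dispersion = dispersion)
    res$log2FC[i] <- fit$log2FC
    res$pvalue[i] <- fit$p_value
    res$status[i] <- fit$status
    alpha_g[i] <- fit$dispersion
  }
  if (moderate_dispersion && is.null(dispersion) &&
      sum(!is.na(alpha_g)) >= 50) {
    n_design <- 2 + if (is.null(covs)) 0 else ncol(covs)
    base_mean <- (res$baseMean_A * sum(group_a) +
                    res$baseMean_B * sum(!group_a)) / length(group_a)
    tr <- .dispersion_trend(alpha_g, base_mean,
                            df_resid = length(group_a) - n_design)
    for (i in seq_along(kept)) {
      if (res$status[i] == "untestable") next
      fit <- nb_fit_and_test(
        sub[kept[i], ], group_a, covariates = covs, size_factors = sf,
        dispersion_prior = list(log_mean = log(tr$trend[i]),
                                var = tr$s2_prior))
      res$log2FC[i] <- fit$log2FC
      res$pvalue[i] <- fit$p_value
      res$status[i] <- fit$status
    }
  }
  res$padj <- bh_adjust(res$pvalue)
  attr(res, "contrast") <- list(name = name, samples_a = samples_a,
                                samples_b = samples_b,
                                covariates = covariates)
  res
}

#' Select sample ids by chamber and/or disease
#'
#' @param metadata Sample metadata with `sample_id`, `chamber`, `disease`.
#' @param chamber,disease Optional values to match.
#' @return Character vector of sample ids.
#' @export
select_samples <- function(metadata, chamber = NULL, disease = NULL) {
  keep <- rep(TRUE, nrow(metadata))
  if (!is.null(chamber)) keep <- keep & metadata$chamber %in% chamber
  if (!is.null(disease)) keep <- keep & metadata$disease %in% disease
  metadata$sample_id[keep]
}
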