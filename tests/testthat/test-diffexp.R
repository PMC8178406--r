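test_that("size factors: identity, closed-form ratio, equivariance", {
  counts <- toy_counts(30, 4, seed = 1, mu = 80) + 1
  same <- counts
  same[] <- counts[, 1]
  expect_equal(unname(size_factors(same)), rep(1, 4))

  # one sample exactly 3x another: factors sqrt(3) and 1/sqrt(3)
  two <- counts[, 1:2]
  two[, 2] <- two[, 1] * 3
  sf <- size_factors(two)
  expect_equal(unname(sf), c(1 / sqrt(3), sqrt(3)))
  expect_equal(exp(mean(log(sf))), 1)

  # permuting samples permutes the factors identically
  perm <- c(3, 1, 4, 2)
  expect_equal(unname(size_factors(counts[, perm])),
               unname(size_factors(counts))[perm])
})

test_that("bh_adjust matches the brute-force step-up everywhere", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.3, 7)), rep(0.3, 7))

  set.seed(42)
  for (i in 1:200) {
    p <- runif(sample(1:80, 1))
    q <- bh_adjust(p)
    expect_equal(q, bf_bh(p))
    # monotone transform
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
  }

  # NA propagates and is excluded from the family size
  p <- c(0.01, NA, 0.02)
  q <- bh_adjust(p)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bf_bh(c(0.01, 0.02)))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("NB Wald test recovers exact ratios and the Poisson limit", {
  # group A exactly 2x group B at unit size factors, near-zero dispersion
  y <- c(20, 40, 60, 80, 10, 20, 30, 40)
  grp <- rep(c(TRUE, FALSE), each = 4)
  fit <- nb_fit_and_test(y, grp, dispersion = 0)
  expect_equal(fit$log2FC, 1, tolerance = 1e-6)

  # at dispersion -> 0 the fit agrees with a Poisson GLM Wald test
  set.seed(5)
  y <- rpois(40, lambda = rep(c(30, 60), each = 20))
  grp <- rep(c(FALSE, TRUE), each = 20)
  fit <- nb_fit_and_test(y, grp, dispersion = 0)
  g <- stats::glm(y ~ grp, family = stats::poisson())
  sm <- summary(g)$coefficients
  expect_equal(fit$log2FC, sm[2, 1] / log(2), tolerance = 1e-3)
  expect_equal(fit$p_value, sm[2, 4], tolerance = 1e-3)

  # swapping the groups negates the fold change and keeps the p-value
  f1 <- nb_fit_and_test(y, grp)
  f2 <- nb_fit_and_test(y, !grp)
  expect_equal(f1$log2FC, -f2$log2FC, tolerance = 1e-8)
  expect_equal(f1$p_value, f2$p_value, tolerance = 1e-8)

  # all-zero gene is reported untestable, not dropped
  f0 <- nb_fit_and_test(rep(0, 8), rep(c(TRUE, FALSE), each = 4))
  expect_identical(f0$status, "untestable")
  expect_equal(f0$log2FC, 0)
  expect_equal(f0$p_value, 1)
})

test_that("Wald intervals cover a known Poisson ratio", {
  # truth: ratio 4 (log2FC = 2), n = 50/group; 95% interval should cover in
  # at least 93% of seeded replicates
  set.seed(99)
  covered <- logical(500)
  for (i in seq_len(500)) {
    y <- rpois(100, lambda = rep(c(10, 40), each = 50))
    fit <- nb_fit_and_test(y, rep(c(FALSE, TRUE), each = 50))
    half <- 1.96 * fit$se_log2FC
    covered[i] <- fit$log2FC - half <= 2 && 2 <= fit$log2FC + half
  }
  expect_gte(mean(covered), 0.93)
})

test_that("covariate adjustment absorbs a sex confounder", {
  # gene driven by sex only; groups imbalanced in sex, so the unadjusted
  # test sees a spurious effect that the adjusted test removes
  set.seed(21)
  sex <- rep(c("M", "F"), times = c(10, 10))
  grp <- c(rep(TRUE, 8), rep(FALSE, 2), rep(TRUE, 2), rep(FALSE, 8))
  y <- rnbinom(20, mu = 50 * 2^(2 * (sex == "M")), size = 20)
  unadj <- nb_fit_and_test(y, grp)
  adj <- nb_fit_and_test(y, grp, covariates = data.frame(sex = sex))
  expect_lt(unadj$p_value, 0.01)
  expect_gt(adj$p_value, 0.01)

  # constant covariate is dropped with a warning, not an error
  expect_warning(
    nb_fit_and_test(y, grp, covariates = data.frame(sex = rep("M", 20))),
    "constant")
})

test_that("run_contrast recovers planted 4-fold genes and stays null-calm", {
  planted <- data.frame(gene = 1:40, chambers = "LV", diseases = "*",
                        log2fc = 2)
  spec <- bulk_sim_spec(n_genes = 600, chambers = c("LA", "LV"),
                        diseases = "NF", donors_per_group = 6,
                        baseline_mean = 100, dispersion = 0.1,
                        planted_effects = planted, seed = 314)
  b <- simulate_bulk(spec)
  res <- run_contrast(b$counts, b$gene_lengths, b$metadata,
                      select_samples(b$metadata, "LV"),
                      select_samples(b$metadata, "LA"),
                      name = "LV_vs_LA")
  called <- !is.na(res$padj) & res$padj < 0.01
  truth <- res$gene_id %in% sprintf("gene_%05d", 1:40)
  expect_gte(sum(called & truth) / 40, 0.9)
  expect_lte(sum(called & !truth) / max(1, sum(called)), 0.05)
  # planted genes are upregulated about 2 on the log2 scale
  expect_equal(median(res$log2FC[truth]), 2, tolerance = 0.2)

  # contrast of a group against itself: essentially no q < 0.01 calls
  lv <- select_samples(b$metadata, "LV")
  set.seed(1)
  half <- sample(lv, 3)
  null_res <- run_contrast(b$counts, b$gene_lengths, b$metadata,
                           half, setdiff(lv, half), name = "null")
  expect_lte(sum(null_res$padj < 0.01, na.rm = TRUE), 2)
})

test_that("run_contrast enforces its preconditions", {
  b <- simulate_bulk(bulk_sim_spec(n_genes = 20, donors_per_group = 2,
                                   seed = 3))
  s <- b$metadata$sample_id
  expect_error(run_contrast(b$counts, b$gene_lengths, b$metadata,
                            s[1:3], s[3:6]), "disjoint")
  expect_error(run_contrast(b$counts, b$gene_lengths, b$metadata,
                            s[1], s[2:4]), ">= 2")
  expect_error(run_contrast(b$counts, b$gene_lengths, b$metadata,
                            c(s[1:2], "ghost"), s[3:4]), "ghost")
})
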