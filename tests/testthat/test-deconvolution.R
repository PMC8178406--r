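test_that("signature construction: type profiles, duplication, rank, floors", {
  # two types of internally identical cells: columns equal the profiles
  prof <- cbind(A = c(10, 0, 2, 4), B = c(0, 8, 2, 4))
  rownames(prof) <- sprintf("g%d", 1:4)
  counts <- prof[, rep(c("A", "B"), each = 3)]
  colnames(counts) <- sprintf("c%d", 1:6)
  labels <- rep(c("A", "B"), each = 3)
  sig <- build_signature(counts, labels, min_cells_per_type = 2)
  norm_prof <- sweep(prof, 2, colSums(prof) / 1e4, "/")
  expect_equal(sig, norm_prof)

  # duplicating every cell leaves the signature unchanged
  dup <- cbind(counts, counts)
  colnames(dup) <- sprintf("c%d", 1:12)
  expect_equal(build_signature(dup, rep(labels, 2), min_cells_per_type = 2),
               sig)

  # planted 7-type reference gives a rank-7 signature
  r <- simulate_reference(7, 30, 500, seed = 1)
  s7 <- build_signature(r$counts, r$labels, min_cells_per_type = 10)
  expect_equal(qr(s7)$rank, 7)

  # cell floor drops a type with a warning; < 2 survivors is an error
  wide <- prof[, c("A", "A", "A", "B", "B", "B", "A", "B")]
  colnames(wide) <- sprintf("c%d", 1:8)
  labels3 <- c(rep(c("A", "B"), each = 3), "C", "C")
  expect_warning(
    s <- build_signature(wide, labels3, min_cells_per_type = 3),
    "cell floor")
  expect_identical(colnames(s), c("A", "B"))
  expect_error(
    suppressWarnings(build_signature(counts, c("A", "A", "A", "B", "C", "D"),
                                     min_cells_per_type = 2)),
    "fewer than 2")
})

test_that("reference QC removes mislabeled cells and only those", {
  r <- simulate_reference(3, 30, 300, dispersion = 0.05, seed = 2)
  # clean reference: nothing removed
  qc <- qc_reference(r$counts, r$labels)
  expect_equal(length(qc$removed), 0)

  # a cell generated from type 1 but labeled as type 2 is removed
  bad <- r$labels
  swap_idx <- 1L  # first cell belongs to the first type
  bad[swap_idx] <- unique(r$labels)[2]
  qc2 <- qc_reference(r$counts, bad)
  expect_true(colnames(r$counts)[swap_idx] %in% qc2$removed)

  # vacuous threshold: identity
  qc3 <- qc_reference(r$counts, bad, min_self_correlation = -1)
  expect_equal(length(qc3$removed), 0)
})

test_that("weighted NNLS recovers pure and noiseless mixed samples exactly", {
  r <- simulate_reference(7, 40, 400, seed = 3)
  sig <- build_signature(r$counts, r$labels)

  # bulk equal to one signature column
  pure <- wnnls_deconvolve(sig[, 4] * 50, sig)
  expect_equal(unname(pure$proportions[1, 4]), 1, tolerance = 1e-9)
  expect_lt(pure$recon_error[1], 1e-12)

  # noiseless 0.6/0.3/0.1 mixture
  p_true <- c(0.6, 0.3, 0.1, rep(0, 4))
  names(p_true) <- colnames(sig)
  mix <- simulate_mixtures(r, p_true, noise_sd = 0)
  dec <- wnnls_deconvolve(mix$bulk, sig)
  expect_equal(unname(dec$proportions[1, ]), unname(p_true),
               tolerance = 1e-6)

  # scaling the bulk vector changes nothing
  dec2 <- wnnls_deconvolve(mix$bulk * 1e3, sig)
  expect_equal(dec2$proportions, dec$proportions, tolerance = 1e-12)

  # with uniform weights and an interior solution, NNLS equals the
  # unconstrained least-squares solve
  ls <- qr.solve(sig, mix$bulk[, 1])
  expect_true(all(ls > -1e-8))
  expect_equal(unname(dec$proportions[1, ]),
               unname(pmax(ls, 0) / sum(pmax(ls, 0))), tolerance = 1e-6)

  # rank-deficient signature names the collinear types
  dup_sig <- cbind(sig, Duplicate = sig[, 1])
  expect_error(wnnls_deconvolve(mix$bulk, dup_sig), "collinear")
})

test_that("noisy mixtures are recovered within tolerance and without bias", {
  r <- simulate_reference(7, 50, 500, seed = 4)
  sig <- build_signature(r$counts, r$labels)
  set.seed(5)
  P <- t(sapply(1:50, function(i) {
    p <- rlnorm(7, 0, 0.8)
    p / sum(p)
  }))
  colnames(P) <- colnames(sig)
  mix <- simulate_mixtures(r, P, noise_sd = 0.2, seed = 6)
  dec <- wnnls_deconvolve(mix$bulk, sig)
  err <- dec$proportions[, colnames(P)] - mix$proportions
  expect_lte(mean(abs(err)), 0.05)
  expect_lte(max(abs(colMeans(err))), 0.02)
  # simplex invariant on every sample
  expect_equal(unname(rowSums(dec$proportions)), rep(1, 50),
               tolerance = 1e-8)
  expect_true(all(dec$proportions >= 0))
})

test_that("ensemble weighting favors the generating reference", {
  r <- simulate_reference(4, 40, 300, seed = 7)
  sig <- build_signature(r$counts, r$labels)
  set.seed(8)
  P <- t(sapply(1:10, function(i) {
    p <- runif(4); p / sum(p)
  }))
  colnames(P) <- colnames(sig)
  mix <- simulate_mixtures(r, P, noise_sd = 0.1, seed = 9)

  # single reference: identical to the plain fit, weight 1
  single <- ensemble_deconvolve(mix$bulk, list(true = sig))
  plain <- wnnls_deconvolve(mix$bulk, sig)
  expect_equal(single$proportions[, colnames(sig)], plain$proportions,
               tolerance = 1e-9)
  expect_equal(unname(single$weights), 1)

  # corrupted second reference (profiles scrambled across genes)
  set.seed(10)
  corrupt <- sig[sample(nrow(sig)), ]
  rownames(corrupt) <- rownames(sig)
  ens <- ensemble_deconvolve(mix$bulk, list(true = sig, corrupt = corrupt),
                             grid_step = 0.05)
  expect_gte(ens$weights[["true"]], 0.8)

  # two identical references: proportions equal the single-reference answer
  twin <- ensemble_deconvolve(mix$bulk, list(a = sig, b = sig),
                              grid_step = 0.25)
  expect_equal(twin$proportions[, colnames(sig)], plain$proportions,
               tolerance = 1e-9)
})

test_that("Mann-Whitney comparisons are exact where promised", {
  mw <- cardioregion:::.mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_less, 1 / 20)  # enumeration over all 20 assignments
  expect_equal(mw$p_two_sided, 2 / 20)

  # identical groups: all ties, two-sided p = 1
  tie <- cardioregion:::.mann_whitney(rep(2, 4), rep(2, 4))
  expect_equal(tie$p_two_sided, 1)

  # agreement with the standard exact test on untied data
  set.seed(12)
  for (i in 1:20) {
    x <- sample(1:1000, 7); y <- sample(1001:2000, 6) - sample(500, 1)
    if (anyDuplicated(c(x, y))) next
    mw <- cardioregion:::.mann_whitney(x, y)
    wt <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(mw$p_two_sided, wt$p.value, tolerance = 1e-12)
  }

  # label swap leaves the two-sided p unchanged
  a <- c(0.1, 0.5, 0.3, 0.9); b <- c(0.2, 0.8, 0.7)
  expect_equal(cardioregion:::.mann_whitney(a, b)$p_two_sided,
               cardioregion:::.mann_whitney(b, a)$p_two_sided)
})

test_that("compare_proportions wires groups and errors correctly", {
  props <- matrix(c(0.7, 0.75, 0.72, 0.4, 0.42, 0.38,
                    0.3, 0.25, 0.28, 0.6, 0.58, 0.62), 6, 2,
                  dimnames = list(sprintf("s%d", 1:6),
                                  c("Cardiomyocytes", "Fibroblasts")))
  meta <- data.frame(sample_id = sprintf("s%d", 1:6),
                     disease = rep(c("NF", "HFrEF"), each = 3))
  out <- compare_proportions(props, meta, "Cardiomyocytes")
  expect_equal(out$U, 9)
  expect_equal(out$p_two_sided, 0.1)   # exact 3v3, complete separation
  expect_error(compare_proportions(props, meta, "Unknown"), "cell type")
  meta$disease[1] <- "other"
  expect_error(compare_proportions(props, meta, "Fibroblasts"),
               "two groups")
})
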