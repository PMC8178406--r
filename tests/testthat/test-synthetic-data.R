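test_that("all four generators are deterministic under a fixed seed", {
  spec <- bulk_sim_spec(n_genes = 50, donors_per_group = 3, seed = 11)
  b1 <- simulate_bulk(spec)
  b2 <- simulate_bulk(spec)
  expect_identical(b1, b2)
  b3 <- simulate_bulk(bulk_sim_spec(n_genes = 50, donors_per_group = 3,
                                    seed = 12))
  expect_false(identical(b1$counts, b3$counts))

  p1 <- simulate_tissue_panel(30, planted_heart_genes = 1:3, seed = 5)
  expect_identical(p1, simulate_tissue_panel(30, planted_heart_genes = 1:3,
                                             seed = 5))

  r1 <- simulate_reference(3, 10, 100, seed = 5)
  r2 <- simulate_reference(3, 10, 100, seed = 5)
  expect_identical(r1, r2)

  m1 <- simulate_mixtures(r1, c(0.5, 0.3, 0.2), noise_sd = 0.1, seed = 9)
  m2 <- simulate_mixtures(r1, c(0.5, 0.3, 0.2), noise_sd = 0.1, seed = 9)
  expect_identical(m1, m2)
})

test_that("a null design carries no enrichment truth", {
  b <- simulate_bulk(bulk_sim_spec(n_genes = 30, donors_per_group = 2,
                                   seed = 2))
  expect_true(all(b$truth$label == "none"))
  expect_true(all(b$truth$effect_matrix == 0))
})

test_that("NB moments: Poisson limit and the planted-effect mean ratio", {
  # dispersion -> 0 with fixed mean: across-sample variance approaches the
  # mean (single gene, one group, many donors, depth variation off)
  spec <- bulk_sim_spec(n_genes = 1, chambers = "LA", diseases = "NF",
                        donors_per_group = 10000, baseline_mean = 50,
                        dispersion = 1e-9, gene_lengths = 1000,
                        depth_sdlog = 0, seed = 33)
  y <- as.numeric(simulate_bulk(spec)$counts)
  expect_equal(mean(y), 50, tolerance = 0.02)
  expect_equal(var(y) / mean(y), 1, tolerance = 0.05)

  # +2 log2 effect in LV only: empirical LV mean ~ 4x the other chambers
  spec <- bulk_sim_spec(n_genes = 1, donors_per_group = 200,
                        baseline_mean = 100, dispersion = 0.05,
                        planted_effects = data.frame(
                          gene = 1, chambers = "LV", diseases = "*",
                          log2fc = 2),
                        gene_lengths = 1000, seed = 44)
  b <- simulate_bulk(spec)
  depth <- b$truth$depth_factors
  adj <- b$counts[1, ] / depth[colnames(b$counts)]
  lv <- mean(adj[b$metadata$chamber == "LV"])
  rest <- mean(adj[b$metadata$chamber != "LV"])
  expect_equal(lv / rest, 4, tolerance = 0.05)
})

test_that("bulk spec validation names the offending field", {
  expect_error(bulk_sim_spec(dispersion = 0), "dispersion")
  expect_error(bulk_sim_spec(baseline_mean = -1), "baseline_mean")
  expect_error(bulk_sim_spec(n_genes = 10, planted_effects = data.frame(
    gene = 11, chambers = "LV", diseases = "*", log2fc = 1)),
    "planted_effects")
  expect_error(bulk_sim_spec(planted_effects = data.frame(
    gene = 1, chambers = "XX", diseases = "*", log2fc = 1)),
    "chamber")
})

test_that("tissue panel construction guarantees exact recovery", {
  # single planted gene: the downstream caller flags exactly that gene
  p <- simulate_tissue_panel(20, n_tissues = 30, planted_heart_genes = 1,
                             seed = 3)
  called <- call_heart_enriched(p$panel)
  expect_identical(unname(which(called)), 1L)

  # empty plant: zero calls
  p0 <- simulate_tissue_panel(50, n_tissues = 30, seed = 4)
  expect_equal(sum(call_heart_enriched(p0$panel)), 0)

  # 1,000 genes, 50 planted: re-applying the printed rule gives perfect
  # sensitivity and specificity on the noiseless construction
  planted <- seq(10, 500, by = 10)
  p <- simulate_tissue_panel(1000, n_tissues = 30,
                             planted_heart_genes = planted, seed = 7)
  called <- call_heart_enriched(p$panel, top_k = 3, min_fpkm = 1)
  expect_identical(unname(called), p$heart_enriched)

  expect_error(simulate_tissue_panel(10, n_tissues = 3), "n_tissues")
})

test_that("single-cell reference has disjoint markers and full-rank means", {
  r <- simulate_reference(n_cell_types = 2, cells_per_type = 20,
                          n_genes = 200, seed = 6)
  m <- sapply(split(seq_along(r$labels), r$labels), function(ix)
    Matrix::rowMeans(r$counts[, ix, drop = FALSE]))
  cosine <- sum(m[, 1] * m[, 2]) / sqrt(sum(m[, 1]^2) * sum(m[, 2]^2))
  expect_lt(cosine, 1 - 1e-4)
  expect_true(length(intersect(r$markers[[1]], r$markers[[2]])) == 0)

  r7 <- simulate_reference(7, 30, 500, seed = 8)
  sig <- build_signature(r7$counts, r7$labels, min_cells_per_type = 10)
  expect_equal(qr(sig)$rank, 7)

  expect_error(simulate_reference(5, 10, 100, marker_fraction = 0.01),
               "marker_fraction")
})

test_that("mixtures hit the expected linear structure", {
  r <- simulate_reference(3, 15, 150, seed = 10)
  M <- cardioregion:::.reference_type_means(r$counts, r$labels)

  # pure sample: bulk proportional to that type's mean profile
  m1 <- simulate_mixtures(r, c(1, 0, 0), depth = 1e5, noise_sd = 0)
  expect_equal(cor(m1$bulk[, 1], M[, 1]), 1, tolerance = 1e-12)

  # uniform mixture equals the arithmetic mean of type means up to scale
  mu <- simulate_mixtures(r, rep(1 / 3, 3), depth = 1e5, noise_sd = 0)
  expect_equal(cor(mu$bulk[, 1], rowMeans(M)), 1, tolerance = 1e-12)

  expect_error(simulate_mixtures(r, c(-0.1, 0.6, 0.5)), "non-negative")
  expect_error(simulate_mixtures(r, c(0.5, 0.2, 0.2)), "sum to 1")
})
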