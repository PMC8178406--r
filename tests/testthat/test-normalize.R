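test_that("counts_to_fpkm matches the formula and its invariances", {
  # one gene carrying a full library of 1e6 reads, length 1 kb
  counts <- matrix(1e6, 1, 1, dimnames = list("g1", "s1"))
  expect_equal(counts_to_fpkm(counts, c(g1 = 1000))[1, 1], 1e6)

  # zero counts map to zero regardless of length
  counts <- matrix(c(10, 0), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  expect_equal(counts_to_fpkm(counts, c(g1 = 100, g2 = 1))[2, 1], 0)

  # depth invariance: doubling every count of a sample changes nothing
  counts <- toy_counts(20, 4) + 1
  lens <- setNames(sample(200:2000, 20), rownames(counts))
  f1 <- counts_to_fpkm(counts, lens)
  doubled <- counts
  doubled[, 2] <- doubled[, 2] * 2
  expect_equal(counts_to_fpkm(doubled, lens), f1)
})

test_that("counts_to_fpkm rejects zero-total samples and bad lengths", {
  counts <- matrix(c(5, 0), 1, 2, dimnames = list("g1", c("good", "empty")))
  expect_error(counts_to_fpkm(counts, c(g1 = 100)), "empty")
  counts <- matrix(1, 1, 1, dimnames = list("g1", "s1"))
  expect_error(counts_to_fpkm(counts, c(g1 = 0)), "positive")
})

test_that("anchor_normalize puts the anchor percentile of nonzero values at 10", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(rlnorm(400, 1, 2), 100, 4,
                dimnames = list(sprintf("g%03d", 1:100), sprintf("s%d", 1:4)))
    x[sample(length(x), 120)] <- 0   # zeros must not enter the anchor
    xn <- anchor_normalize(x)
    p70 <- apply(xn, 2, function(v) quantile(v[v > 0], 0.7, type = 7))
    expect_equal(unname(p70), rep(10, 4), tolerance = 1e-12)
  }
})

test_that("anchor_normalize worked example, idempotence and equivariance", {
  x <- matrix(1:10, 10, 1, dimnames = list(sprintf("g%02d", 1:10), "s1"))
  xn <- anchor_normalize(x)
  # type-7 70th percentile of 1..10 is 7.3, so the smallest value maps there
  expect_equal(xn[1, 1], 10 / 7.3)

  # constant nonzero values all map to the anchor
  xc <- matrix(c(3, 3, 0, 3), 4, 1, dimnames = list(letters[1:4], "s1"))
  expect_equal(unname(anchor_normalize(xc)[, 1]), c(10, 10, 0, 10))

  # idempotent and invariant to per-sample rescaling
  y <- matrix(rlnorm(60), 20, 3,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%d", 1:3)))
  y1 <- anchor_normalize(y)
  expect_equal(anchor_normalize(y1), y1, tolerance = 1e-12)
  scaled <- sweep(y, 2, c(0.01, 1, 250), "*")
  expect_equal(anchor_normalize(scaled), y1, tolerance = 1e-12)

  z <- matrix(c(1, 0, 0, 2), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "dead")))
  z[, 2] <- 0
  expect_error(anchor_normalize(z), "all-zero")
})

test_that("expression_filter keeps genes at min_fpkm in enough samples", {
  # gene above threshold in exactly 4 of 84 samples is removed
  x <- matrix(0, 2, 84,
              dimnames = list(c("four", "five"), sprintf("s%02d", 1:84)))
  x["four", 1:4] <- 1.5
  x["five", 1:5] <- 1
  filt <- expression_filter(x, min_fpkm = 1, min_samples = 5)
  expect_identical(rownames(filt$expr), "five")

  # constructed 10-gene matrix: genes 1-7 pass in >= 5 samples, 8-10 fail
  y <- matrix(0, 10, 8,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:8)))
  y[1:7, 1:5] <- 2
  y[8, 1:4] <- 2
  y[10, ] <- 0.5
  filt <- expression_filter(y)
  expect_identical(filt$kept, 1:7)
  expect_identical(rownames(filt$expr), sprintf("g%02d", 1:7))

  # the all-zero gene is always removed
  expect_false(9L %in% filt$kept)
})

test_that("fpkm then anchoring is invariant to sequencing depth", {
  counts <- toy_counts(50, 3, seed = 3, mu = 100) + 1
  lens <- setNames(sample(500:5000, 50), rownames(counts))
  deeper <- sweep(counts, 2, c(1, 10, 100), "*")
  a <- anchor_normalize(counts_to_fpkm(counts, lens))
  b <- anchor_normalize(counts_to_fpkm(deeper, lens))
  expect_equal(a, b, tolerance = 1e-12)
})
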