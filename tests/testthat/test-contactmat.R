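test_that("balancing equalizes row sums and masks degenerate bins", {
  # symmetric 2x2: equal weights, equal row sums
  w <- balance_matrix(matrix(c(0, 2, 2, 0), 2, 2), min_nnz = 1)
  expect_equal(w[1], w[2])
  b <- balanced_matrix(matrix(c(0, 2, 2, 0), 2, 2), w)
  expect_equal(rowSums(b)[1], rowSums(b)[2], tolerance = 1e-9)

  # all-zero row is masked
  raw <- matrix(c(0, 0, 0, 0, 0, 3, 0, 3, 0), 3, 3)
  w <- balance_matrix(raw, min_nnz = 1)
  expect_true(is.na(w[1]))
  expect_true(all(!is.na(w[2:3])))

  # random matrices meet the 1e-5 relative-spread contract,
  # with mean unmasked balanced row sum scaled to 1
  set.seed(51)
  for (i in 1:5) {
    n <- 50
    raw <- matrix(stats::rpois(n * n, 5) * stats::runif(n * n), n, n)
    raw <- raw + t(raw)
    w <- balance_matrix(raw)
    b <- balanced_matrix(raw, w)
    s <- rowSums(b, na.rm = TRUE)[!is.na(w)]
    expect_lte((max(s) - min(s)) / mean(s), 1e-5)
    expect_equal(mean(s), 1, tolerance = 1e-6)
  }
  expect_error(balance_matrix(matrix(1:4, 2, 2)), "symmetric")
})

test_that("expected profile and OE normalize distance decay", {
  # Toeplitz matrix: every diagonal constant -> OE identically 1
  n <- 8
  b <- outer(1:n, 1:n, function(i, j) 10 / (1 + abs(i - j)))
  oe <- oe_matrix(b)
  expect_equal(oe, matrix(1, n, n), tolerance = 1e-12)

  # single nonzero pair at distance d: expected(d) = b / n_pairs(d)
  b2 <- matrix(0, 6, 6)
  b2[2, 4] <- b2[4, 2] <- 3
  ep <- expected_cis(b2)
  expect_equal(ep$expected[3], 3 / 4)     # distance 2 has 4 pairs
  oe2 <- oe_matrix(b2, ep)
  expect_equal(oe2[2, 4], 4)

  # per-diagonal OE means are 1 wherever there is data
  set.seed(61)
  raw <- matrix(stats::runif(400), 20, 20)
  raw <- raw + t(raw)
  oe3 <- oe_matrix(raw)
  for (d in 0:19) {
    i <- seq_len(20 - d)
    expect_equal(mean(oe3[cbind(i, i + d)]), 1, tolerance = 1e-9)
  }
})

test_that("PC1 separates planted blocks and obeys the orientation contract", {
  # two-block matrix with within-block enrichment
  n <- 20
  block <- rep(c(1, 2), each = n / 2)
  oe <- outer(block, block, function(a, b) ifelse(a == b, 2, 0.5)) +
    matrix(stats::rnorm(n * n, 0, 1e-3), n, n)
  oe <- (oe + t(oe)) / 2
  ref <- as.numeric(block == 2)   # "lamina" high in block 2
  pc1 <- compute_pc1(oe, ref, orient = "negative")
  expect_true(all(pc1[block == 1] > 0))
  expect_true(all(pc1[block == 2] < 0))
  # flipping the reference sign flips PC1
  pc1b <- compute_pc1(oe, -ref, orient = "negative")
  expect_equal(pc1b, -pc1)
  # positive orientation is the mirror contract
  pc1c <- compute_pc1(oe, ref, orient = "positive")
  expect_equal(pc1c, -pc1)
  expect_error(compute_pc1(oe[1:5, 1:5], ref[1:5]), "fewer than 10")

  expect_equal(compartments_from_pc1(c(0.5, -0.2, 0, NA)),
               c("A", "B", NA, NA))
})

test_that("A/B ratio is the log2 contrast of partner-class OE means", {
  n <- 6
  comp <- c("A", "A", "A", "B", "B", "B")
  oe <- matrix(1, n, n)
  expect_equal(unname(ab_ratio(oe, comp)), rep(0, n))
  oe[, 1:3] <- 2   # every bin sees A partners at twice the OE
  r <- ab_ratio(oe, comp)
  expect_equal(unname(r[5]), 1)   # log2(2/1), self-bin not in either mean
})

test_that("label interaction summaries match a direct per-pair oracle", {
  set.seed(71)
  n <- 20
  labels <- sample(c("p", "q"), n, replace = TRUE)
  oe <- matrix(stats::runif(n * n, 0.5, 2), n, n)
  oe <- (oe + t(oe)) / 2
  s <- label_interaction_summary(oe, labels)
  expect_true(all(is.finite(s$mean)))
  # oracle: per-bin mean log2 OE with each partner class, then average
  loe <- log2(oe)
  diag(loe) <- NA
  for (a in c("p", "q")) for (b in c("p", "q")) {
    per_bin <- sapply(which(labels == a), function(i)
      mean(loe[i, labels == b], na.rm = TRUE))
    expect_equal(s$mean[[a, b]], mean(per_bin), tolerance = 1e-12)
  }
  # constant OE of 1 -> all zero
  s1 <- label_interaction_summary(matrix(1, n, n), labels)
  expect_true(all(s1$mean == 0))
})

test_that("same-label affinity shows as diagonal dominance in summaries", {
  cfg <- sim_config(n_chroms = 1L, chrom_length = 5e6, n_contacts = 5e4)
  fx <- list(model = simulate_genome(cfg))
  fx$contacts <- filter_contacts(
    simulate_contacts(fx$model, cfg, "vehicle", 42L))$contacts
  bs <- fx$model$binspec
  raw <- contact_matrix(fx$contacts, bs, "chr1")
  oe <- oe_matrix(balanced_matrix(raw, balance_matrix(raw)))
  lab <- fx$model$labels[chrom_bins(bs, "chr1")]
  s <- label_interaction_summary(oe, lab)
  for (l in rownames(s$mean)) {
    others <- setdiff(colnames(s$mean), l)
    expect_true(all(s$mean[l, l] > s$mean[l, others]))
  }
})

test_that("saddle quantile budgets follow largest-remainder allocation", {
  n <- 200
  labels <- rep(c("a", "b", "c", "d"), each = n / 4)
  sig <- stats::rnorm(n)
  oe <- matrix(1, n, n)
  s <- saddle_by_signal(oe, labels, sig, n_quantiles = 100,
                        label_order = c("a", "b", "c", "d"))
  expect_equal(s$allocation, rep(25L, 4))
  expect_equal(sum(s$allocation), 100L)
  # constant OE -> all-zero saddle
  expect_true(all(s$matrix == 0, na.rm = TRUE))
  # every usable bin belongs to exactly one quantile
  expect_true(all(!is.na(s$assignment)))
  expect_equal(sort(unique(s$assignment)), 1:100)

  # uneven classes: allocation proportional, sums exactly to total
  labels2 <- rep(c("a", "b", "c", "d"), times = c(19, 10, 7, 4))
  s2 <- saddle_by_signal(matrix(1, 40, 40), labels2, stats::rnorm(40),
                         n_quantiles = 10,
                         label_order = c("a", "b", "c", "d"))
  expect_equal(sum(s2$allocation), 10L)
  expect_true(all(s2$allocation >= 1L))
  expect_equal(s2$allocation, c(5L, 2L, 2L, 1L))
})

test_that("saddles are equivariant under consistent bin permutation", {
  set.seed(81)
  n <- 60
  labels <- sample(c("a", "b", "c"), n, replace = TRUE)
  sig <- stats::rnorm(n)
  oe <- matrix(stats::runif(n * n, 0.5, 2), n, n)
  oe <- (oe + t(oe)) / 2
  s1 <- saddle_by_signal(oe, labels, sig, n_quantiles = 12,
                         label_order = c("a", "b", "c"))
  p <- sample(n)
  s2 <- saddle_by_signal(oe[p, p], labels[p], sig[p], n_quantiles = 12,
                         label_order = c("a", "b", "c"))
  expect_equal(s2$matrix, s1$matrix, tolerance = 1e-12)
  expect_equal(s2$mean_signal, s1$mean_signal, tolerance = 1e-12)

  d <- saddle_difference(s1, s2)
  expect_true(all(abs(d) < 1e-12, na.rm = TRUE))
  s3 <- saddle_by_signal(oe, labels, sig, n_quantiles = 11,
                         label_order = c("a", "b", "c"))
  expect_error(saddle_difference(s1, s3), "mismatched")
})
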