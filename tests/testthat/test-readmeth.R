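test_that("read ends classify by the inclusive context thresholds", {
  expect_equal(classify_read_end(10, 5, "CpG"), "METH")    # exactly 50%
  expect_equal(classify_read_end(10, 4, "CpG"), "UNMETH")
  expect_equal(classify_read_end(10, 1, "GpC"), "METH")    # exactly 10%
  expect_equal(classify_read_end(100, 9, "GpC"), "UNMETH")
  expect_equal(classify_read_end(0, 0, "GpC"), "UNCALLABLE")
  expect_error(classify_read_end(3, 5, "GpC"), "exceeds site count")
  expect_error(classify_read_end(3, 1, "XpX"), "context")
})

test_that("contact filtering drops trans, same-fragment, mapq-0 and close pairs", {
  base <- toy_two_bin_contacts()[1, ]
  cases <- rbind(
    base,                                             # kept
    transform(base, chrom2 = "chrU"),                 # trans
    transform(base, frag2 = base$frag1),              # same fragment
    transform(base, mapq = 0),                        # mapq
    transform(base, pos2 = base$pos1 + 500),          # too close
    transform(base, pos2 = base$pos1 + 1000))         # exactly 1 kb: kept
  f <- filter_contacts(cases)
  expect_equal(nrow(f$contacts), 2L)
  expect_equal(unname(f$dropped),
               c(1L, 1L, 1L, 1L))
  expect_equal(sum(f$dropped), nrow(cases) - nrow(f$contacts))
})

test_that("the two-bin worked example reproduces the displayed formulas", {
  bs <- toy_binspec()
  m <- build_cometh_matrices(toy_two_bin_contacts(), bs, "chrT", "GpC")
  Tm <- cometh_total(m)
  expect_equal(m$M[1, 2], 1L)
  expect_equal(m$Y[1, 2], 1L)
  expect_equal(m$Y[2, 1], 0L)
  expect_equal(m$U[1, 2], 1L)
  expect_equal(Tm[1, 2], 3L)
  A <- cometh_locus_methylation(m)
  expect_equal(A, c(2 / 3, 1 / 3))
  oe <- cometh_oe(m)
  expect_equal(oe[1, 2], 2 / 3 - ((2 / 3) * (1 / 3) + (1 / 3) * (2 / 3)))
  expect_equal(oe[1, 2], 2 / 9)
  O <- cometh_observed(m)
  expect_equal(O[1, 2], 2 / 3)
  expect_equal(O[2, 1], 1 / 3)
})

test_that("matrices match the naive per-contact oracle on simulated data", {
  fx <- small_sim()
  bs <- fx$model$binspec
  for (ctx in c("GpC", "CpG")) {
    m <- build_cometh_matrices(fx$contacts, bs, "chr1", ctx)
    ref <- naive_cometh(fx$contacts, bs, "chr1", ctx)
    expect_identical(unname(m$M), unname(ref$M))
    expect_identical(unname(m$U), unname(ref$U))
    expect_identical(unname(m$Y), unname(ref$Y))
    expect_identical(m$n_callable, ref$n_callable)
    # conservation: T = M + Y + Y' + U, exactly, and accounts for every
    # callable contact
    Tm <- cometh_total(m)
    expect_identical(Tm, m$M + m$Y + t(m$Y) + m$U)
    expect_true(isSymmetric(Tm))
    expect_equal((sum(Tm) + sum(diag(m$M)) + sum(diag(m$U))) / 2,
                 m$n_callable)
    # bounds
    A <- cometh_locus_methylation(m)
    expect_true(all(A >= 0 & A <= 1, na.rm = TRUE))
    O <- cometh_observed(m)
    expect_true(all(O >= 0 & O <= 1, na.rm = TRUE))
  }
})

test_that("uncallable ends exclude the contact and are counted", {
  cc <- toy_two_bin_contacts()
  cc$n_gpc1[2] <- 0
  cc$n_gpc_meth1[2] <- 0
  m <- build_cometh_matrices(cc, toy_binspec(), "chrT", "GpC")
  expect_equal(m$n_callable, 2L)
  expect_equal(m$n_uncallable, 1L)
  expect_equal(m$Y[1, 2], 0L)  # the (M,U) contact was the uncallable one
  # a bin with no callable partners has undefined A
  m0 <- build_cometh_matrices(cc[0, ], toy_binspec(), "chrT", "GpC")
  expect_true(all(m0$M == 0 & m0$U == 0 & m0$Y == 0))
  expect_true(all(is.na(cometh_locus_methylation(m0))))
})

test_that("min-max normalization anchors compartment means to 0 and 1", {
  set.seed(21)
  n <- 40
  comp <- rep(c("A", "B"), each = n / 2)
  O <- matrix(stats::runif(n * n), n, n)
  On <- minmax_normalize_observed(O, comp, "GpC")
  m_A <- mean(O[comp == "A", ])
  m_B <- mean(O[comp == "B", ])
  expect_equal(mean(On[comp == "A", ]), 0, tolerance = 1e-12)
  expect_equal(mean(On[comp == "B", ]), 1, tolerance = 1e-12)
  # for CpG the anchors swap
  On_c <- minmax_normalize_observed(O, comp, "CpG")
  expect_equal(mean(On_c[comp == "B", ]), 0, tolerance = 1e-12)
  expect_equal(mean(On_c[comp == "A", ]), 1, tolerance = 1e-12)
  # affine invariance
  On2 <- minmax_normalize_observed(0.3 * O + 5, comp, "GpC")
  expect_equal(On2, On, tolerance = 1e-9)
  expect_error(minmax_normalize_observed(matrix(0.5, n, n), comp, "GpC"),
               "degenerate dynamic range")
})

test_that("partner summaries average matrix entries by label pair", {
  labels <- c("x", "x", "y", "y")
  O <- matrix(7, 4, 4)
  s <- partner_conditional_summary(O, labels)
  expect_true(all(s$mean == 7))
  expect_equal(s$n[["x", "y"]], 4)

  # independent oracle: enumerate entries from the naive matrices
  fx <- small_sim()
  bs <- fx$model$binspec
  cc <- fx$contacts[seq_len(1000), ]
  m <- build_cometh_matrices(cc, bs, "chr1", "GpC")
  O <- cometh_observed(m)
  lab <- fx$model$labels[chrom_bins(bs, "chr1")]
  s <- partner_conditional_summary(O, lab)
  ref <- naive_cometh(cc, bs, "chr1", "GpC")
  Tn <- ref$M + ref$Y + t(ref$Y) + ref$U
  On <- (ref$M + ref$Y) / Tn
  for (l1 in rownames(s$mean)) for (l2 in colnames(s$mean)) {
    v <- On[lab == l1, lab == l2]
    v <- v[!is.na(v)]
    if (length(v)) expect_equal(s$mean[[l1, l2]], mean(v), tolerance = 1e-12)
  }
})

test_that("locus partner log ratios behave like log2 of partner means", {
  O <- rbind(c(NA, 0.4, 0.2), c(0.3, NA, 0.3), c(0.1, 0.5, NA))
  labels <- c("self", "B", "A")
  r <- locus_partner_log_ratio(O, labels, "B", "A")
  expect_equal(r[1], 1)           # 0.4 vs 0.2
  # bin 3's only A partner is itself (undefined) -> NA
  expect_true(is.na(r[3]))
  # equal partner means -> 0
  r2 <- locus_partner_log_ratio(matrix(0.4, 3, 3), labels, "B", "A")
  expect_equal(unname(r2), rep(0, 3))
  # zero denominator mean -> NA
  O[1, 3] <- 0
  expect_true(is.na(locus_partner_log_ratio(O, labels, "B", "A")[1]))
})

test_that("methylation fraction tracks pool end counts per bin", {
  bs <- toy_binspec()
  cc <- toy_two_bin_contacts()
  tr <- methylation_fraction_track(cc, bs, "GpC")
  # bin 1 ends: meth 10+10+0 of 30; bin 2 ends: 10+0+0 of 30
  expect_equal(track_values(tr), c(20 / 30, 10 / 30))
  # excluding bin-1 positions masks bin 1
  excl <- region_set("chrT", 0, 5000)
  tr2 <- methylation_fraction_track(cc, bs, "GpC", exclude = excl,
                                    pad_bp = 0)
  expect_true(is.na(track_values(tr2)[1]))
  expect_equal(track_values(tr2)[2], 10 / 30)
})
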