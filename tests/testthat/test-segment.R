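test_that("k-means recovers planted archetypes with the naming rule", {
  model <- simulate_genome(sim_config())
  ft <- simulate_subcompartment_features(model, noise_sd = 0.5, seed = 5L)
  call <- kmeans_subcompartments(ft$gpc_z, ft$cpg_z, ft$pc1_z, seed = 7L)
  core <- call$labels %in% c("Core-A", "PcG-A", "PcG-B", "Core-B")
  ari <- adjusted_rand(call$labels[core], model$labels[core])
  expect_gte(ari, 0.95)
  # naming: the dominant truth label of each called class is itself
  for (l in c("Core-A", "PcG-A", "PcG-B", "Core-B")) {
    tab <- table(model$labels[call$labels == l])
    expect_equal(names(which.max(tab)), l)
  }
  # centroid geometry follows the naming rule
  cent <- call$centroids
  expect_true(all(cent[c("Core-A", "PcG-A"), "pc1_z"] >
                    cent[c("PcG-B", "Core-B"), "pc1_z"]))
  expect_gt(cent["Core-A", "cpg_z"], cent["PcG-A", "cpg_z"])
  expect_gt(cent["Core-B", "gpc_z"], cent["PcG-B", "gpc_z"])
})

test_that("extreme-z bins are excluded and clustering ignores bin order", {
  model <- simulate_genome(sim_config())
  ft <- simulate_subcompartment_features(model, noise_sd = 0.5, seed = 5L)
  v <- track_values(ft$gpc_z)
  v[10] <- 3.5
  ft$gpc_z <- binned_track(model$binspec, v)
  call <- kmeans_subcompartments(ft$gpc_z, ft$cpg_z, ft$pc1_z, seed = 7L)
  expect_equal(call$labels[10], "excluded")

  # permuting bins permutes the labels identically
  bs <- model$binspec
  set.seed(3)
  p <- sample(bs$total_bins)
  permute <- function(tr) binned_track(bs, track_values(tr)[p])
  call_p <- kmeans_subcompartments(permute(ft$gpc_z), permute(ft$cpg_z),
                                   permute(ft$pc1_z), seed = 7L)
  expect_identical(call_p$labels, call$labels[p])
  expect_equal(call_p$centroids, call$centroids)
})

test_that("LAD calling keeps threshold runs of at least min_bins", {
  bs <- binspec(c(chr1 = 400000), 50000)
  z <- binned_track(bs, c(-1, 0.2, 0.3, 0.4, -1, 0.5, 0.6, -1))
  lads <- call_lads(z)
  expect_equal(nrow(lads), 1L)        # the 2-bin run is removed
  expect_equal(lads$start, 50000)
  expect_equal(lads$end, 200000)
  expect_equal(lads$score, mean(c(0.2, 0.3, 0.4)))

  expect_equal(nrow(call_lads(binned_track(bs, rep(-1, 8)))), 0L)
  # z exactly 0 is not attachment; masked bins terminate runs
  z2 <- binned_track(bs, c(1, 0, 1, 1, NA, 1, 1, 1))
  lads2 <- call_lads(z2)
  expect_equal(lads2$start, 250000)
  expect_equal(lads2$end, 400000)
  # output never overlaps and respects the minimum length
  expect_true(all(lads2$end - lads2$start >= 3 * 50000))
})

test_that("consensus keeps positions covered by enough replicates", {
  mk <- function(...) region_set("chr1", c(...)[c(TRUE, FALSE)],
                                 c(...)[c(FALSE, TRUE)])
  a <- mk(0, 300)
  b <- mk(100, 400)
  c3 <- mk(200, 500)
  cons <- consensus_regions(list(a, b, c3), min_support = 2)
  expect_equal(cons$start, 100)
  expect_equal(cons$end, 400)

  # base-pair coverage oracle on random staggered sets
  set.seed(91)
  for (i in 1:5) {
    sets <- lapply(1:3, function(k) {
      s <- sort(sample(0:80, 6)) * 10
      region_set("chr1", s, s + sample(1:15, 6) * 10)
    })
    cons <- consensus_regions(sets, min_support = 2)
    cov <- rep(0L, 1200)
    for (st in sets) {
      m <- rep(FALSE, 1200)
      for (r in seq_len(nrow(st)))
        m[(st$start[r] + 1):st$end[r]] <- TRUE
      cov <- cov + m
    }
    expect_covered <- which(cov >= 2) - 1L
    got <- unlist(lapply(seq_len(nrow(cons)), function(r)
      cons$start[r]:(cons$end[r] - 1L)))
    expect_identical(sort(got), expect_covered)
    # monotone: raising support never adds bases
    cons3 <- consensus_regions(sets, min_support = 3)
    expect_lte(sum(cons3$end - cons3$start), sum(cons$end - cons$start))
  }

  # presence in only one replicate is dropped; the length filter re-applies
  single <- consensus_regions(list(a, mk(900, 1200), mk(2000, 2300)),
                              min_support = 2)
  expect_equal(nrow(single), 0L)
  short <- consensus_regions(list(mk(0, 100), mk(50, 160)), min_support = 2,
                             min_len_bp = 100)
  expect_equal(nrow(short), 0L)
  expect_error(consensus_regions(list(a), min_support = 2), "exceeds")
})

test_that("differential regions use the per-bin Welch t-statistic", {
  bs <- binspec(c(chr1 = 400000), 50000)
  mk <- function(v) binned_track(bs, rep(v, 8))
  treat <- lapply(c(2.0, 2.1, 1.9), mk)
  veh <- lapply(c(0.0, 0.1, -0.1), mk)
  dr <- call_differential_regions(treat, veh, t_threshold = 4)
  t_by_hand <- 2 / sqrt(0.01 / 3 + 0.01 / 3)
  expect_equal(t_by_hand, 24.49, tolerance = 1e-3)
  expect_equal(unname(attr(dr, "t")[1]), t_by_hand)
  expect_equal(nrow(dr), 1L)
  expect_equal(dr$label, "gain")
  expect_equal(dr$start, 0)
  expect_equal(dr$end, 400000)

  # identical groups -> empty
  expect_equal(nrow(call_differential_regions(treat, treat, 4)), 0L)

  # antisymmetry: swapping groups swaps gain and loss coordinates
  model <- simulate_genome(sim_config())
  planted <- model$labels == "PcG-B"
  tm <- simulate_planted_tracks(model$binspec, planted, 2, 0.3, seeds = 1:3)
  vm <- simulate_planted_tracks(model$binspec, planted, 0, 0.3, seeds = 4:6)
  d1 <- call_differential_regions(tm, vm, 4)
  d2 <- call_differential_regions(vm, tm, 4)
  g1 <- as.data.frame(d1)[d1$label == "gain", c("chrom", "start", "end")]
  l2 <- as.data.frame(d2)[d2$label == "loss", c("chrom", "start", "end")]
  rownames(g1) <- rownames(l2) <- NULL
  expect_equal(g1, l2)
  expect_equal(attr(d1, "t"), -attr(d2, "t"))
})

test_that("overlap statistics count intersected bases", {
  a <- region_set("chr1", 0, 100)
  b <- region_set("chr1", 50, 150)
  s <- overlap_stats(a, b)
  expect_equal(s$bp_overlap, 50)
  expect_equal(s$jaccard, 1 / 3)
  expect_equal(overlap_stats(a, a)$jaccard, 1)
  expect_equal(overlap_stats(a, region_set("chr1", 500, 600))$jaccard, 0)
  lab <- region_set(c("chr1", "chr1"), c(0, 200), c(100, 300),
                    label = c("x", "y"))
  s2 <- overlap_stats(lab, b)
  expect_equal(unname(s2$per_label["x"]), 50)
  expect_equal(unname(s2$per_label["y"]), 0)
})
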