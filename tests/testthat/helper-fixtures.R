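# Shared fixtures and independent oracles used across the suite.

# Three contacts between two 50 kb bins with end states (M,M), (M,U), (U,U)
# in both contexts: the worked formula example.
toy_two_bin_contacts <- function() {
  data.frame(
    chrom1 = "chrT", pos1 = c(10, 10, 10), strand1 = "+",
    frag1 = c(1, 3, 5),
    chrom2 = "chrT", pos2 = c(60000, 60000, 60000), strand2 = "-",
    frag2 = c(2, 4, 6), mapq = 30,
    n_cpg1 = 10, n_cpg_meth1 = c(10, 10, 0),
    n_gpc1 = 10, n_gpc_meth1 = c(10, 10, 0),
    n_cpg2 = 10, n_cpg_meth2 = c(10, 0, 0),
    n_gpc2 = 10, n_gpc_meth2 = c(10, 0, 0),
    stringsAsFactors = FALSE)
}

toy_binspec <- function() binspec(c(chrT = 100000), 50000)

# Independent per-contact enumeration of the methylation-stratified
# matrices: a plain loop with explicit state logic, no shared code with
# build_cometh_matrices.
naive_cometh <- function(contacts, bs, chrom, context) {
  df <- as.data.frame(contacts)
  df <- df[df$chrom1 == chrom & df$chrom2 == chrom, , drop = FALSE]
  n <- bs$n_bins[[chrom]]
  M <- U <- Y <- matrix(0L, n, n)
  thr <- if (tolower(context) == "cpg") 0.5 else 0.1
  ctx <- tolower(context)
  state <- function(nn, kk) {
    if (nn == 0) return(NA)
    kk / nn >= thr
  }
  n_call <- 0L
  for (r in seq_len(nrow(df))) {
    s1 <- state(df[[paste0("n_", ctx, "1")]][r],
                df[[paste0("n_", ctx, "_meth1")]][r])
    s2 <- state(df[[paste0("n_", ctx, "2")]][r],
                df[[paste0("n_", ctx, "_meth2")]][r])
    if (is.na(s1) || is.na(s2)) next
    n_call <- n_call + 1L
    i <- floor(df$pos1[r] / bs$bin_width) + 1
    j <- floor(df$pos2[r] / bs$bin_width) + 1
    if (s1 && s2) {
      M[i, j] <- M[i, j] + 1L
      if (i != j) M[j, i] <- M[j, i] + 1L
    } else if (!s1 && !s2) {
      U[i, j] <- U[i, j] + 1L
      if (i != j) U[j, i] <- U[j, i] + 1L
    } else if (s1 && !s2) {
      Y[i, j] <- Y[i, j] + 1L
    } else {
      Y[j, i] <- Y[j, i] + 1L
    }
  }
  list(M = M, U = U, Y = Y, n_callable = n_call)
}

# Adjusted Rand index between two label vectors (closed form from the
# pair-counting contingency table).
adjusted_rand <- function(x, y) {
  tab <- table(x, y)
  ch2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- ch2(as.vector(tab))
  a <- ch2(rowSums(tab))
  b <- ch2(colSums(tab))
  n <- ch2(sum(tab))
  exp_idx <- a * b / n
  (sum_ij - exp_idx) / ((a + b) / 2 - exp_idx)
}

# Fraction of bins covered by regions, as a per-bin logical vector.
regions_to_bin_mask <- function(regions, bs) {
  bc <- bin_coords(bs)
  out <- rep(FALSE, bs$total_bins)
  df <- as.data.frame(regions)
  for (i in seq_len(nrow(df))) {
    gb <- chrom_bins(bs, df$chrom[i])
    out[gb[bc$start[gb] >= df$start[i] & bc$end[gb] <= df$end[i]]] <- TRUE
  }
  out
}

# Small simulated dataset reused by several files.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_chroms = 1L, chrom_length = 5e6, n_contacts = 2e4)
      model <- simulate_genome(cfg)
      contacts <- filter_contacts(
        simulate_contacts(model, cfg, "vehicle", 42L))$contacts
      cache <<- list(cfg = cfg, model = model, contacts = contacts)
    }
    cache
  }
})
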