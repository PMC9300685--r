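#' Classify a read end's methylation state
#'
#' A read end is methylated for a context when the fraction of its
#' informative sites that are methylated reaches the context threshold:
#' 50% for CpG (endogenous methylation), 10% for GpC (the exogenous lamina
#' mark, which is sparser). Thresholds are inclusive. Ends with zero
#' informative sites are UNCALLABLE.
#'
#' @param n_sites,n_meth non-negative integer vectors (recycled),
#'   `n_meth <= n_sites`.
#' @param context `"CpG"` or `"GpC"` (case-insensitive).
#' @return character vector in `{"METH", "UNMETH", "UNCALLABLE"}`.
#' @export
classify_read_end <- function(n_sites, n_meth, context) {
  thr <- meth_threshold(context)
  if (any(n_meth > n_sites)) stop("meth count exceeds site count")
  if (any(n_sites < 0 | n_meth < 0)) stop("negative counts")
  out <- rep("UNCALLABLE", length(n_sites))
  has <- n_sites > 0
  out[has] <- ifelse(n_meth[has] / n_sites[has] >= thr, "METH", "UNMETH")
  out
}

meth_threshold <- function(context) {
  switch(tolower(context), cpg = 0.5, gpc = 0.1,
         stop("context must be 'CpG' or 'GpC'"))
}

#' Filter contacts for co-methylation analysis
#'
#' Keeps intra-chromosomal contacts between different restriction fragments
#' with MAPQ > 0 whose ends map at least `min_distance` bp apart (close
#' pairs are biased by directly neighbouring fragments). Each dropped
#' contact is tallied under the first matching reason, in the order trans,
#' fragment, mapq, distance.
#'
#' @param contacts a `tagged_contacts` data.frame.
#' @param min_distance minimum end separation in bp (default 1000; a pair
#'   exactly at `min_distance` is kept).
#' @return list with `contacts` (the retained rows) and `dropped`, a named
#'   count per rejection reason.
#' @export
filter_contacts <- function(contacts, min_distance = 1000) {
  df <- as.data.frame(contacts)
  reason <- rep(NA_character_, nrow(df))
  trans <- df$chrom1 != df$chrom2
  reason[trans] <- "trans"
  frag <- is.na(reason) & df$frag1 == df$frag2
  reason[frag] <- "fragment"
  mapq <- is.na(reason) & df$mapq <= 0
  reason[mapq] <- "mapq"
  near <- is.na(reason) & abs(df$pos1 - df$pos2) < min_distance
  reason[near] <- "distance"
  keep <- is.na(reason)
  dropped <- c(trans = sum(reason == "trans", na.rm = TRUE),
               fragment = sum(reason == "fragment", na.rm = TRUE),
               mapq = sum(reason == "mapq", na.rm = TRUE),
               distance = sum(reason == "distance", na.rm = TRUE))
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tagged_contacts", "data.frame")
  list(contacts = out, dropped = dropped)
}

#' Methylation-stratified contact matrices for one chromosome
#'
#' Each filtered contact whose two ends are both callable for the context
#' is assigned, by the per-end methylation state, to one of three binned
#' count matrices: M (both ends methylated), U (both unmethylated), or the
#' asymmetric Y, where `Y[i, j]` counts contacts whose end in bin i is
#' methylated and whose end in bin j is not. M and U are symmetrized;
#' contacts with an uncallable end are excluded and counted.
#'
#' @param contacts filtered `tagged_contacts` (single chromosome expected;
#'   rows on other chromosomes raise an error).
#' @param bs a [binspec].
#' @param chrom chromosome to build matrices for.
#' @param context `"CpG"` or `"GpC"`.
#' @return object of class `cometh_matrices`: `M`, `U`, `Y` (n x n),
#'   `binspec`, `chrom`, `context`, `n_callable`, `n_uncallable`.
#' @export
build_cometh_matrices <- function(contacts, bs, chrom, context) {
  stopifnot(inherits(bs, "binspec"), chrom %in% names(bs$chrom_sizes))
  df <- as.data.frame(contacts)
  df <- df[df$chrom1 == chrom & df$chrom2 == chrom, , drop = FALSE]
  n <- bs$n_bins[[chrom]]
  M <- U <- Y <- matrix(0L, n, n)
  n_unc <- 0L
  if (nrow(df)) {
    ctx <- tolower(context)
    s1 <- classify_read_end(df[[paste0("n_", ctx, "1")]],
                            df[[paste0("n_", ctx, "_meth1")]], context)
    s2 <- classify_read_end(df[[paste0("n_", ctx, "2")]],
                            df[[paste0("n_", ctx, "_meth2")]], context)
    callable <- s1 != "UNCALLABLE" & s2 != "UNCALLABLE"
    n_unc <- sum(!callable)
    df <- df[callable, , drop = FALSE]
    s1 <- s1[callable]; s2 <- s2[callable]
    b1 <- floor(df$pos1 / bs$bin_width) + 1L
    b2 <- floor(df$pos2 / bs$bin_width) + 1L
    if (any(b1 > n | b2 > n)) stop("bin index out of range")
    inc <- function(mat, i, j) {
      # accumulate duplicated (i,j) pairs
      idx <- (j - 1L) * n + i
      t <- tabulate(idx, nbins = n * n)
      mat + matrix(t, n, n)
    }
    mm <- s1 == "METH" & s2 == "METH"
    uu <- s1 == "UNMETH" & s2 == "UNMETH"
    mu <- s1 == "METH" & s2 == "UNMETH"
    um <- s1 == "UNMETH" & s2 == "METH"
    if (any(mm)) {
      M <- inc(M, b1[mm], b2[mm])
      off <- mm & b1 != b2
      if (any(off)) M <- inc(M, b2[off], b1[off])
    }
    if (any(uu)) {
      U <- inc(U, b1[uu], b2[uu])
      off <- uu & b1 != b2
      if (any(off)) U <- inc(U, b2[off], b1[off])
    }
    if (any(mu)) Y <- inc(Y, b1[mu], b2[mu])
    if (any(um)) Y <- inc(Y, b2[um], b1[um])
  }
  structure(list(binspec = bs, chrom = chrom, context = context,
                 M = M, U = U, Y = Y,
                 n_callable = if (nrow(df)) nrow(df) else 0L,
                 n_uncallable = n_unc),
            class = "cometh_matrices")
}

#' @export
print.cometh_matrices <- function(x, ...) {
  cat("cometh_matrices [", x$context, "] ", x$chrom, ": ",
      nrow(x$M), "x", ncol(x$M), " bins, ",
      x$n_callable, " callable contacts (", x$n_uncallable,
      " excluded uncallable)\n", sep = "")
  invisible(x)
}

#' Total contact matrix T
#'
#' `T[i,j] = M[i,j] + Y[i,j] + Y[j,i] + U[i,j]` — the callable contacts
#' between bins i and j regardless of methylation state; symmetric by
#' construction.
#'
#' @param mats a `cometh_matrices`.
#' @return integer matrix.
#' @export
cometh_total <- function(mats) {
  mats$M + mats$Y + t(mats$Y) + mats$U
}

#' Per-locus average methylation A
#'
#' `A[i]` is the mean, over partner bins j with `T[i,j] > 0`, of the
#' fraction of contacts with j whose i-side end is methylated,
#' `(M[i,j] + Y[i,j]) / T[i,j]`. Bins with no callable partners are NA.
#'
#' @param mats a `cometh_matrices`.
#' @return numeric vector in `[0, 1]` with NA for partnerless bins.
#' @export
cometh_locus_methylation <- function(mats) {
  Tm <- cometh_total(mats)
  frac <- (mats$M + mats$Y) / Tm
  frac[Tm == 0] <- NA_real_
  A <- rowMeans(frac, na.rm = TRUE)
  A[rowSums(Tm > 0) == 0] <- NA_real_
  A
}

#' Observed methylation matrix O
#'
#' `O[i,j] = (M[i,j] + Y[i,j]) / T[i,j]`: the fraction of contacts between
#' i and j in which the i-side read is methylated. Not symmetric. NA where
#' `T = 0`.
#'
#' @param mats a `cometh_matrices`.
#' @return numeric matrix in `[0, 1]`.
#' @export
cometh_observed <- function(mats) {
  Tm <- cometh_total(mats)
  O <- (mats$M + mats$Y) / Tm
  O[Tm == 0] <- NA_real_
  O
}

#' Observed-minus-expected co-methylation OE
#'
#' `OE[i,j] = (M[i,j] + U[i,j]) / T[i,j] - [A_i A_j + (1 - A_i)(1 - A_j)]`:
#' the observed concordance of the two ends' methylation states minus the
#' concordance expected if the ends' states were independent with their
#' locus-level methylation frequencies. Positive values mean contacting
#' reads share methylation status more often than chance.
#'
#' @param mats a `cometh_matrices`.
#' @param A optional precomputed [cometh_locus_methylation()] vector.
#' @return numeric matrix in `[-1, 1]`, NA where `T = 0` or A undefined.
#' @export
cometh_oe <- function(mats, A = cometh_locus_methylation(mats)) {
  Tm <- cometh_total(mats)
  obs <- (mats$M + mats$U) / Tm
  expd <- outer(A, A) + outer(1 - A, 1 - A)
  oe <- obs - expd
  oe[Tm == 0] <- NA_real_
  oe
}

#' Min-max normalize an observed methylation matrix
#'
#' Anchors the matrix to the per-sample compartment means so samples with
#' different dynamic range are comparable: for GpC, the mean of entries
#' whose row bin is in the A compartment maps to 0 and the B-compartment
#' mean maps to 1 (lamina methylation is low in A, high in B); for CpG the
#' anchors swap. Values are not clipped.
#'
#' @param O observed matrix from [cometh_observed()].
#' @param compartments per-row-bin compartment label, `"A"` or `"B"`
#'   (NA allowed).
#' @param context `"CpG"` or `"GpC"`.
#' @return numeric matrix.
#' @export
minmax_normalize_observed <- function(O, compartments, context) {
  stopifnot(length(compartments) == nrow(O))
  m_A <- mean(O[compartments %in% "A", ], na.rm = TRUE)
  m_B <- mean(O[compartments %in% "B", ], na.rm = TRUE)
  if (!is.finite(m_A) || !is.finite(m_B) || m_A == m_B)
    stop("degenerate dynamic range: compartment anchors are equal or undefined")
  lo <- if (tolower(context) == "gpc") m_A else m_B
  hi <- if (tolower(context) == "gpc") m_B else m_A
  (O - lo) / (hi - lo)
}

#' Mean observed methylation per (locus label, partner label) pair
#'
#' Averages matrix entries `[i, j]` grouped by the label of bin i (the
#' locus whose methylation O measures) and the label of partner bin j.
#'
#' @param O an observed (or normalized) methylation matrix.
#' @param labels per-bin labels (NA bins are skipped).
#' @param label_order optional ordering of the label axes.
#' @return list with `mean` (L x L matrix, rows = locus label, cols =
#'   partner label; NA where no entries) and `n` (entry counts).
#' @export
partner_conditional_summary <- function(O, labels,
                                        label_order = NULL) {
  stopifnot(length(labels) == nrow(O), nrow(O) == ncol(O))
  lv <- if (is.null(label_order)) sort(unique(labels[!is.na(labels)]))
        else label_order
  mean_m <- n_m <- matrix(NA_real_, length(lv), length(lv),
                          dimnames = list(lv, lv))
  ri <- match(labels, lv)
  ok <- !is.na(O) & !is.na(ri[row(O)]) & !is.na(ri[col(O)])
  if (any(ok)) {
    g1 <- ri[row(O)][ok]; g2 <- ri[col(O)][ok]; v <- O[ok]
    key <- (g1 - 1L) * length(lv) + g2
    s <- tapply(v, key, sum)
    cnt <- tapply(v, key, length)
    idx <- as.integer(names(s))
    mean_m[cbind((idx - 1L) %/% length(lv) + 1L,
                 (idx - 1L) %% length(lv) + 1L)] <- s / cnt
    n_m[cbind((idx - 1L) %/% length(lv) + 1L,
              (idx - 1L) %% length(lv) + 1L)] <- cnt
  }
  list(mean = mean_m, n = n_m)
}

#' Per-locus log2 ratio of partner-conditioned methylation
#'
#' For each bin i, the log2 ratio of its mean observed methylation when
#' contacting numerator-label bins versus denominator-label bins:
#' `r[i] = log2(mean_j-in-num O[i,j] / mean_j-in-den O[i,j])`. NA where
#' either mean is zero or undefined.
#'
#' @param O observed methylation matrix.
#' @param labels per-bin partner labels.
#' @param numerator_label,denominator_label label (or set of labels)
#'   defining the two partner classes.
#' @return numeric per-bin vector.
#' @export
locus_partner_log_ratio <- function(O, labels, numerator_label,
                                    denominator_label) {
  stopifnot(length(labels) == ncol(O))
  num_cols <- which(labels %in% numerator_label)
  den_cols <- which(labels %in% denominator_label)
  m_num <- rowMeans(O[, num_cols, drop = FALSE], na.rm = TRUE)
  m_den <- rowMeans(O[, den_cols, drop = FALSE], na.rm = TRUE)
  r <- log2(m_num / m_den)
  r[!is.finite(r)] <- NA_real_
  r
}

#' Per-bin methylation fraction track from contact read ends
#'
#' Pools both ends of every contact and computes, per bin, the fraction of
#' informative context sites that are methylated (site-level, weighted by
#' per-end site counts). Optionally removes ends falling inside padded
#' exclusion regions (e.g. CpG islands for the CpG context). Bins with no
#' sites are masked.
#'
#' @param contacts `tagged_contacts` (typically filtered).
#' @param bs a [binspec].
#' @param context `"CpG"` or `"GpC"`.
#' @param exclude optional [region_set] of exclusion regions.
#' @param pad_bp padding added to each exclusion region (default 2000).
#' @return a [binned_track] of fractions.
#' @export
methylation_fraction_track <- function(contacts, bs, context,
                                       exclude = NULL, pad_bp = 2000) {
  df <- as.data.frame(contacts)
  ctx <- tolower(context)
  ends <- data.frame(
    chrom = c(df$chrom1, df$chrom2),
    pos = c(df$pos1, df$pos2),
    n = c(df[[paste0("n_", ctx, "1")]], df[[paste0("n_", ctx, "2")]]),
    k = c(df[[paste0("n_", ctx, "_meth1")]], df[[paste0("n_", ctx, "_meth2")]]),
    stringsAsFactors = FALSE)
  if (!is.null(exclude) && nrow(as.data.frame(exclude)) > 0) {
    if (pad_bp < 0) stop("pad_bp must be non-negative")
    ex <- as.data.frame(exclude)
    exg <- GenomicRanges::GRanges(
      ex$chrom, IRanges::IRanges(pmax(0, ex$start - pad_bp) + 1L,
                                 ex$end + pad_bp))
    eg <- GenomicRanges::GRanges(ends$chrom,
                                 IRanges::IRanges(ends$pos + 1L, width = 1L))
    ends <- ends[!IRanges::overlapsAny(eg, exg), , drop = FALSE]
  }
  tot <- meth <- numeric(bs$total_bins)
  if (nrow(ends)) {
    idx <- bin_index(bs, ends$chrom, ends$pos)
    tot <- as.numeric(tapply(ends$n, factor(idx, levels = seq_len(bs$total_bins)),
                             sum, default = 0))
    meth <- as.numeric(tapply(ends$k, factor(idx, levels = seq_len(bs$total_bins)),
                              sum, default = 0))
  }
  mask <- tot == 0
  binned_track(bs, ifelse(mask, NA_real_, meth / tot), mask)
}
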