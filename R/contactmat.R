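#' Raw binned contact matrix for one chromosome
#'
#' Counts filtered contacts into a symmetric n x n bin matrix (off-diagonal
#' contacts increment both triangles; within-bin contacts increment the
#' diagonal once).
#'
#' @param contacts filtered `tagged_contacts`.
#' @param bs a [binspec].
#' @param chrom chromosome name.
#' @return symmetric numeric matrix.
#' @export
contact_matrix <- function(contacts, bs, chrom) {
  stopifnot(inherits(bs, "binspec"), chrom %in% names(bs$chrom_sizes))
  df <- as.data.frame(contacts)
  df <- df[df$chrom1 == chrom & df$chrom2 == chrom, , drop = FALSE]
  n <- bs$n_bins[[chrom]]
  mat <- matrix(0, n, n)
  if (nrow(df)) {
    b1 <- floor(df$pos1 / bs$bin_width) + 1L
    b2 <- floor(df$pos2 / bs$bin_width) + 1L
    idx <- (pmax(b1, b2) - 1L) * n + pmin(b1, b2)
    t <- tabulate(idx, nbins = n * n)
    lower <- matrix(t, n, n)
    mat <- lower + t(lower)
    diag(mat) <- diag(lower)
  }
  mat
}

#' Balance a contact matrix to equal row sums
#'
#' Iterative correction: finds positive per-bin weights `w` such that the
#' balanced matrix `b[i,j] = w_i w_j raw[i,j]` has equal row sums over
#' unmasked bins (relative spread at most `tol`), then scales the weights
#' so the mean unmasked balanced row sum is 1. Bins with fewer than
#' `min_nnz` nonzero entries are masked (weight NA).
#'
#' @param raw symmetric non-negative matrix.
#' @param max_iter iteration cap (default 200).
#' @param tol relative row-sum spread target (default 1e-5).
#' @param min_nnz minimum nonzero entries for a bin to be balanced
#'   (default 2).
#' @return numeric weight vector with NA at masked bins.
#' @export
balance_matrix <- function(raw, max_iter = 200L, tol = 1e-5, min_nnz = 2L) {
  if (!isTRUE(all.equal(raw, t(raw)))) stop("raw matrix must be symmetric")
  if (any(raw < 0)) stop("raw matrix must be non-negative")
  n <- nrow(raw)
  mask <- rowSums(raw > 0) < min_nnz
  keep <- which(!mask)
  if (length(keep) == 0L) stop("no bins left to balance")
  sub <- raw[keep, keep, drop = FALSE]
  x <- rep(1, length(keep))
  spread <- Inf
  for (it in seq_len(max_iter)) {
    s <- as.vector(sub %*% x) * x
    m <- mean(s)
    spread <- (max(s) - min(s)) / m
    if (spread <= tol) break
    x <- x / sqrt(s / m)
  }
  if (spread > tol)
    stop("balancing did not converge in ", max_iter,
         " iterations (row-sum spread ", format(spread, digits = 3), ")")
  s <- as.vector(sub %*% x) * x
  x <- x / sqrt(mean(s))
  w <- rep(NA_real_, n)
  w[keep] <- x
  w
}

#' Apply balancing weights
#' @param raw symmetric matrix.
#' @param weights from [balance_matrix()].
#' @return balanced matrix with NA rows/cols at masked bins.
#' @export
balanced_matrix <- function(raw, weights) {
  b <- raw * outer(weights, weights)
  b
}

#' Distance-decay expected profile (cis)
#'
#' Mean balanced contact value at each bin separation d, over pairs whose
#' two bins are both unmasked.
#'
#' @param b balanced matrix (NA at masked bins).
#' @return object of class `expected_profile`: `distance` (0-based bin
#'   separations), `expected`, `n_pairs`.
#' @export
expected_cis <- function(b) {
  n <- nrow(b)
  expected <- n_pairs <- numeric(n)
  for (d in 0:(n - 1L)) {
    i <- seq_len(n - d)
    v <- b[cbind(i, i + d)]
    v <- v[!is.na(v)]
    n_pairs[d + 1L] <- length(v)
    expected[d + 1L] <- if (length(v)) mean(v) else NA_real_
  }
  structure(list(distance = 0:(n - 1L), expected = expected,
                 n_pairs = n_pairs),
            class = "expected_profile")
}

#' Observed/expected matrix
#'
#' `OE[i,j] = b[i,j] / expected(|i-j|)`; NA where the expected value is
#' zero or undefined or a bin is masked.
#'
#' @param b balanced matrix.
#' @param expected an `expected_profile` (defaults to [expected_cis()] of
#'   `b`).
#' @return numeric matrix.
#' @export
oe_matrix <- function(b, expected = expected_cis(b)) {
  n <- nrow(b)
  d <- abs(row(b) - col(b))
  e <- matrix(expected$expected[d + 1L], n, n)
  oe <- b / e
  oe[!is.finite(oe)] <- NA_real_
  oe
}

#' Compartment score: first eigenvector of the OE correlation matrix
#'
#' Computes the Pearson correlation matrix of the OE columns over usable
#' bins, takes the eigenvector of the largest eigenvalue and orients its
#' arbitrary sign against a reference track: with
#' `orient = "negative"` (lamina GpC reference; B-compartment bins have
#' high lamina signal and negative PC1) the eigenvector is flipped if its
#' correlation with the reference is positive; `orient = "positive"` is
#' the converse (e.g. CpG methylation reference). One chromosome at a time.
#'
#' @param oe per-chromosome OE matrix.
#' @param reference numeric per-bin reference values (same length as
#'   `nrow(oe)`).
#' @param orient `"negative"` or `"positive"`.
#' @return numeric per-bin score vector, NA at masked/constant bins.
#' @export
compute_pc1 <- function(oe, reference, orient = c("negative", "positive")) {
  orient <- match.arg(orient)
  stopifnot(length(reference) == nrow(oe))
  usable <- which(colSums(is.finite(oe)) > 1)
  sds <- apply(oe[, usable, drop = FALSE], 2,
               function(v) stats::sd(v, na.rm = TRUE))
  usable <- usable[is.finite(sds) & sds > 0]
  if (length(usable) < 10L) stop("fewer than 10 usable bins")
  C <- stats::cor(oe[usable, usable, drop = FALSE],
                  use = "pairwise.complete.obs")
  C[!is.finite(C)] <- 0
  eg <- eigen(C, symmetric = TRUE)
  v <- eg$vectors[, 1L]
  r <- suppressWarnings(stats::cor(v, reference[usable],
                                   use = "complete.obs"))
  if (is.finite(r) && r != 0) {
    flip <- if (orient == "negative") r > 0 else r < 0
    if (flip) v <- -v
  }
  out <- rep(NA_real_, nrow(oe))
  out[usable] <- v
  out
}

#' Compartment assignment from a PC1 score
#' @param pc1 per-bin score.
#' @return character vector: `"A"` where `pc1 > 0`, `"B"` where
#'   `pc1 < 0`, NA at 0 or masked.
#' @export
compartments_from_pc1 <- function(pc1) {
  ifelse(is.na(pc1) | pc1 == 0, NA_character_, ifelse(pc1 > 0, "A", "B"))
}

#' A/B interaction ratio
#'
#' Per bin, `log2(mean OE with A-compartment partners) - log2(mean OE with
#' B-compartment partners)`, self-bin excluded. Positive values mean the
#' bin interacts preferentially with the A compartment.
#'
#' @param oe OE matrix.
#' @param compartments per-bin `"A"`/`"B"` labels.
#' @return numeric per-bin vector, NA where either class mean is undefined
#'   or zero.
#' @export
ab_ratio <- function(oe, compartments) {
  stopifnot(length(compartments) == nrow(oe))
  oe2 <- oe
  diag(oe2) <- NA_real_
  mA <- rowMeans(oe2[, compartments %in% "A", drop = FALSE], na.rm = TRUE)
  mB <- rowMeans(oe2[, compartments %in% "B", drop = FALSE], na.rm = TRUE)
  r <- log2(mA) - log2(mB)
  r[!is.finite(r)] <- NA_real_
  r
}

#' Mean log2 OE between label classes
#'
#' For each bin, the mean log2 OE with partners of each label; the summary
#' cell (own label, partner label) averages these per-bin values over bins
#' of the own label. Entries with non-positive or missing OE are skipped.
#'
#' @param oe OE matrix.
#' @param labels per-bin labels.
#' @param label_order optional axis ordering.
#' @return list: `per_bin` (n x L matrix of per-bin means), `mean`
#'   (L x L summary), `n` (bins contributing per cell).
#' @export
label_interaction_summary <- function(oe, labels, label_order = NULL) {
  stopifnot(length(labels) == nrow(oe))
  lv <- if (is.null(label_order)) sort(unique(labels[!is.na(labels)]))
        else label_order
  loe <- log2(oe)
  loe[!is.finite(loe)] <- NA_real_
  diag(loe) <- NA_real_
  per_bin <- sapply(lv, function(l) {
    cols <- which(labels %in% l)
    rowMeans(loe[, cols, drop = FALSE], na.rm = TRUE)
  })
  per_bin[!is.finite(per_bin)] <- NA_real_
  colnames(per_bin) <- lv
  mean_m <- n_m <- matrix(NA_real_, length(lv), length(lv),
                          dimnames = list(lv, lv))
  for (a in seq_along(lv)) {
    rows <- which(labels %in% lv[a])
    for (b in seq_along(lv)) {
      v <- per_bin[rows, b]
      v <- v[!is.na(v)]
      n_m[a, b] <- length(v)
      mean_m[a, b] <- if (length(v)) mean(v) else NA_real_
    }
  }
  list(per_bin = per_bin, mean = mean_m, n = n_m)
}

largest_remainder <- function(counts, total) {
  nonzero <- counts > 0
  alloc <- integer(length(counts))
  if (!any(nonzero)) stop("no non-empty labels")
  share <- counts[nonzero] / sum(counts[nonzero]) * total
  fl <- floor(share)
  rem <- total - sum(fl)
  if (rem > 0) {
    extra <- order(share - fl, decreasing = TRUE)[seq_len(rem)]
    fl[extra] <- fl[extra] + 1L
  }
  # every non-empty label gets at least one quantile; take from the largest
  while (any(fl == 0L)) {
    z <- which(fl == 0L)[1L]
    big <- which.max(fl)
    fl[z] <- 1L
    fl[big] <- fl[big] - 1L
  }
  alloc[nonzero] <- as.integer(fl)
  alloc
}

#' Signal-ordered saddle summary within label classes
#'
#' Divides the usable bins into `n_quantiles` quantiles: each label class
#' receives a number of quantiles proportional to its bin count
#' (largest-remainder rounding, minimum 1 per non-empty class), and within
#' a class, bins are split into equal-occupancy quantiles by the signal
#' (ties broken by bin index). The saddle cell (q1, q2) is the mean log2 OE
#' over bin pairs across the two quantiles.
#'
#' @param oe OE matrix.
#' @param labels per-bin label vector.
#' @param signal per-bin ordering signal (e.g. H3K27me3 level).
#' @param n_quantiles total quantile count (default 100).
#' @param label_order order of label blocks along the saddle axes.
#' @return object of class `saddle_summary`: `matrix` (Q x Q mean log2 OE),
#'   `assignment` (per-bin quantile id, NA unusable), `quantile_label`,
#'   `allocation`, `mean_signal` per quantile, `label_order`.
#' @export
saddle_by_signal <- function(oe, labels, signal, n_quantiles = 100L,
                             label_order = NULL) {
  stopifnot(length(labels) == nrow(oe), length(signal) == nrow(oe))
  lv <- if (is.null(label_order)) sort(unique(labels[!is.na(labels)]))
        else label_order
  usable <- !is.na(labels) & labels %in% lv & is.finite(signal) &
    rowSums(is.finite(oe)) > 0
  counts <- vapply(lv, function(l) sum(labels[usable] == l), numeric(1))
  alloc <- largest_remainder(counts, n_quantiles)
  assignment <- rep(NA_integer_, length(labels))
  quantile_label <- character(0)
  q0 <- 0L
  for (k in seq_along(lv)) {
    if (alloc[k] == 0L) next
    bins <- which(usable & labels == lv[k])
    ord <- bins[order(signal[bins], bins)]
    grp <- ceiling(seq_along(ord) * alloc[k] / length(ord))
    assignment[ord] <- q0 + grp
    quantile_label <- c(quantile_label, rep(lv[k], alloc[k]))
    q0 <- q0 + alloc[k]
  }
  Q <- q0
  loe <- log2(oe)
  loe[!is.finite(loe)] <- NA_real_
  mat <- matrix(NA_real_, Q, Q)
  idx_by_q <- split(which(!is.na(assignment)),
                    assignment[!is.na(assignment)])
  for (a in seq_len(Q)) for (b in a:Q) {
    v <- loe[idx_by_q[[as.character(a)]], idx_by_q[[as.character(b)]]]
    v <- v[!is.na(v)]
    mat[a, b] <- mat[b, a] <- if (length(v)) mean(v) else NA_real_
  }
  mean_signal <- vapply(seq_len(Q), function(q)
    mean(signal[which(assignment == q)]), numeric(1))
  structure(list(matrix = mat, assignment = assignment,
                 quantile_label = quantile_label, allocation = alloc,
                 mean_signal = mean_signal, n_quantiles = Q,
                 label_order = lv),
            class = "saddle_summary")
}

#' @export
print.saddle_summary <- function(x, ...) {
  cat("saddle_summary:", x$n_quantiles, "quantiles over",
      length(x$label_order), "labels (",
      paste(x$allocation, collapse = "/"), ")\n")
  invisible(x)
}

#' Difference of two saddle summaries
#'
#' Elementwise `s1 - s2`; the two saddles must share the same quantile
#' layout (label order and allocation).
#'
#' @param s1,s2 `saddle_summary` objects.
#' @return Q x Q numeric matrix.
#' @export
saddle_difference <- function(s1, s2) {
  if (!identical(s1$quantile_label, s2$quantile_label))
    stop("mismatched quantile layouts")
  s1$matrix - s2$matrix
}
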