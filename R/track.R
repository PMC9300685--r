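#' Per-bin signal track with a missing-data mask
#'
#' Container for any per-bin quantity (methylation fraction, z-score,
#' compartment score, ChIP signal, rank). Masked bins carry no value;
#' arithmetic ignores them. Missing data are masked, never zero-filled:
#' zero is a legitimate methylation fraction.
#'
#' @param bs a [binspec].
#' @param values numeric vector, one entry per global bin.
#' @param mask logical vector, `TRUE` = missing/excluded. Defaults to
#'   `!is.finite(values)`.
#' @return object of class `binned_track`.
#' @export
binned_track <- function(bs, values, mask = NULL) {
  stopifnot(inherits(bs, "binspec"))
  if (length(values) != bs$total_bins)
    stop("values must have one entry per bin (", bs$total_bins, ")")
  if (is.null(mask)) mask <- !is.finite(values)
  if (length(mask) != bs$total_bins) stop("mask length mismatch")
  mask <- mask | !is.finite(values)
  values[mask] <- NA_real_
  structure(list(binspec = bs, values = as.numeric(values), mask = mask),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat("binned_track:", x$binspec$total_bins, "bins,",
      sum(x$mask), "masked\n")
  v <- x$values[!x$mask]
  if (length(v))
    cat("  range", format(min(v), digits = 4), "..",
        format(max(v), digits = 4), "\n")
  invisible(x)
}

#' Per-bin values of a track with masked bins as NA
#' @param track a [binned_track].
#' @return numeric vector, NA at masked bins.
#' @export
track_values <- function(track) {
  stopifnot(inherits(track, "binned_track"))
  ifelse(track$mask, NA_real_, track$values)
}

#' Z-score a track genome-wide
#'
#' Standardizes unmasked bins to mean 0, sample sd 1 (n-1 denominator).
#' Masked bins stay masked. Location/scale invariant: `zscore_track(a*v+b)`
#' equals `zscore_track(v)` for `a > 0`.
#'
#' @param track a [binned_track].
#' @return a `binned_track` of z-scores; attributes `center` and `scale`
#'   store the mean and sd used.
#' @export
zscore_track <- function(track) {
  v <- track_values(track)
  ok <- !track$mask
  if (sum(ok) < 2L) stop("need at least 2 unmasked bins to z-score")
  m <- mean(v[ok])
  s <- stats::sd(v[ok])
  if (!is.finite(s) || s == 0) stop("constant track: sd is zero")
  out <- binned_track(track$binspec, (v - m) / s, track$mask)
  attr(out, "center") <- m
  attr(out, "scale") <- s
  out
}

#' Average replicate tracks bin-wise
#'
#' Per-bin mean over replicates in which the bin is unmasked; a bin is
#' masked only if masked in every replicate.
#'
#' @param tracks list of [binned_track] on a shared binspec.
#' @return a `binned_track`.
#' @export
average_replicates <- function(tracks) {
  if (length(tracks) < 1L) stop("need at least one track")
  bs <- tracks[[1L]]$binspec
  for (t in tracks)
    if (!same_binspec(t$binspec, bs)) stop("binspec mismatch between replicates")
  vals <- vapply(tracks, track_values, numeric(bs$total_bins))
  if (is.null(dim(vals))) vals <- matrix(vals, ncol = length(tracks))
  m <- rowMeans(vals, na.rm = TRUE)
  mask <- rowSums(!is.na(vals)) == 0L
  binned_track(bs, ifelse(mask, NA_real_, m), mask)
}

#' Elementwise difference of two tracks
#'
#' `a - b`; a bin is masked if masked in either input.
#'
#' @param a,b [binned_track]s on a shared binspec.
#' @return a `binned_track`.
#' @export
diff_tracks <- function(a, b) {
  if (!same_binspec(a$binspec, b$binspec)) stop("binspec mismatch")
  mask <- a$mask | b$mask
  binned_track(a$binspec, track_values(a) - track_values(b), mask)
}

#' Rank-transform a track
#'
#' Unmasked bins are ranked ascending with ties averaged; masked bins stay
#' masked. For cross-replicate use, rank each replicate then
#' [average_replicates()] the rank tracks.
#'
#' @param track a [binned_track].
#' @return a `binned_track` of ranks.
#' @export
rank_track <- function(track) {
  v <- track_values(track)
  ok <- !track$mask
  if (!any(ok)) stop("no unmasked bins to rank")
  r <- rep(NA_real_, length(v))
  r[ok] <- rank(v[ok], ties.method = "average")
  binned_track(track$binspec, r, track$mask)
}

#' Binned methylation fraction with region exclusion
#'
#' Computes a per-bin methylated/total site fraction after removing sites
#' that fall inside exclusion regions (e.g. annotated CpG islands) padded by
#' `pad_bp` on each side. Bins left with zero sites are masked.
#'
#' @param sites data.frame with columns `chrom`, `pos` (0-based bp) and
#'   `meth` (0/1 or logical), one row per observed cytosine site.
#' @param bs a [binspec].
#' @param exclude optional region data.frame (`chrom`, `start`, `end`) whose
#'   padded footprint removes sites from numerator and denominator alike.
#' @param pad_bp symmetric padding applied to each exclusion region
#'   (default 2000 bp).
#' @return a `binned_track` of fractions in `[0, 1]`.
#' @export
bin_fraction_track <- function(sites, bs, exclude = NULL, pad_bp = 2000) {
  stopifnot(inherits(bs, "binspec"))
  if (pad_bp < 0) stop("pad_bp must be non-negative")
  keep <- rep(TRUE, nrow(sites))
  if (!is.null(exclude) && nrow(as.data.frame(exclude)) > 0) {
    ex <- as.data.frame(exclude)
    exg <- GenomicRanges::GRanges(
      ex$chrom,
      IRanges::IRanges(pmax(0, ex$start - pad_bp) + 1L, ex$end + pad_bp))
    sg <- GenomicRanges::GRanges(sites$chrom,
                                 IRanges::IRanges(sites$pos + 1L, width = 1L))
    keep <- !IRanges::overlapsAny(sg, exg)
  }
  s <- sites[keep, , drop = FALSE]
  n_tot <- n_meth <- numeric(bs$total_bins)
  if (nrow(s)) {
    idx <- bin_index(bs, s$chrom, s$pos)
    n_tot <- tabulate(idx, nbins = bs$total_bins)
    n_meth <- tabulate(idx[as.logical(s$meth)], nbins = bs$total_bins)
  }
  mask <- n_tot == 0
  binned_track(bs, ifelse(mask, NA_real_, n_meth / n_tot), mask)
}
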