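#' Genome binning specification
#'
#' A `binspec` fixes the chromosome sizes and the bin width used by every
#' binned object in the package. Bins are 0-based, half-open
#' `[k*w, (k+1)*w)`; position `p` on a chromosome falls in bin
#' `floor(p / w)`; the last bin of a chromosome may be short.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths in bp.
#' @param bin_width bin width in bp (default 50000, the resolution at which
#'   lamina GpC methylation, CpG methylation and compartment scores are
#'   compared).
#' @return an object of class `binspec` with the per-chromosome bin counts
#'   and global bin offsets precomputed.
#' @export
binspec <- function(chrom_sizes, bin_width = 50000L) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector")
  if (length(bin_width) != 1L || !is.finite(bin_width) || bin_width <= 0)
    stop("bin_width must be a single positive number")
  if (any(!is.finite(chrom_sizes)) || any(chrom_sizes <= 0))
    stop("every chromosome length must be > 0")
  chrom_sizes <- stats::setNames(round(as.numeric(chrom_sizes)),
                                 names(chrom_sizes))
  bin_width <- as.integer(bin_width)
  n_bins <- as.integer(ceiling(chrom_sizes / bin_width))
  offsets <- c(0L, cumsum(n_bins))
  structure(
    list(
      chrom_sizes = chrom_sizes,
      bin_width = bin_width,
      n_bins = stats::setNames(n_bins, names(chrom_sizes)),
      offsets = stats::setNames(offsets[-length(offsets)], names(chrom_sizes)),
      total_bins = sum(n_bins)
    ),
    class = "binspec"
  )
}

#' @export
print.binspec <- function(x, ...) {
  cat("binspec:", length(x$chrom_sizes), "chromosome(s),",
      x$bin_width, "bp bins,", x$total_bins, "bins total\n")
  invisible(x)
}

#' Map genomic positions to global bin indices
#'
#' @param bs a [binspec].
#' @param chrom chromosome names (recycled against `pos`).
#' @param pos 0-based positions in bp.
#' @return 1-based global bin indices into the concatenated genome.
#' @export
bin_index <- function(bs, chrom, pos) {
  stopifnot(inherits(bs, "binspec"))
  unknown <- setdiff(unique(chrom), names(bs$chrom_sizes))
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  if (any(pos < 0) || any(pos >= bs$chrom_sizes[chrom]))
    stop("position outside chromosome bounds")
  local <- floor(pos / bs$bin_width)
  as.integer(bs$offsets[chrom] + local + 1L)
}

#' Per-bin genomic coordinates
#'
#' @param bs a [binspec].
#' @return data.frame with columns chrom, start, end (0-based half-open),
#'   one row per global bin in genome order.
#' @export
bin_coords <- function(bs) {
  stopifnot(inherits(bs, "binspec"))
  chrom <- rep(names(bs$n_bins), bs$n_bins)
  local <- unlist(lapply(bs$n_bins, function(n) seq_len(n) - 1L), use.names = FALSE)
  start <- local * bs$bin_width
  end <- pmin(start + bs$bin_width, bs$chrom_sizes[chrom])
  data.frame(chrom = chrom, start = start, end = unname(end),
             stringsAsFactors = FALSE)
}

#' Global bin indices belonging to one chromosome
#' @param bs a [binspec].
#' @param chrom single chromosome name.
#' @return integer vector of global bin indices.
#' @export
chrom_bins <- function(bs, chrom) {
  stopifnot(inherits(bs, "binspec"), chrom %in% names(bs$chrom_sizes))
  bs$offsets[[chrom]] + seq_len(bs$n_bins[[chrom]])
}

same_binspec <- function(a, b) {
  isTRUE(all.equal(a$chrom_sizes, b$chrom_sizes)) && a$bin_width == b$bin_width
}
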