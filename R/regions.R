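#' Genomic interval set
#'
#' Thin data.frame container for 0-based half-open intervals with optional
#' score and label columns, kept sorted by (chrom, start). Used for LADs,
#' differential regions, compartment domains and peaks.
#'
#' @param chrom,start,end vectors defining intervals (`start < end`, bp).
#' @param score optional numeric per-interval statistic.
#' @param label optional character per-interval label.
#' @return a sorted data.frame of class `region_set`.
#' @export
region_set <- function(chrom = character(), start = integer(),
                       end = integer(), score = NULL, label = NULL) {
  if (any(start < 0)) stop("start must be >= 0")
  if (any(end <= start)) stop("every interval needs start < end")
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   stringsAsFactors = FALSE)
  if (!is.null(score)) df$score <- as.numeric(score)
  if (!is.null(label)) df$label <- as.character(label)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("region_set", "data.frame")
  df
}

as_region_set <- function(df) {
  region_set(df$chrom, df$start, df$end,
             score = if ("score" %in% names(df)) df$score,
             label = if ("label" %in% names(df)) df$label)
}

regions_to_granges <- function(regions) {
  df <- as.data.frame(regions)
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end))
}

granges_to_regions <- function(gr) {
  region_set(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr) - 1L,
             GenomicRanges::end(gr))
}

#' Base-pair overlap statistics between two region sets
#'
#' @param a,b `region_set` (or plain data.frames with chrom/start/end).
#' @return list with `bp_overlap` (intersected bases), `bp_union`,
#'   `jaccard` (intersection over union in bases), and `per_label` — a
#'   table of overlap bases split by the `label` column of `a` when present.
#' @export
overlap_stats <- function(a, b) {
  ga <- GenomicRanges::reduce(regions_to_granges(a))
  gb <- GenomicRanges::reduce(regions_to_granges(b))
  inter <- GenomicRanges::intersect(ga, gb)
  uni <- GenomicRanges::union(ga, gb)
  bp_i <- sum(as.numeric(GenomicRanges::width(inter)))
  bp_u <- sum(as.numeric(GenomicRanges::width(uni)))
  per_label <- NULL
  adf <- as.data.frame(a)
  if ("label" %in% names(adf) && nrow(adf)) {
    per_label <- vapply(split(adf, adf$label), function(sub) {
      gi <- GenomicRanges::intersect(
        GenomicRanges::reduce(regions_to_granges(sub)), gb)
      sum(as.numeric(GenomicRanges::width(gi)))
    }, numeric(1))
  }
  list(bp_overlap = bp_i, bp_union = bp_u,
       jaccard = if (bp_u > 0) bp_i / bp_u else 0,
       per_label = per_label)
}
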