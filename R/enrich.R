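#' Single-base border points of a region set
#'
#' Two borders per region: the first covered base (`start`) and the last
#' covered base (`end - 1`), so borders are coordinates of covered
#' positions. Chromosome-terminal borders are retained.
#'
#' @param regions a merged, non-overlapping [region_set].
#' @return data.frame with columns `chrom`, `pos`.
#' @export
borders_from_regions <- function(regions) {
  df <- as.data.frame(regions)
  if (!nrow(df)) return(data.frame(chrom = character(), pos = numeric()))
  out <- data.frame(chrom = rep(df$chrom, each = 2L),
                    pos = as.numeric(rbind(df$start, df$end - 1L)),
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Median distance from regions to their nearest border
#'
#' Per query region, the minimum gap to any same-chromosome border point
#' (0 if a border falls inside the region); the statistic is the median
#' over usable regions. Regions on chromosomes without borders are skipped
#' and counted.
#'
#' @param query a [region_set].
#' @param borders data.frame from [borders_from_regions()].
#' @return list: `median` (bp), `distances` (per usable region),
#'   `n_skipped`.
#' @export
median_distance_to_borders <- function(query, borders) {
  q <- as.data.frame(query)
  if (!nrow(q)) stop("no query regions")
  by_chrom <- split(borders$pos, borders$chrom)
  dist <- rep(NA_real_, nrow(q))
  for (i in seq_len(nrow(q))) {
    b <- by_chrom[[q$chrom[i]]]
    if (is.null(b) || !length(b)) next
    # distance from point b to half-open [start, end): 0 on containment
    dist[i] <- min(pmax(0, q$start[i] - b, b - (q$end[i] - 1L)))
  }
  usable <- !is.na(dist)
  if (!any(usable)) stop("no query region has a same-chromosome border")
  list(median = stats::median(dist[usable]), distances = dist[usable],
       n_skipped = sum(!usable))
}

#' Shuffle regions within their chromosomes
#'
#' Each region is placed uniformly at random on its own chromosome with its
#' length preserved; placements within one shuffle must not overlap each
#' other (rejection-resampled, up to 1000 attempts per region).
#'
#' @param regions a [region_set].
#' @param bs a [binspec] supplying chromosome lengths.
#' @param seed RNG seed.
#' @return a shuffled [region_set].
#' @export
shuffle_regions <- function(regions, bs, seed = 1L) {
  df <- as.data.frame(regions)
  if (!nrow(df)) return(region_set())
  if (any(!(df$chrom %in% names(bs$chrom_sizes))))
    stop("region on a chromosome absent from the binspec")
  len <- df$end - df$start
  if (any(len > bs$chrom_sizes[df$chrom]))
    stop("region longer than its chromosome")
  with_seed(seed, {
    out_start <- numeric(nrow(df))
    for (ch in unique(df$chrom)) {
      idx <- which(df$chrom == ch)
      L <- bs$chrom_sizes[[ch]]
      placed_s <- numeric(0)
      placed_e <- numeric(0)
      for (i in idx) {
        ok <- FALSE
        for (attempt in seq_len(1000L)) {
          s <- floor(stats::runif(1L) * (L - len[i] + 1))
          e <- s + len[i]
          if (!any(s < placed_e & placed_s < e)) {
            ok <- TRUE
            break
          }
        }
        if (!ok) stop("could not place region after 1000 attempts (", ch, ")")
        out_start[i] <- s
        placed_s <- c(placed_s, s)
        placed_e <- c(placed_e, e)
      }
    }
    region_set(df$chrom, out_start, out_start + len,
               score = df$score, label = df$label)
  })
}

#' Permutation enrichment of a region set against a reference
#'
#' Compares an observed statistic — interval Jaccard with the reference, or
#' median distance to the reference's borders — against a null distribution
#' obtained by shuffling the query regions within their chromosomes
#' `n_shuffles` times. The empirical p-value uses the add-one formula
#' `p = (1 + #{null at least as extreme}) / (n_shuffles + 1)` and is never
#' zero; the enrichment ratio is observed / mean(null).
#'
#' @param query,reference [region_set]s.
#' @param bs a [binspec].
#' @param statistic `"jaccard"` or `"distance"` (median distance to the
#'   borders of `reference`).
#' @param n_shuffles number of shuffles (default 1000).
#' @param alternative `"greater"` (null >= observed counts as extreme) or
#'   `"less"`; defaults to `"greater"` for Jaccard enrichment and `"less"`
#'   for border distance.
#' @param seed base RNG seed; shuffle s uses `seed + s`.
#' @return object of class `enrichment_result`: `observed`, `null`,
#'   `ratio`, `p`, `n_shuffles`, `statistic`, `alternative`, `seed`.
#' @export
permutation_enrichment <- function(query, reference, bs,
                                   statistic = c("jaccard", "distance"),
                                   n_shuffles = 1000L,
                                   alternative = NULL, seed = 1L) {
  statistic <- match.arg(statistic)
  if (is.null(alternative))
    alternative <- if (statistic == "jaccard") "greater" else "less"
  alternative <- match.arg(alternative, c("greater", "less"))
  stat_fn <- if (statistic == "jaccard") {
    ref_merged <- merge_intervals_df(as.data.frame(reference))
    function(q) interval_jaccard(merge_intervals_df(as.data.frame(q)),
                                 ref_merged)
  } else {
    borders <- borders_from_regions(reference)
    function(q) median_distance_to_borders(q, borders)$median
  }
  observed <- stat_fn(query)
  null <- vapply(seq_len(n_shuffles), function(s)
    stat_fn(shuffle_regions(query, bs, seed = seed + s)), numeric(1))
  extreme <- if (alternative == "greater") sum(null >= observed)
             else sum(null <= observed)
  p <- (1 + extreme) / (n_shuffles + 1)
  ratio <- if (mean(null) > 0) observed / mean(null) else NA_real_
  structure(list(observed = observed, null = null, ratio = ratio, p = p,
                 n_shuffles = n_shuffles, statistic = statistic,
                 alternative = alternative, seed = seed),
            class = "enrichment_result")
}

# merged (non-overlapping, sorted) intervals per chromosome, base-R sweep;
# semantics match GenomicRanges::reduce and are cross-checked in the tests
merge_intervals_df <- function(df) {
  if (!nrow(df)) return(list())
  lapply(split(df[c("start", "end")], df$chrom), function(d) {
    o <- order(d$start, d$end)
    s <- d$start[o]; e <- d$end[o]
    grp <- cumsum(c(1L, as.integer(s[-1] > cummax(e[-length(e)]))))
    list(start = as.numeric(tapply(s, grp, min)),
         end = as.numeric(tapply(e, grp, max)))
  })
}

# bases of merged interval list `iv` lying strictly before coordinate x
bases_before <- function(iv, x) {
  cumcov <- c(0, cumsum(iv$end - iv$start))
  j <- findInterval(x, iv$start)
  out <- cumcov[j + 1L]
  inside <- j >= 1L
  out[inside] <- cumcov[j[inside]] +
    pmin(pmax(0, x[inside] - iv$start[j[inside]]),
         (iv$end - iv$start)[j[inside]])
  out
}

interval_jaccard <- function(a, b) {
  chroms <- union(names(a), names(b))
  inter <- uni_a <- uni_b <- 0
  for (ch in chroms) {
    ia <- a[[ch]]; ib <- b[[ch]]
    if (!is.null(ia)) uni_a <- uni_a + sum(ia$end - ia$start)
    if (!is.null(ib)) uni_b <- uni_b + sum(ib$end - ib$start)
    if (is.null(ia) || is.null(ib)) next
    inter <- inter +
      sum(bases_before(ib, ia$end) - bases_before(ib, ia$start))
  }
  uni <- uni_a + uni_b - inter
  if (uni > 0) inter / uni else 0
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("permutation enrichment (", x$statistic, ", alternative ",
      x$alternative, "):\n  observed ", format(x$observed, digits = 4),
      ", null mean ", format(mean(x$null), digits = 4),
      ", ratio ", format(x$ratio, digits = 4),
      ", p = ", format(x$p, digits = 4),
      " (", x$n_shuffles, " shuffles)\n", sep = "")
  invisible(x)
}
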