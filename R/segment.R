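#' Sub-compartment classification by k-means
#'
#' Clusters bins in the replicate-averaged (GpC-z, CpG-z, PC1-z) feature
#' space into k = 4 sub-compartments. Bins where any feature has |z| above
#' `z_exclude` are excluded before clustering; masked bins stay masked.
#' Clusters are mapped to names by their centroids: of the two centroids
#' with the highest PC1 (the A compartment), the one with higher CpG-z is
#' Core-A and the other PcG-A; of the two with the lowest PC1, the one with
#' higher GpC-z (more lamina-associated) is Core-B and the other PcG-B.
#' Bins are clustered in a canonical (content-sorted) order so the result
#' is invariant to input bin order.
#'
#' @param gpc_z,cpg_z,pc1_z replicate-averaged z-score [binned_track]s on a
#'   shared binspec.
#' @param k number of clusters (default 4).
#' @param z_exclude absolute z cutoff for exclusion (default 3).
#' @param seed RNG seed for the k-means restarts.
#' @param n_init number of random restarts (default 10).
#' @return object of class `subcompartment_call`: `labels` (per bin, one of
#'   the four names, `"excluded"` or `"masked"`), `centroids` (named 4 x 3
#'   matrix), `binspec`.
#' @export
kmeans_subcompartments <- function(gpc_z, cpg_z, pc1_z, k = 4L,
                                   z_exclude = 3, seed = 1L, n_init = 10L) {
  bs <- gpc_z$binspec
  if (!same_binspec(bs, cpg_z$binspec) || !same_binspec(bs, pc1_z$binspec))
    stop("binspec mismatch between feature tracks")
  X <- cbind(gpc_z = track_values(gpc_z), cpg_z = track_values(cpg_z),
             pc1_z = track_values(pc1_z))
  masked <- rowSums(is.na(X)) > 0
  excluded <- !masked & apply(abs(X), 1L, max) > z_exclude
  use <- which(!masked & !excluded)
  if (length(use) < k) stop("fewer usable bins than clusters")
  Xu <- X[use, , drop = FALSE]
  ord <- order(Xu[, 1L], Xu[, 2L], Xu[, 3L])
  fit <- with_seed(seed,
                   stats::kmeans(Xu[ord, , drop = FALSE], centers = k,
                                 nstart = n_init, iter.max = 100L))
  cl <- integer(length(use))
  cl[ord] <- fit$cluster
  cent <- fit$centers
  name_map <- name_subcompartment_clusters(cent)
  labels <- rep("masked", bs$total_bins)
  labels[excluded] <- "excluded"
  labels[use] <- name_map[cl]
  centroids <- cent
  rownames(centroids) <- name_map
  centroids <- centroids[SUBCOMP_LABELS, , drop = FALSE]
  structure(list(labels = labels, centroids = centroids, binspec = bs),
            class = "subcompartment_call")
}

name_subcompartment_clusters <- function(cent) {
  if (nrow(cent) != 4L)
    stop("centroid naming rule requires exactly 4 clusters")
  ord <- order(cent[, "pc1_z"], decreasing = TRUE)
  if (abs(cent[ord[2L], "pc1_z"] - cent[ord[3L], "pc1_z"]) < 1e-9)
    stop("centroid rule ambiguous: equal PC1 centroids")
  a_pair <- ord[1:2]
  b_pair <- ord[3:4]
  name <- character(4L)
  name[a_pair[order(cent[a_pair, "cpg_z"], decreasing = TRUE)]] <-
    c("Core-A", "PcG-A")
  name[b_pair[order(cent[b_pair, "gpc_z"], decreasing = TRUE)]] <-
    c("Core-B", "PcG-B")
  name
}

#' @export
print.subcompartment_call <- function(x, ...) {
  cat("subcompartment_call:\n")
  print(table(x$labels))
  invisible(x)
}

#' Call lamina-associated domains from a z-scored track
#'
#' LADs are maximal runs of consecutive unmasked bins with z strictly above
#' the threshold (0 = the genome mean; z = 0 itself is not evidence of
#' attachment); masked bins terminate runs. Runs shorter than `min_bins`
#' bins are removed.
#'
#' @param z_track a z-scored [binned_track].
#' @param threshold run threshold (default 0).
#' @param min_bins minimum run length in bins (default 3; runs of 2 or
#'   fewer bins, i.e. under 150 kb at 50 kb bins, are dropped).
#' @return a [region_set] with per-region mean z as score.
#' @export
call_lads <- function(z_track, threshold = 0, min_bins = 3L) {
  v <- track_values(z_track)
  keep <- !is.na(v) & v > threshold
  mask_to_regions(z_track$binspec, keep, min_bins = min_bins, score = v)
}

#' Replicate-consensus regions
#'
#' Genomic positions covered by at least `min_support` of the input region
#' sets, merged into intervals; intervals shorter than `min_len_bp` are
#' then removed (re-applying the run-length filter after consensus).
#'
#' @param region_sets list of [region_set].
#' @param min_support minimum number of supporting sets (default 2).
#' @param min_len_bp minimum consensus interval length in bp (default 0 =
#'   no filter; pass `3 * bin_width` to mirror the LAD-calling filter).
#' @return a [region_set].
#' @export
consensus_regions <- function(region_sets, min_support = 2L,
                              min_len_bp = 0) {
  if (min_support > length(region_sets))
    stop("min_support exceeds the number of region sets")
  merged <- lapply(region_sets, function(r)
    merge_intervals_df(as.data.frame(r)))
  chroms <- sort(unique(unlist(lapply(merged, names))))
  out <- list()
  for (ch in chroms) {
    pos <- delta <- numeric(0)
    for (m in merged) {
      iv <- m[[ch]]
      if (is.null(iv)) next
      pos <- c(pos, iv$start, iv$end)
      delta <- c(delta, rep(1, length(iv$start)), rep(-1, length(iv$end)))
    }
    if (!length(pos)) next
    o <- order(pos)
    p <- pos[o]
    cum <- cumsum(delta[o])
    last <- !duplicated(p, fromLast = TRUE)
    bp <- p[last]                 # unique breakpoints
    cov <- cum[last]              # coverage on [bp[k], bp[k+1])
    if (length(bp) < 2L) next
    qual <- cov[-length(cov)] >= min_support
    r <- rle(qual)
    ends_idx <- cumsum(r$lengths)
    starts_idx <- ends_idx - r$lengths + 1L
    for (k in which(r$values)) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = bp[starts_idx[k]], end = bp[ends_idx[k] + 1L],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(region_set())
  df <- do.call(rbind, out)
  df <- df[df$end - df$start >= max(1, min_len_bp), , drop = FALSE]
  if (!nrow(df)) return(region_set())
  region_set(df$chrom, df$start, df$end)
}

#' Differential lamina regions by per-bin Welch t-statistic
#'
#' Per bin, a two-sample Welch (unequal-variance) t-statistic comparing
#' treatment to vehicle z-scored replicate tracks; gain regions are runs of
#' bins with `t > t_threshold`, loss regions runs with `t < -t_threshold`;
#' runs shorter than `min_bins` are dropped. Swapping the groups swaps
#' gains and losses exactly.
#'
#' @param treat_z_reps,vehicle_z_reps lists of z-scored [binned_track]s
#'   (at least 2 replicates each) on a shared binspec.
#' @param t_threshold signed t cutoff (e.g. 4 for an EZH2i-like contrast,
#'   2 for a DNMT1i-like one).
#' @param min_bins minimum run length (default 3).
#' @return a [region_set] with `score` = mean t over the region's bins and
#'   `label` in `{"gain", "loss"}`; the per-bin t vector is attached as
#'   attribute `t`.
#' @export
call_differential_regions <- function(treat_z_reps, vehicle_z_reps,
                                      t_threshold, min_bins = 3L) {
  if (length(treat_z_reps) < 2L || length(vehicle_z_reps) < 2L)
    stop("need at least 2 replicates per condition")
  bs <- treat_z_reps[[1L]]$binspec
  for (tr in c(treat_z_reps, vehicle_z_reps))
    if (!same_binspec(tr$binspec, bs)) stop("binspec mismatch")
  t_stat <- welch_t_bins(treat_z_reps, vehicle_z_reps)
  gain <- mask_to_regions(bs, !is.na(t_stat) & t_stat > t_threshold,
                          min_bins = min_bins, score = t_stat)
  loss <- mask_to_regions(bs, !is.na(t_stat) & t_stat < -t_threshold,
                          min_bins = min_bins, score = t_stat)
  gdf <- as.data.frame(gain); ldf <- as.data.frame(loss)
  if (nrow(gdf)) gdf$label <- "gain"
  if (nrow(ldf)) ldf$label <- "loss"
  df <- rbind(if (nrow(gdf)) gdf, if (nrow(ldf)) ldf)
  out <- if (is.null(df) || !nrow(df)) region_set() else
    region_set(df$chrom, df$start, df$end, score = df$score,
               label = df$label)
  attr(out, "t") <- t_stat
  out
}

welch_t_bins <- function(treat, vehicle) {
  Xt <- vapply(treat, track_values, numeric(treat[[1L]]$binspec$total_bins))
  Xv <- vapply(vehicle, track_values,
               numeric(vehicle[[1L]]$binspec$total_bins))
  n1 <- rowSums(!is.na(Xt)); n2 <- rowSums(!is.na(Xv))
  m1 <- rowMeans(Xt, na.rm = TRUE); m2 <- rowMeans(Xv, na.rm = TRUE)
  v1 <- apply(Xt, 1L, stats::var, na.rm = TRUE)
  v2 <- apply(Xv, 1L, stats::var, na.rm = TRUE)
  se <- sqrt(v1 / n1 + v2 / n2)
  t_stat <- (m1 - m2) / se
  t_stat[!is.finite(t_stat) | n1 < 2 | n2 < 2] <- NA_real_
  t_stat
}
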