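#' @name io
#' @title Text I/O for the pipeline's external formats
#'
#' @description
#' All coordinates are 0-based half-open, the native convention of BED and
#' bedGraph; any 1-based source must be converted before entering the
#' package. Readers validate and fail with the offending line number; they
#' never silently drop records.
NULL

LIMEPAIRS_COLS <- c("chrom1", "pos1", "strand1", "frag1",
                    "chrom2", "pos2", "strand2", "frag2", "mapq",
                    "n_cpg1", "n_cpg_meth1", "n_gpc1", "n_gpc_meth1",
                    "n_cpg2", "n_cpg_meth2", "n_gpc2", "n_gpc_meth2")

#' Read methylation-tagged contacts ("limepairs" TSV)
#'
#' One contact per line: mapped coordinates, strands, restriction-fragment
#' ids and MAPQ for both ends, plus per-end CpG and GpC site/methylated-site
#' counts extracted upstream from the bisulfite reads (GpCpG-ambiguous sites
#' are assumed already excluded).
#'
#' @param path TSV file with the 17-column header
#'   `#chrom1 pos1 strand1 frag1 chrom2 pos2 strand2 frag2 mapq n_cpg1 ...`.
#' @param bs optional [binspec]; when given, chromosome names and positions
#'   are validated against it.
#' @return data.frame of class `tagged_contacts`, one row per contact, in
#'   file order.
#' @export
read_limepairs <- function(path, bs = NULL) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty file (missing header): ", path)
  header <- sub("^#", "", lines[[1L]])
  cols <- strsplit(header, "\t", fixed = TRUE)[[1L]]
  if (!identical(cols, LIMEPAIRS_COLS))
    stop("bad limepairs header in ", path,
         ": expected columns ", paste(LIMEPAIRS_COLS, collapse = " "))
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0L) return(empty_contacts())
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 17L))
    stop("line ", which(nf != 17L)[1L] + 1L, ": expected 17 columns, got ",
         nf[nf != 17L][1L])
  m <- matrix(unlist(parts), ncol = 17L, byrow = TRUE)
  colnames(m) <- LIMEPAIRS_COLS
  df <- data.frame(m, stringsAsFactors = FALSE)
  num_cols <- setdiff(LIMEPAIRS_COLS, c("chrom1", "strand1", "chrom2", "strand2"))
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v))
      stop("line ", which(is.na(v))[1L] + 1L, ": non-numeric value in ", cc)
    df[[cc]] <- v
  }
  validate_contacts(df, bs)
  class(df) <- c("tagged_contacts", "data.frame")
  df
}

empty_contacts <- function() {
  df <- as.data.frame(stats::setNames(
    c(list(character(), numeric(), character(), numeric(),
           character(), numeric(), character(), numeric()),
      rep(list(numeric()), 9L)),
    LIMEPAIRS_COLS), stringsAsFactors = FALSE)
  class(df) <- c("tagged_contacts", "data.frame")
  df
}

validate_contacts <- function(df, bs = NULL) {
  bad_strand <- !(df$strand1 %in% c("+", "-")) | !(df$strand2 %in% c("+", "-"))
  if (any(bad_strand))
    stop("line ", which(bad_strand)[1L] + 1L, ": strand must be + or -")
  counts <- df[, grep("^n_", names(df)), drop = FALSE]
  if (any(counts < 0))
    stop("negative site or methylation count")
  for (ctx in c("cpg", "gpc")) for (end in 1:2) {
    n <- df[[paste0("n_", ctx, end)]]
    k <- df[[paste0("n_", ctx, "_meth", end)]]
    bad <- k > n
    if (any(bad))
      stop("line ", which(bad)[1L] + 1L,
           ": meth count exceeds site count (", ctx, " end ", end, ")")
  }
  if (!is.null(bs)) {
    known <- names(bs$chrom_sizes)
    unk <- !(df$chrom1 %in% known) | !(df$chrom2 %in% known)
    if (any(unk))
      stop("line ", which(unk)[1L] + 1L, ": unknown chromosome")
    oob <- df$pos1 < 0 | df$pos2 < 0 |
      df$pos1 >= bs$chrom_sizes[df$chrom1] |
      df$pos2 >= bs$chrom_sizes[df$chrom2]
    if (any(oob))
      stop("line ", which(oob)[1L] + 1L, ": position outside chromosome")
  }
  invisible(df)
}

#' Write methylation-tagged contacts
#' @param contacts a `tagged_contacts` data.frame.
#' @param path output TSV path.
#' @export
write_limepairs <- function(contacts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(LIMEPAIRS_COLS, collapse = "\t")), con)
  if (nrow(contacts)) {
    df <- as.data.frame(contacts)[, LIMEPAIRS_COLS]
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a 4-column bedGraph into a binned track
#'
#' Each bin's value is the coverage-weighted mean of the bedGraph intervals
#' overlapping it; bins with no coverage are masked. Intervals may be
#' unsorted.
#'
#' @param path bedGraph file (chrom, start, end, value; 0-based half-open).
#' @param bs a [binspec].
#' @return a [binned_track].
#' @export
read_bedgraph <- function(path, bs) {
  stopifnot(inherits(bs, "binspec"))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "numeric", "numeric",
                                         "numeric"))
  if (nrow(df) == 0L)
    return(binned_track(bs, rep(NA_real_, bs$total_bins)))
  if (any(df$end <= df$start)) stop("bedGraph interval with end <= start")
  unk <- setdiff(unique(df$chrom), names(bs$chrom_sizes))
  if (length(unk)) stop("chromosome absent from binspec: ", unk[1L])
  if (any(df$end > bs$chrom_sizes[df$chrom]))
    stop("bedGraph interval beyond chromosome end")
  w <- bs$bin_width
  b0 <- floor(df$start / w)
  b1 <- floor((df$end - 1) / w)
  nspan <- b1 - b0 + 1L
  row <- rep(seq_len(nrow(df)), nspan)
  binl <- unlist(lapply(seq_len(nrow(df)),
                        function(i) seq(b0[i], b1[i])), use.names = FALSE)
  bstart <- binl * w
  ov <- pmin(df$end[row], bstart + w) - pmax(df$start[row], bstart)
  idx <- bs$offsets[df$chrom[row]] + binl + 1L
  wt <- tapply(ov, idx, sum)
  sv <- tapply(ov * df$value[row], idx, sum)
  vals <- rep(NA_real_, bs$total_bins)
  vals[as.integer(names(wt))] <- as.numeric(sv / wt)
  binned_track(bs, vals)
}

#' Write a binned track as bedGraph
#'
#' One line per unmasked bin; masked bins are omitted (missing data are not
#' written as zero).
#'
#' @param track a [binned_track].
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  bc <- bin_coords(track$binspec)
  keep <- !track$mask
  df <- cbind(bc[keep, , drop = FALSE],
              value = track$values[keep])
  utils::write.table(format(df, scientific = FALSE, trim = TRUE,
                            digits = 15),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write BED interval files
#'
#' BED3 plus optional name (used as label) and score columns; 0-based
#' half-open as native BED.
#'
#' @param path BED file.
#' @return a [region_set].
#' @export
read_bed <- function(path) {
  first <- tryCatch(readLines(path, n = 1L), error = function(e) character())
  if (length(first) == 0L || !nzchar(first)) return(region_set())
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character")
  if (ncol(df) < 3L) stop("BED needs at least 3 columns: ", path)
  out <- region_set(df[[1L]], as.numeric(df[[2L]]), as.numeric(df[[3L]]),
                    label = if (ncol(df) >= 4L) df[[4L]],
                    score = if (ncol(df) >= 5L)
                      suppressWarnings(as.numeric(df[[5L]])))
  out
}

#' @rdname read_bed
#' @param regions a [region_set].
#' @export
write_bed <- function(regions, path) {
  df <- as.data.frame(regions)
  cols <- data.frame(chrom = df$chrom,
                     start = format(df$start, scientific = FALSE, trim = TRUE),
                     end = format(df$end, scientific = FALSE, trim = TRUE))
  if (!is.null(df$label) || !is.null(df$score)) {
    cols$name <- if (is.null(df$label)) "." else df$label
    cols$score <- if (is.null(df$score)) "0" else
      format(df$score, scientific = FALSE, trim = TRUE, digits = 10)
  }
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a binned contact matrix as triplet text
#'
#' The triplet format mirrors text dumps of binned contact matrices:
#' `start1<TAB>start2<TAB>value`, bin starts in bp on one chromosome.
#' Symmetric matrices are written upper-triangle only and mirrored on read.
#'
#' @param path triplet file.
#' @param bs a [binspec].
#' @param chrom chromosome the matrix belongs to.
#' @return dense numeric matrix (n_bins x n_bins for `chrom`).
#' @export
read_triplets <- function(path, bs, chrom) {
  stopifnot(inherits(bs, "binspec"), chrom %in% names(bs$chrom_sizes))
  n <- bs$n_bins[[chrom]]
  mat <- matrix(0, n, n)
  first <- tryCatch(readLines(path, n = 1L), error = function(e) character())
  if (length(first) == 0L || !nzchar(first)) return(mat)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("start1", "start2", "value"))
  w <- bs$bin_width
  if (any(df$start1 %% w != 0 | df$start2 %% w != 0))
    stop("triplet bin start not a multiple of bin_width")
  i <- df$start1 / w + 1L
  j <- df$start2 / w + 1L
  if (any(i > n | j > n)) stop("triplet bin beyond chromosome end")
  mat[cbind(i, j)] <- df$value
  lower <- i > j
  mat[cbind(j[!lower], i[!lower])] <- df$value[!lower]
  mat[cbind(i[lower], j[lower])] <- df$value[lower]
  mat
}

#' @rdname read_triplets
#' @param mat dense matrix to write; only nonzero entries are written,
#'   upper triangle only when `mat` is symmetric.
#' @export
write_triplets <- function(mat, path, bs, chrom) {
  stopifnot(inherits(bs, "binspec"))
  w <- bs$bin_width
  sym <- isTRUE(all.equal(mat, t(mat), tolerance = 0))
  idx <- which(mat != 0, arr.ind = TRUE)
  if (sym) idx <- idx[idx[, 1L] <= idx[, 2L], , drop = FALSE]
  df <- data.frame(start1 = (idx[, 1L] - 1L) * w,
                   start2 = (idx[, 2L] - 1L) * w,
                   value = mat[idx])
  df <- df[order(df$start1, df$start2), , drop = FALSE]
  utils::write.table(format(df, scientific = FALSE, trim = TRUE, digits = 15),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write chromosome sizes (two-column text)
#' @param path chrom.sizes file.
#' @param bin_width bin width handed to the resulting [binspec].
#' @return a [binspec].
#' @export
read_chrom_sizes <- function(path, bin_width = 50000L) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "size"),
                          colClasses = c("character", "numeric"))
  binspec(stats::setNames(df$size, df$chrom), bin_width)
}

#' @rdname read_chrom_sizes
#' @param bs a [binspec] to write.
#' @export
write_chrom_sizes <- function(bs, path) {
  utils::write.table(
    data.frame(names(bs$chrom_sizes),
               format(bs$chrom_sizes, scientific = FALSE, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
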