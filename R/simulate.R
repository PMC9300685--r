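#' Simulation configuration
#'
#' Parameters of the synthetic genome and contact generator. Defaults are
#' the package's reference conditions: two 20 Mb chromosomes at 50 kb bins,
#' 1e5 intra-chromosomal contacts with power-law distance decay, a
#' same-label contact affinity that makes compartments recoverable, and
#' per-read GpC methylation driven by a latent shared "peripheral"
#' (lamina-proximal) state coupling the two ends of a contact.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param bin_width bin width in bp.
#' @param n_contacts contacts to draw per replicate.
#' @param rho coupling in `[0,1]`: probability that the two ends of a
#'   contact share one lamina-state draw instead of drawing independently.
#' @param alpha contact distance-decay exponent (`P(d) ~ d^-alpha`).
#' @param beta same-sub-compartment affinity multiplier (>= 1); pairs in the
#'   same compartment but different sub-compartments get `sqrt(beta)`.
#' @param mu_sites mean extra informative sites per read end
#'   (`n_sites ~ 1 + Poisson(mu_sites)`).
#' @param p_gpc_on,p_gpc_off per-site GpC methylation probability for a
#'   lamina-proximal / interior read.
#' @param p_cpg_on,p_cpg_off per-site CpG methylation probability for a read
#'   from a high- / low-CpG-methylation locus.
#' @param noise_sd replicate track noise sd.
#' @param mean_block_bins mean sub-compartment block length in bins.
#' @param seed default RNG seed for [simulate_genome()].
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 2L, chrom_length = 2e7, bin_width = 50000L,
                       n_contacts = 1e5, rho = 0.5, alpha = 1.0, beta = 3,
                       mu_sites = 8, p_gpc_on = 0.8, p_gpc_off = 0.1,
                       p_cpg_on = 0.8, p_cpg_off = 0.1,
                       noise_sd = 0.05, mean_block_bins = 12, seed = 1L) {
  probs <- c(p_gpc_on, p_gpc_off, p_cpg_on, p_cpg_off, rho)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  if (p_gpc_on <= p_gpc_off) stop("p_gpc_on must exceed p_gpc_off")
  if (n_contacts <= 0) stop("n_contacts must be positive")
  if (beta < 1) stop("beta must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(n_chroms = as.integer(n_chroms),
                 chrom_length = chrom_length, bin_width = bin_width,
                 n_contacts = n_contacts, rho = rho, alpha = alpha,
                 beta = beta, mu_sites = mu_sites,
                 p_gpc_on = p_gpc_on, p_gpc_off = p_gpc_off,
                 p_cpg_on = p_cpg_on, p_cpg_off = p_cpg_off,
                 noise_sd = noise_sd, mean_block_bins = mean_block_bins,
                 seed = seed),
            class = "sim_config")
}

SUBCOMP_LABELS <- c("Core-A", "PcG-A", "PcG-B", "Core-B")

# Per-label lamina attachment propensity: constitutive heterochromatin
# (Core-B) most peripheral, Polycomb-B intermediate, A compartment low.
LAMBDA_BY_LABEL <- c("Core-B" = 0.85, "PcG-B" = 0.60,
                     "PcG-A" = 0.25, "Core-A" = 0.15)
# Endogenous CpG methylation propensity: highest in active Core-A,
# lowest over Polycomb (CpG-island-rich, hypomethylated) regions.
CPG_BY_LABEL <- c("Core-A" = 0.80, "Core-B" = 0.55,
                  "PcG-A" = 0.35, "PcG-B" = 0.20)
H3K27ME3_BY_LABEL <- c("Core-A" = 0.2, "PcG-A" = 2.0,
                       "PcG-B" = 2.0, "Core-B" = 0.3)

#' Which compartment a sub-compartment label belongs to
#' @param labels character vector of sub-compartment labels.
#' @return character vector "A"/"B".
#' @export
compartment_of <- function(labels) {
  ifelse(labels %in% c("Core-A", "PcG-A"), "A", "B")
}

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(expr)
}

geo_len <- function(n, mean_len) 1L + stats::rpois(n, max(0, mean_len - 1))

#' Simulate a genome model with planted sub-compartment structure
#'
#' Lays down contiguous blocks of the four sub-compartment labels
#' (Core-A, PcG-A, PcG-B, Core-B). Core-B blocks are always flanked by
#' PcG-B blocks, mirroring the tendency of Polycomb-B regions to sit at
#' compartment borders. Each bin carries a lamina-attachment propensity
#' (ordered Core-B > PcG-B > PcG-A > Core-A), a CpG-methylation propensity
#' (highest in Core-A) and an H3K27me3 level (high over PcG labels).
#'
#' @param config a [sim_config].
#' @return list of class `genome_model`: `binspec`, `labels` (per global
#'   bin), `lambda`, `cpg_propensity`, `h3k27me3`, `condition_effects`
#'   (named list of per-label additive shifts on lambda).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  bs <- binspec(stats::setNames(rep(config$chrom_length, config$n_chroms),
                                paste0("chr", seq_len(config$n_chroms))),
                config$bin_width)
  if (any(bs$n_bins < 10L)) stop("chromosome shorter than 10 bins")
  mb <- config$mean_block_bins
  labels <- with_seed(config$seed, {
    unlist(lapply(bs$n_bins, function(n) {
      lab <- character(0)
      while (length(lab) < n) {
        kind <- sample(c("Core-A", "PcG-A", "B-cassette"), 1L,
                       prob = c(0.30, 0.30, 0.40))
        block <- if (kind == "B-cassette") {
          # Core-B core flanked on both sides by PcG-B
          c(rep("PcG-B", geo_len(1L, mb / 2)),
            rep("Core-B", geo_len(1L, mb)),
            rep("PcG-B", geo_len(1L, mb / 2)))
        } else rep(kind, geo_len(1L, if (kind == "Core-A") 1.4 * mb else mb))
        lab <- c(lab, block)
      }
      lab[seq_len(n)]
    }), use.names = FALSE)
  })
  structure(list(
    binspec = bs,
    labels = labels,
    lambda = unname(LAMBDA_BY_LABEL[labels]),
    cpg_propensity = unname(CPG_BY_LABEL[labels]),
    h3k27me3 = unname(H3K27ME3_BY_LABEL[labels]),
    condition_effects = list(
      vehicle = c("Core-A" = 0, "PcG-A" = 0, "PcG-B" = 0, "Core-B" = 0),
      # EZH2 inhibition shifts Polycomb-B loci toward the lamina
      EZH2i = c("Core-A" = 0, "PcG-A" = 0, "PcG-B" = 0.3, "Core-B" = 0))
  ), class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", x$binspec$total_bins, "bins\n")
  print(round(table(x$labels) / length(x$labels), 3))
  invisible(x)
}

condition_lambda <- function(model, condition) {
  eff <- model$condition_effects[[condition]]
  if (is.null(eff)) stop("unknown condition: ", condition)
  pmin(1, pmax(0, model$lambda + unname(eff[model$labels])))
}

pair_affinity <- function(l1, l2, beta) {
  ifelse(l1 == l2, beta,
         ifelse(compartment_of(l1) == compartment_of(l2), sqrt(beta), 1))
}

#' Simulate methylation-tagged contacts
#'
#' Draws intra-chromosomal contacts with loci sampled proportionally to
#' `d^-alpha` times the label affinity (see [sim_config()]), then tags each
#' end with CpG/GpC site counts. GpC methylation is driven by a latent
#' lamina-proximal indicator: with probability `rho` both ends share a
#' single Bernoulli draw at the mean of their propensities, otherwise each
#' end draws independently — this coupling is what makes the per-read
#' lamina states of contacting loci correlate. CpG states are drawn per end
#' with no coupling. Condition effects shift the lamina propensity before
#' sampling.
#'
#' @param model a `genome_model`.
#' @param config a [sim_config].
#' @param condition condition name registered in `model$condition_effects`.
#' @param replicate_seed RNG seed for this replicate.
#' @return a `tagged_contacts` data.frame (mapq fixed at 30, distinct
#'   fragment ids).
#' @export
simulate_contacts <- function(model, config, condition = "vehicle",
                              replicate_seed = 1L) {
  stopifnot(inherits(model, "genome_model"), inherits(config, "sim_config"))
  lam <- condition_lambda(model, condition)
  bs <- model$binspec
  with_seed(replicate_seed, {
    # per-chromosome pair weights: decay times label affinity
    per_chrom <- lapply(names(bs$chrom_sizes), function(ch) {
      gb <- chrom_bins(bs, ch)
      n <- length(gb)
      pr <- which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
      d <- pr[, 2L] - pr[, 1L]
      lab <- model$labels[gb]
      w <- d^(-config$alpha) * pair_affinity(lab[pr[, 1L]], lab[pr[, 2L]],
                                             config$beta)
      list(chrom = ch, gb = gb, i = pr[, 1L], j = pr[, 2L], w = w)
    })
    tot_w <- vapply(per_chrom, function(x) sum(x$w), numeric(1))
    n_per <- stats::rmultinom(1L, config$n_contacts, tot_w)[, 1L]
    pieces <- lapply(seq_along(per_chrom), function(k) {
      pc <- per_chrom[[k]]
      m <- n_per[[k]]
      if (m == 0L) return(NULL)
      sel <- sample.int(length(pc$w), m, replace = TRUE, prob = pc$w)
      bi <- pc$i[sel]; bj <- pc$j[sel]
      w <- bs$bin_width
      L <- bs$chrom_sizes[[pc$chrom]]
      draw_pos <- function(b) {
        lo <- (b - 1L) * w
        lo + floor(stats::runif(length(b)) * (pmin(lo + w, L) - lo))
      }
      pos1 <- draw_pos(bi); pos2 <- draw_pos(bj)
      # enforce the >= 1 kb separation the read-level filter assumes
      for (it in 1:50) {
        close <- abs(pos1 - pos2) < 1000
        if (!any(close)) break
        pos1[close] <- draw_pos(bi[close])
        pos2[close] <- draw_pos(bj[close])
      }
      gi <- pc$gb[bi]; gj <- pc$gb[bj]
      li <- lam[gi]; lj <- lam[gj]
      shared <- stats::runif(m) < config$rho
      z_shared <- stats::rbinom(m, 1L, (li + lj) / 2)
      z1 <- ifelse(shared, z_shared, stats::rbinom(m, 1L, li))
      z2 <- ifelse(shared, z_shared, stats::rbinom(m, 1L, lj))
      n_gpc1 <- 1L + stats::rpois(m, config$mu_sites)
      n_gpc2 <- 1L + stats::rpois(m, config$mu_sites)
      k_gpc1 <- stats::rbinom(m, n_gpc1,
                              ifelse(z1 == 1L, config$p_gpc_on, config$p_gpc_off))
      k_gpc2 <- stats::rbinom(m, n_gpc2,
                              ifelse(z2 == 1L, config$p_gpc_on, config$p_gpc_off))
      c1 <- stats::rbinom(m, 1L, model$cpg_propensity[gi])
      c2 <- stats::rbinom(m, 1L, model$cpg_propensity[gj])
      n_cpg1 <- 1L + stats::rpois(m, config$mu_sites)
      n_cpg2 <- 1L + stats::rpois(m, config$mu_sites)
      k_cpg1 <- stats::rbinom(m, n_cpg1,
                              ifelse(c1 == 1L, config$p_cpg_on, config$p_cpg_off))
      k_cpg2 <- stats::rbinom(m, n_cpg2,
                              ifelse(c2 == 1L, config$p_cpg_on, config$p_cpg_off))
      data.frame(chrom1 = pc$chrom, pos1 = pos1,
                 strand1 = sample(c("+", "-"), m, replace = TRUE),
                 frag1 = 0, chrom2 = pc$chrom, pos2 = pos2,
                 strand2 = sample(c("+", "-"), m, replace = TRUE),
                 frag2 = 0, mapq = 30,
                 n_cpg1 = n_cpg1, n_cpg_meth1 = k_cpg1,
                 n_gpc1 = n_gpc1, n_gpc_meth1 = k_gpc1,
                 n_cpg2 = n_cpg2, n_cpg_meth2 = k_cpg2,
                 n_gpc2 = n_gpc2, n_gpc_meth2 = k_gpc2,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, pieces)
    if (is.null(df)) df <- empty_contacts()
    if (nrow(df)) {
      df$frag1 <- 2 * seq_len(nrow(df)) - 1
      df$frag2 <- 2 * seq_len(nrow(df))
    }
    class(df) <- c("tagged_contacts", "data.frame")
    df
  })
}

#' Simulate replicate lamina-methylation tracks
#'
#' Per-bin replicate value is a logistic-bounded noisy readout of the
#' lamina propensity: `plogis(lambda_i + condition_shift + N(0, noise_sd))`.
#' Bounded in (0,1) and monotone in the propensity, which is all downstream
#' z-scoring relies on.
#'
#' @param model a `genome_model`.
#' @param condition condition name.
#' @param n_replicates number of replicate tracks.
#' @param noise_sd replicate noise sd (on the logit-input scale).
#' @param seeds integer vector of per-replicate seeds (length
#'   `n_replicates`).
#' @return list of [binned_track].
#' @export
simulate_replicate_tracks <- function(model, condition = "vehicle",
                                      n_replicates = 3L, noise_sd = 0.05,
                                      seeds = seq_len(n_replicates)) {
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (length(seeds) != n_replicates) stop("need one seed per replicate")
  eff <- model$condition_effects[[condition]]
  if (is.null(eff)) stop("unknown condition: ", condition)
  shift <- unname(eff[model$labels])
  lapply(seeds, function(s) with_seed(s, {
    eps <- stats::rnorm(model$binspec$total_bins, 0, noise_sd)
    binned_track(model$binspec, stats::plogis(model$lambda + shift + eps))
  }))
}

#' Simulate replicate tracks with a planted shift on chosen bins
#'
#' Generic z-scale generator for segmentation benchmarks: replicate value
#' is `baseline + shift * planted + N(0, noise_sd)` per bin.
#'
#' @param bs a [binspec].
#' @param planted logical per-bin vector of bins carrying the shift.
#' @param shift additive planted effect.
#' @param noise_sd replicate noise sd.
#' @param n_replicates number of tracks.
#' @param seeds per-replicate seeds.
#' @param baseline per-bin baseline (default 0).
#' @return list of [binned_track].
#' @export
simulate_planted_tracks <- function(bs, planted, shift, noise_sd,
                                    n_replicates = 3L,
                                    seeds = seq_len(n_replicates),
                                    baseline = 0) {
  stopifnot(inherits(bs, "binspec"), length(planted) == bs$total_bins)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  mu <- baseline + shift * as.numeric(planted)
  lapply(seeds, function(s) with_seed(s, {
    binned_track(bs, mu + stats::rnorm(bs$total_bins, 0, noise_sd))
  }))
}

# Archetype feature centroids for the four sub-compartments on the
# (GpC-z, CpG-z, PC1-z) axes: Core-A low lamina / high CpG / A-like PC1;
# PcG-A low lamina / low CpG; PcG-B lamina-intermediate / CpG-poor / B-like
# PC1; Core-B most lamina-associated with intermediate CpG.
FEATURE_ARCHETYPES <- rbind(
  "Core-A" = c(gpc_z = -1.5, cpg_z = 1.5, pc1_z = 1.2),
  "PcG-A"  = c(gpc_z = -0.5, cpg_z = -1.2, pc1_z = 1.0),
  "PcG-B"  = c(gpc_z = 0.5, cpg_z = -1.5, pc1_z = -1.2),
  "Core-B" = c(gpc_z = 2.0, cpg_z = 0.5, pc1_z = -1.0))

#' Simulate replicate-averaged classification features from planted labels
#'
#' Draws (GpC-z, CpG-z, PC1-z) features around per-label archetype
#' centroids with isotropic Gaussian noise, emulating the replicate-averaged
#' z-scored feature space fed to sub-compartment k-means.
#'
#' @param model a `genome_model`.
#' @param noise_sd isotropic feature noise sd (default 0.5).
#' @param seed RNG seed.
#' @return list of three [binned_track]: `gpc_z`, `cpg_z`, `pc1_z`.
#' @export
simulate_subcompartment_features <- function(model, noise_sd = 0.5, seed = 1L) {
  stopifnot(inherits(model, "genome_model"))
  n <- model$binspec$total_bins
  mu <- FEATURE_ARCHETYPES[model$labels, , drop = FALSE]
  with_seed(seed, {
    out <- lapply(colnames(FEATURE_ARCHETYPES), function(f) {
      binned_track(model$binspec, mu[, f] + stats::rnorm(n, 0, noise_sd))
    })
    names(out) <- colnames(FEATURE_ARCHETYPES)
    out
  })
}

#' Truth regions for a label subset
#'
#' Maximal runs of bins whose planted label lies in `labels`, as genomic
#' intervals — e.g. the planted lamina-associated domains are the runs of
#' B-compartment labels.
#'
#' @param model a `genome_model`.
#' @param labels label subset (default the B sub-compartments).
#' @return a [region_set].
#' @export
planted_regions <- function(model, labels = c("PcG-B", "Core-B")) {
  mask_to_regions(model$binspec, model$labels %in% labels)
}

# maximal runs of TRUE bins -> genomic intervals on bin boundaries
mask_to_regions <- function(bs, keep, min_bins = 1L, score = NULL) {
  bc <- bin_coords(bs)
  out <- list()
  for (ch in names(bs$chrom_sizes)) {
    gb <- chrom_bins(bs, ch)
    r <- rle(keep[gb] & !is.na(keep[gb]))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- which(r$values & r$lengths >= min_bins)
    for (k in sel) {
      i0 <- gb[starts[k]]; i1 <- gb[ends[k]]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = bc$start[i0], end = bc$end[i1],
        score = if (is.null(score)) NA_real_ else
          mean(score[gb[starts[k]:ends[k]]]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(region_set())
  df <- do.call(rbind, out)
  region_set(df$chrom, df$start, df$end,
             score = if (!all(is.na(df$score))) df$score)
}
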