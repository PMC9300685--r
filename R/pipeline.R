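#' Validate a pipeline configuration
#'
#' A config is a flat named list (or a YAML file of one) with entries:
#' `chrom_sizes` (path), `pairs` (named list: condition -> vector of
#' limepairs paths; a `vehicle` condition is required), optional
#' `exclude_bed` (CpG islands) and `signal_bedgraph` (saddle ordering
#' signal), and numeric parameters `bin_width` (50000), `min_distance`
#' (1000), `z_exclude` (3), `k` (4), `lad_threshold` (0), `min_bins` (3),
#' `t_threshold` (4), `n_quantiles` (100), `n_shuffles` (100), `seed` (1).
#' All referenced files must exist; validation happens before any stage
#' runs.
#'
#' @param config named list or path to a YAML file.
#' @return the validated config with defaults filled in.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(bin_width = 50000L, min_distance = 1000, z_exclude = 3,
                   k = 4L, lad_threshold = 0, min_bins = 3L,
                   t_threshold = 4, n_quantiles = 100L, n_shuffles = 100L,
                   seed = 1L)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (is.null(config$chrom_sizes)) stop("config needs 'chrom_sizes'")
  if (is.null(config$pairs) || is.null(config$pairs$vehicle))
    stop("config needs 'pairs' with a 'vehicle' condition")
  files <- c(config$chrom_sizes, unlist(config$pairs),
             config$exclude_bed, config$signal_bedgraph)
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  if (config$min_bins < 1 || config$k < 2 || config$n_quantiles < config$k)
    stop("parameter out of range")
  config
}

#' Run the full analysis pipeline
#'
#' Executes, in order: contact reading and filtering; per-replicate GpC and
#' CpG methylation tracks with z-scoring and condition averages; balanced
#' contact matrices, distance-decay expected, OE and compartment PC1;
#' k-means sub-compartments; per-chromosome co-methylation matrices and
#' partner-conditioned summaries; LAD calling with replicate consensus;
#' differential-region calling for each non-vehicle condition; permutation
#' enrichment of differential regions against B-compartment borders and
#' PcG-B bins; H3K27me3-style saddle summaries. Every output file is listed
#' in a manifest with its stage and checksum; rerunning an identical config
#' reproduces identical outputs.
#'
#' @param config named list or YAML path, see [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress per-stage log lines.
#' @return (invisibly) the manifest data.frame (stage, file, md5).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  cfg <- pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(stage = character(), file = character(),
                         md5 = character(), stringsAsFactors = FALSE)
  log <- function(...) if (!quiet) message("[limehic] ", ...)
  emit <- function(stage, file) {
    manifest <<- rbind(manifest, data.frame(
      stage = stage, file = basename(file),
      md5 = unname(tools::md5sum(file)), stringsAsFactors = FALSE))
  }
  stage <- function(name, expr) {
    tryCatch(force(expr),
             error = function(e) stop("stage '", name, "' failed: ",
                                      conditionMessage(e), call. = FALSE))
  }

  bs <- stage("binspec", read_chrom_sizes(cfg$chrom_sizes, cfg$bin_width))
  exclude <- if (!is.null(cfg$exclude_bed)) read_bed(cfg$exclude_bed)

  # -- contacts: read + filter per condition/replicate -----------------
  contacts <- stage("contacts", lapply(cfg$pairs, function(paths) {
    lapply(paths, function(p) {
      raw <- read_limepairs(p, bs)
      f <- filter_contacts(raw, cfg$min_distance)
      log(basename(p), ": ", nrow(raw), " contacts, ",
          nrow(f$contacts), " kept (dropped ",
          paste(names(f$dropped), f$dropped, sep = "=", collapse = ", "), ")")
      f$contacts
    })
  }))

  # -- replicate methylation tracks ------------------------------------
  tracks <- stage("tracks", lapply(contacts, function(reps) {
    gpc <- lapply(reps, methylation_fraction_track, bs = bs, context = "GpC")
    cpg <- lapply(reps, methylation_fraction_track, bs = bs, context = "CpG",
                  exclude = exclude)
    list(gpc_z = lapply(gpc, zscore_track),
         cpg_z = lapply(cpg, zscore_track))
  }))
  avg <- lapply(tracks, function(tr)
    list(gpc_z = average_replicates(tr$gpc_z),
         cpg_z = average_replicates(tr$cpg_z)))
  for (cond in names(avg)) {
    f <- file.path(out_dir, paste0("gpc_z_mean_", cond, ".bedgraph"))
    write_bedgraph(avg[[cond]]$gpc_z, f); emit("tracks", f)
    f <- file.path(out_dir, paste0("cpg_z_mean_", cond, ".bedgraph"))
    write_bedgraph(avg[[cond]]$cpg_z, f); emit("tracks", f)
  }

  # -- contact matrices, balancing, OE, PC1 ----------------------------
  pooled_vehicle <- do.call(rbind, lapply(contacts$vehicle, as.data.frame))
  matstage <- stage("contactmat", {
    lapply(names(bs$chrom_sizes), function(ch) {
      raw <- contact_matrix(pooled_vehicle, bs, ch)
      w <- balance_matrix(raw)
      b <- balanced_matrix(raw, w)
      oe <- oe_matrix(b)
      gb <- chrom_bins(bs, ch)
      pc1 <- compute_pc1(oe, track_values(avg$vehicle$gpc_z)[gb],
                         orient = "negative")
      list(chrom = ch, oe = oe, pc1 = pc1)
    })
  })
  pc1_vals <- rep(NA_real_, bs$total_bins)
  for (m in matstage) pc1_vals[chrom_bins(bs, m$chrom)] <- m$pc1
  pc1_track <- binned_track(bs, pc1_vals)
  f <- file.path(out_dir, "pc1.bedgraph")
  write_bedgraph(pc1_track, f); emit("contactmat", f)
  compartments <- compartments_from_pc1(pc1_vals)

  # -- sub-compartments ------------------------------------------------
  subc <- stage("subcompartments",
                kmeans_subcompartments(avg$vehicle$gpc_z, avg$vehicle$cpg_z,
                                       zscore_track(pc1_track),
                                       k = cfg$k, z_exclude = cfg$z_exclude,
                                       seed = cfg$seed + 1L))
  sub_labels <- ifelse(subc$labels %in% SUBCOMP_LABELS, subc$labels,
                       NA_character_)
  f <- file.path(out_dir, "subcompartments.bed")
  write_bed(mask_labels_to_bed(bs, subc$labels), f)
  emit("subcompartments", f)

  # -- co-methylation statistics (GpC, vehicle) ------------------------
  cometh <- stage("cometh", lapply(matstage, function(m) {
    gb <- chrom_bins(bs, m$chrom)
    mats <- build_cometh_matrices(pooled_vehicle, bs, m$chrom, "GpC")
    A <- cometh_locus_methylation(mats)
    O <- cometh_observed(mats)
    On <- minmax_normalize_observed(O, compartments[gb], "GpC")
    summ <- partner_conditional_summary(On, sub_labels[gb],
                                        label_order = SUBCOMP_LABELS)
    list(chrom = m$chrom, mats = mats, A = A, O = O, On = On, summary = summ)
  }))
  for (cm in cometh) {
    f <- file.path(out_dir, paste0("cometh_M_", cm$chrom, ".triplets"))
    write_triplets(cm$mats$M, f, bs, cm$chrom); emit("cometh", f)
    f <- file.path(out_dir, paste0("cometh_summary_", cm$chrom, ".tsv"))
    utils::write.table(cm$summary$mean, f, sep = "\t", quote = FALSE)
    emit("cometh", f)
  }

  # -- LADs and consensus ----------------------------------------------
  lads <- stage("lads", lapply(tracks$vehicle$gpc_z, call_lads,
                               threshold = cfg$lad_threshold,
                               min_bins = cfg$min_bins))
  cons <- consensus_regions(lads, min_support = 2L,
                            min_len_bp = cfg$min_bins * bs$bin_width)
  f <- file.path(out_dir, "lads_consensus.bed")
  write_bed(cons, f); emit("lads", f)
  log("LADs: ", paste(vapply(lads, nrow, integer(1)), collapse = "/"),
      " per replicate, ", nrow(cons), " consensus")

  # -- differential regions + enrichment per treatment condition ------
  treats <- setdiff(names(cfg$pairs), "vehicle")
  b_domains <- mask_to_regions(bs, compartments %in% "B",
                               min_bins = cfg$min_bins)
  pcgb_bins <- mask_to_regions(bs, sub_labels %in% "PcG-B")
  for (cond in treats) {
    dr <- stage("differential",
                call_differential_regions(tracks[[cond]]$gpc_z,
                                          tracks$vehicle$gpc_z,
                                          t_threshold = cfg$t_threshold,
                                          min_bins = cfg$min_bins))
    f <- file.path(out_dir, paste0("differential_", cond, ".bed"))
    write_bed(dr, f); emit("differential", f)
    log("differential (", cond, "): ", nrow(dr), " regions")
    if (nrow(dr) && nrow(b_domains)) {
      enr <- stage("enrich", list(
        distance = permutation_enrichment(dr, b_domains, bs, "distance",
                                          n_shuffles = cfg$n_shuffles,
                                          seed = cfg$seed + 2L),
        jaccard = permutation_enrichment(dr, pcgb_bins, bs, "jaccard",
                                         n_shuffles = cfg$n_shuffles,
                                         seed = cfg$seed + 3L)))
      f <- file.path(out_dir, paste0("enrichment_", cond, ".tsv"))
      utils::write.table(data.frame(
        statistic = names(enr),
        observed = vapply(enr, `[[`, numeric(1), "observed"),
        null_mean = vapply(enr, function(e) mean(e$null), numeric(1)),
        ratio = vapply(enr, `[[`, numeric(1), "ratio"),
        p = vapply(enr, `[[`, numeric(1), "p")),
        f, sep = "\t", quote = FALSE, row.names = FALSE)
      emit("enrich", f)
    }
  }

  # -- saddle ----------------------------------------------------------
  signal <- if (!is.null(cfg$signal_bedgraph))
    track_values(read_bedgraph(cfg$signal_bedgraph, bs))
  else track_values(avg$vehicle$gpc_z)
  saddles <- stage("saddle", lapply(matstage, function(m) {
    gb <- chrom_bins(bs, m$chrom)
    saddle_by_signal(m$oe, sub_labels[gb], signal[gb],
                     n_quantiles = cfg$n_quantiles,
                     label_order = SUBCOMP_LABELS)
  }))
  for (k in seq_along(saddles)) {
    f <- file.path(out_dir,
                   paste0("saddle_", matstage[[k]]$chrom, ".tsv"))
    utils::write.table(saddles[[k]]$matrix, f, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    emit("saddle", f)
  }

  f <- file.path(out_dir, "manifest.tsv")
  utils::write.table(manifest, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  log("done: ", nrow(manifest), " outputs")
  invisible(manifest)
}

mask_labels_to_bed <- function(bs, labels) {
  keep <- labels %in% SUBCOMP_LABELS
  out <- list()
  for (lab in SUBCOMP_LABELS) {
    r <- mask_to_regions(bs, labels == lab & keep)
    rdf <- as.data.frame(r)
    if (nrow(rdf)) {
      rdf$label <- lab
      out[[lab]] <- rdf
    }
  }
  if (!length(out)) return(region_set())
  df <- do.call(rbind, out)
  region_set(df$chrom, df$start, df$end, label = df$label)
}
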