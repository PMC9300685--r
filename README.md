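# limehic

Analysis of methylation-tagged Hi-C: chromatin contacts whose bisulfite
reads also record, per read end, exogenous GpC methylation deposited by a
lamina-tethered methyltransferase (a proximity stamp for the nuclear
periphery) and endogenous CpG methylation. One library therefore supports
both population-scale genome organization (LADs, A/B compartments,
sub-compartments) and single-molecule questions: do the two loci of one
contact share their lamina state more often than chance?

The package is aimed at computational epigenomics work on nuclear
organization. It provides:

* per-read methylation classification (CpG ≥ 50%, GpC ≥ 10% of
  informative sites) and contact filtering (cis, distinct fragments,
  MAPQ > 0, ends ≥ 1 kb apart);
* methylation-stratified contact matrices M / U / Y and the
  co-methylation statistics built from them

  ```
  T_ij = M_ij + Y_ij + Y_ji + U_ij
  A_i  = mean over {j : T_ij > 0} of (M_ij + Y_ij) / T_ij
  O_ij = (M_ij + Y_ij) / T_ij
  OE_ij = (M_ij + U_ij) / T_ij − [A_i A_j + (1 − A_i)(1 − A_j)]
  ```

  where `OE` is the observed concordance of the two ends' methylation
  states minus the concordance expected under independence, plus
  min-max normalization, partner-conditioned summaries and per-locus
  log2 partner ratios;
* binned-track operations: fraction binning with padded exclusion
  regions (CpG islands), z-scoring, replicate averaging, rank
  transforms;
* contact-matrix balancing to equal row sums, cis distance-decay
  expected values, O/E, compartment PC1 (first eigenvector of the O/E
  Pearson correlation matrix, sign-oriented by a reference track), A/B
  interaction ratios, label interaction summaries and signal-ordered
  100-quantile saddle plots;
* segmentation: k-means sub-compartments (Core-A / PcG-A / PcG-B /
  Core-B, |z| > 3 exclusion, centroid-based naming), LAD calling by
  threshold runs (< 150 kb removed), 2-of-3 replicate consensus, and
  differential lamina regions by per-bin Welch t;
* permutation enrichment: within-chromosome shuffles, single-bp domain
  borders, median border distance and interval Jaccard with add-one
  empirical p-values;
* a synthetic-data generator that plants all of the above structure
  (power-law contact decay, label-affinity blocks, a latent shared
  lamina state coupling the two ends of each contact) so the entire
  pipeline is testable offline, and `run_pipeline()` to orchestrate the
  stages from a YAML config with a reproducible manifest.

## Worked example

```r
library(limehic)

cfg      <- sim_config()                 # two 20 Mb chromosomes, 1e5 contacts
model    <- simulate_genome(cfg)
contacts <- filter_contacts(simulate_contacts(model, cfg, "vehicle", 1))$contacts
bs       <- model$binspec

# co-methylation: is lamina state coordinated along single contacts?
mats <- build_cometh_matrices(contacts, bs, "chr1", "GpC")
mats
#> cometh_matrices [GpC] chr1: 400x400 bins, 50772 callable contacts (0 excluded uncallable)
oe <- cometh_oe(mats)
mean(oe[upper.tri(oe)], na.rm = TRUE)
#> [1] 0.0552

# compartments from the contact matrix, oriented by the lamina track
raw <- contact_matrix(contacts, bs, "chr1")
oem <- oe_matrix(balanced_matrix(raw, balance_matrix(raw)))
gpc <- methylation_fraction_track(contacts, bs, "GpC")
pc1 <- compute_pc1(oem, track_values(gpc)[chrom_bins(bs, "chr1")], "negative")
comp  <- compartments_from_pc1(pc1)
truth <- compartment_of(model$labels[chrom_bins(bs, "chr1")])
mean(comp == truth, na.rm = TRUE)
#> [1] 0.968

# B-compartment loci are more lamina-methylated when contacting B
r <- locus_partner_log_ratio(cometh_observed(mats), truth, "B", "A")
median(r[truth == "B"], na.rm = TRUE)
#> [1] 0.13
```

The mean co-methylation OE of 0.055 is positive because the generator
couples the two ends of each contact through a shared latent peripheral
state (`rho = 0.5`); with `rho = 0` it is statistically indistinguishable
from zero. PC1 recovers 96.8% of the planted compartment assignments on
this replicate, and the positive median log2 ratio reproduces the
partner-conditional asymmetry: a B locus is measurably more
lamina-methylated on the molecules that contact other B loci.

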