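---
title: "Models and methods behind limehic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind limehic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limehic)
```

## The measurement this package analyses

In a methylation-tagged Hi-C experiment, a GpC methyltransferase tethered
to Lamin B1 stamps exogenous GpC methylation onto DNA that visits the
nuclear periphery. Because the stamp is read from the same bisulfite
fragments that report chromatin contacts, every contact carries, on each
of its two ends, a per-read record of (a) lamina proximity (GpC context)
and (b) endogenous CpG methylation. This makes two kinds of questions
answerable from one library:

* population-scale: where are the lamina-associated domains (LADs), the
  A/B compartments, and the four sub-compartments (Core-A, PcG-A, PcG-B,
  Core-B), and how do they move under perturbation;
* single-molecule scale: do the two loci of one contact share their
  lamina state more often than chance — i.e. is radial position
  coordinated along an individual chromatin path?

`limehic` implements the full analysis chain for both, plus a synthetic
generator that plants known structure so every stage can be validated
end-to-end offline.

## Per-read classification and the co-methylation model

A read end with $n$ informative sites of which $k$ are methylated is
called methylated when $k/n \ge t$, with $t = 0.5$ for CpG and $t = 0.1$
for GpC (the lamina stamp is sparse, so a low threshold is appropriate).
The thresholds are applied inclusively: a read at exactly the threshold
is methylated. Ends with $n = 0$ are uncallable; the contact is then
excluded for that context and the exclusion is counted. Contacts are
retained only when intra-chromosomal, between different restriction
fragments, with MAPQ > 0 and with ends $\ge$ 1 kb apart.

Callable contacts on one chromosome populate three binned count
matrices: $M_{ij}$ (both ends methylated), $U_{ij}$ (both unmethylated),
and the asymmetric $Y_{ij}$ (end in bin $i$ methylated, end in bin $j$
not). From these:

$$T_{ij} = M_{ij} + Y_{ij} + Y_{ji} + U_{ij}$$

$$A_i = \operatorname{mean}_{j:\,T_{ij}>0}\;\frac{M_{ij}+Y_{ij}}{T_{ij}},
\qquad
O_{ij} = \frac{M_{ij}+Y_{ij}}{T_{ij}}$$

$$\mathrm{OE}_{ij} = \frac{M_{ij}+U_{ij}}{T_{ij}}
 - \bigl[A_i A_j + (1-A_i)(1-A_j)\bigr]$$

$\mathrm{OE}$ contrasts the observed concordance of the two ends'
states with the concordance expected if the ends drew their states
independently at their locus frequencies; it is zero in expectation
under independence and positive when contacting molecules coordinate
their lamina state. $A_i$ is computed as the unweighted mean over
partner bins with $T > 0$: a bare sum over partners would not lie in
$[0,1]$ and could not serve as a probability in the expected-concordance
term.

For cross-sample comparisons, $O$ is min-max normalized per sample with
the compartment means as anchors — for GpC the A-compartment mean maps
to 0 and the B mean to 1 (lamina methylation is low in A), and for CpG
the anchors swap. Values outside $[0,1]$ are allowed; the anchors are
what carry meaning. Partner-conditioned summaries average $O$ entries by
(locus label, partner label), and the per-locus statistic
$\log_2(\bar O_{i,\text{B partners}} / \bar O_{i,\text{A partners}})$
asks whether a locus is more lamina-methylated on molecules contacting
one class than another.

## Contact-matrix analysis

Raw binned counts are balanced by iterative correction to equal row
sums (relative spread $\le 10^{-5}$, at most 200 iterations, bins with
fewer than 2 nonzero entries masked, weights scaled so the mean
balanced row sum is 1). Equal row sums is the contract every downstream
statistic relies on; the specific balancing algorithm is not.

The cis expected value at bin separation $d$ is the mean balanced value
over unmasked pairs at $d$; $\mathrm{O/E}$ divides by it, so each
diagonal has mean 1 by construction. The compartment score is the first
eigenvector of the Pearson correlation matrix of the O/E columns,
computed per chromosome. An eigenvector's sign is arbitrary, so it is
oriented against a reference track: negative correlation with lamina
GpC (or positive with CpG methylation). A is assigned where the score
is positive, B where negative. The A/B ratio of a bin is
$\log_2 \overline{\mathrm{OE}}_{i,A} - \log_2 \overline{\mathrm{OE}}_{i,B}$
with the self-bin excluded.

Saddle summaries divide bins into 100 quantiles: each label class gets
quantiles proportional to its bin count by largest-remainder rounding
(minimum 1 for a non-empty class, exact total), and within a class,
bins are ranked by the ordering signal (H3K27me3 in the intended use),
ties broken by bin index, and split into equal-occupancy quantiles. The
saddle cell is the mean $\log_2$ O/E over bin pairs; condition
differences subtract matrices cell-wise and require identical layouts.

## Segmentation

Sub-compartments: k-means (k = 4, 10 restarts, seeded) on the
replicate-averaged z-scores of lamina GpC, CpG methylation and PC1.
Bins with any |z| > 3 are excluded first. Clusters are named from their
centroids — among the two highest-PC1 centroids the higher CpG-z is
Core-A and the other PcG-A; among the two lowest-PC1 centroids the
higher GpC-z is Core-B and the other PcG-B. Bins are clustered in
content-sorted order so results do not depend on input bin order.

LADs: maximal runs of bins with z strictly above 0 (the genome mean is
not evidence of attachment), runs of fewer than 3 bins (< 150 kb at
50 kb bins) removed, masked bins terminating runs. Replicate consensus
keeps positions covered by at least 2 of 3 replicate calls at base-pair
resolution — the calls need not coincide as whole regions — and then
re-applies the length filter. Differential regions use a per-bin Welch
(unequal-variance) t-statistic between condition replicate tracks;
gains are runs with $t > 4$ (an EZH2-inhibition-like contrast; 2 for a
DNMT1-inhibition-like one), losses the mirror image, with the same
run-length filter. No variance smoothing is applied across bins: at
n = 3 vs 3 the plain Welch statistic is heavy-tailed, which is exactly
what the high threshold absorbs.

## Permutation enrichment

Borders of a region set are single base pairs: the first covered base
and the last covered base (end − 1) of each merged region. The distance
of a query region to a border is zero if the border lies inside it.
Null distributions come from placing each query region uniformly at
random on its own chromosome, lengths preserved, placements
non-overlapping within a shuffle (rejection sampling, 1000 attempts
before error). The empirical p-value uses the add-one rule
$p = (1 + \#\{\text{null at least as extreme}\})/(N+1)$, one-sided
("less" for border distance, "greater" for Jaccard enrichment), and the
enrichment ratio is observed over null mean. The add-one rule keeps p
strictly positive and sub-uniform under the null, which the suite
verifies by a Kolmogorov–Smirnov calibration experiment.

## The synthetic generator

The generator is the package's test bed; its defaults are the reference
conditions every recovery experiment runs under.

* **Genome**: two 20 Mb chromosomes at 50 kb bins (800 bins). Labels
  are laid down in blocks (mean ~12 bins); Core-B blocks are always
  flanked by PcG-B blocks, mirroring the tendency of Polycomb-B to sit
  at compartment borders. Label frequencies land near
  25/20/25/30% for Core-A/PcG-A/PcG-B/Core-B.
* **Lamina propensity** $\lambda$ per label: Core-B 0.85, PcG-B 0.60,
  PcG-A 0.25, Core-A 0.15 — the ordering (constitutive heterochromatin
  most peripheral, Polycomb intermediate, active chromatin interior) is
  the structure the partner-conditioned statistics must recover. CpG
  propensity is highest in Core-A (0.80) and lowest over the
  CpG-island-rich, hypomethylated Polycomb classes (PcG-B 0.20).
* **Contacts**: $10^5$ intra-chromosomal contacts with pair weights
  $d^{-\alpha}\times$ affinity, $\alpha = 1$. Affinity is hierarchical:
  $\beta = 3$ for the same sub-compartment, $\sqrt\beta$ for the same
  compartment, 1 across compartments. A flat same-label-only affinity
  does not guarantee that the leading eigenvector of the correlation
  matrix splits A from B — the four label blocks decorrelate pairwise —
  so the intermediate same-compartment tier is what makes compartments
  recoverable by PC1, while keeping same-label enrichment strongest
  (the diagonal-dominance property).
* **Per-read methylation**: each end draws
  $n \sim 1 + \mathrm{Poisson}(8)$ sites. GpC methylation is driven by
  a latent peripheral indicator: with probability $\rho$ (default 0.5)
  both ends share a single Bernoulli draw at the mean of their
  propensities; otherwise each end draws independently. Site-level
  rates are 0.8 for a peripheral read and 0.1 for an interior one. This
  shared-state coupling is the mechanism that creates per-molecule
  coordination; at $\rho = 0$ the ends are exactly independent, which
  gives an analytically clean null ($\mathrm{OE} = 0$ in expectation) —
  the reason this construction was preferred over a copula. CpG states
  are drawn per end with no coupling. The EZH2i condition adds +0.3 to
  $\lambda$ on PcG-B before sampling.
* **Replicate tracks** are logistic-bounded noisy readouts of
  $\lambda$; planted-shift tracks (used for the segmentation
  benchmarks) add a stated shift on chosen bins with Gaussian replicate
  noise on the z scale. Feature tracks for the clustering benchmark
  draw from per-label archetype centroids in (GpC-z, CpG-z, PC1-z) with
  isotropic noise (sd 0.5); the centroids encode the qualitative
  geometry of the four classes and sit 2.1–5 noise-sd apart.

What the generator does **not** emulate: trans contacts, restriction
fragments, bisulfite conversion error, sequence composition, copy
number, centromeres/arms, and distance-dependent methylation biases. A
passing recovery test therefore demonstrates that the estimators invert
the generative structure they target at realistic noise, not that real
libraries are free of the artifacts listed above.

## Numerical choices

* Coordinates are 0-based half-open everywhere; 1-based sources must be
  converted at the boundary.
* Missing bins are masked, never zero-filled (zero is a legitimate
  methylation fraction); no operation unmasks a bin.
* z-scores use the sample sd (n − 1); replicates are z-scored
  genome-wide first and then averaged, not re-standardized.
* Ranks average ties.
* k-means naming fails loudly if the 2nd and 3rd PC1 centroids coincide
  within 1e-9 (the A/B split would be arbitrary).
* Balancing reports its final row-sum spread on non-convergence rather
  than returning approximate weights.
* Bins with $T_{ij} = 0$, empty label classes, zero partner means and
  the like propagate as masked values (NA), not as errors, except where
  a statistic becomes meaningless (min-max normalization with equal
  compartment anchors).

## Problem sizes

The validation suite runs the co-methylation oracle at $10^3$ contacts
over 20 bins (exact equality against per-contact enumeration), the
independence null and compartment recovery at $10^5$ contacts, the
segmentation and clustering benchmarks on the 800-bin default genome,
balancing contracts on 200×200 matrices, and the permutation
calibration on 50 null datasets of 40 regions at 200 shuffles each.
These sizes give stable statistics for every threshold tested while
keeping a full run in the low minutes on one core.

## Known limitations

* Per-chromosome matrices only; genome-wide summaries concatenate
  chromosomes. Trans contacts are out of scope.
* The bump-hunting region caller of the segmentation literature is
  reduced to threshold-run segmentation; with a threshold of 0 on
  z-scores and a minimum-run filter this is the operative definition,
  but smoothed callers may merge runs across single noisy bins where
  this one splits them.
* The balancing contract (equal row sums) is shared with Knight–Ruiz
  balancing but the weights are not numerically identical to KR's.
* `run_pipeline()` is a thin orchestration of the exported functions
  with a manifest; it is deterministic per config but has no resume or
  scheduling machinery.
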