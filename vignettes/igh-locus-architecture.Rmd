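---
title: "Modeling antigen-receptor locus architecture with ighfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling antigen-receptor locus architecture with ighfold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ighfold)
```

## The scientific problem

During B-cell development the mouse immunoglobulin heavy-chain (Igh) locus —
roughly 2.8 Mb on chromosome 12 carrying VH, DH, JH and constant gene
segments — contracts so that distal VH genes can reach the DH-JH
recombination center, enabling V(D)J recombination. Population Capture Hi-C
measures the average contact frequency between 20-kb bins of the locus, but
recombination happens in single cells, one conformation at a time. `ighfold`
provides the computational chain for studying this system end to end:

1. building, balancing, and distance-correcting binned contact matrices from
   contact-pair records;
2. inverse polymer modeling: fitting pairwise spherical-well energies so a
   coarse-grained beads-on-a-string ensemble reproduces the contact map, then
   reading single-structure statistics off the ensemble;
3. calling interchromosomal (trans) contacts of baited viewpoints by a
   modified Z-score on virtual-4C profiles;
4. spatial statistics for 3D DNA FISH spot tables that validate such
   contacts in single nuclei.

Seeded synthetic generators stand in for sequencing and imaging data, so the
entire pipeline is exercised by the test suite without downloads.

## The polymer model

The locus is a chain of `n` beads, one per 20-kb bin, with coordinates in
units of the bond length `a`. The model energy at `kT = 1` is

```
U = sum_bonds k_b (d_i - a)^2  +  sum_{|i-j| >= 2} u_ij(d_ij)
u_ij(d) = +Inf        d <  0.6 a     (hard core, all pairs)
        = eps_ij      0.6 a <= d < 1.5 a   (spherical well)
        = 0           d >= 1.5 a
```

with `eps_ij <= 0`: wells are attractive or neutral; repulsion is carried
entirely by the hard core. Two beads are "in contact" when their distance is
strictly below `1.5a`, the same radius as the well; the boundary point
`d = 1.5a` counts as non-contact.

Choices that the model statement leaves open, and how this package resolves
them:

* **Bonds.** Consecutive beads are joined by stiff harmonic springs,
  `k_b = 100 kT/a^2` by default. This keeps the chain connected while
  permitting simple single-bead moves; at `k_b = 100` the bond-length
  standard deviation is ~0.07a, so bonded geometry is essentially fixed.
* **Bonded pairs and the well.** The nonbonded well is skipped for
  `|i - j| = 1` because bonded neighbours sit permanently inside `1.5a`;
  including them would add a constant. Contact *counting* in the analyses,
  by contrast, uses the bare distance rule and therefore includes bonded
  neighbours.
* **Sampling.** Metropolis Monte Carlo with two move types proposed 1:1:
  single-bead Gaussian displacements, whose width is adapted toward ~40%
  acceptance during the first half of burn-in only (the production kernel is
  fixed, preserving detailed balance), and crankshaft rotations of short
  internal segments (at most 8 beads) about the axis through their flanking
  beads. Crankshaft moves leave distances inside the segment and to the two
  axis beads unchanged, which both speeds energy evaluation and improves
  mixing. Defaults: burn-in `200 n` sweeps, one snapshot every `20 n`
  sweeps, one chain per seed. Ensembles are bit-reproducible for a given
  seed because all randomness flows through R's RNG.

The sampler is validated against brute-force numerical integration of the
two-bond chain's Boltzmann weight: the bead-1 to bead-3 distance
distribution (Kolmogorov–Smirnov) and the 1–3 contact probability with and
without an attractive well must match the quadrature within Monte-Carlo
error. These checks run in the test suite at 5,000 snapshots.

## Inverse fitting of the well depths

`fit_polymer()` estimates the energy matrix from a target contact-probability
map by iterative-Boltzmann-style updates. Each iteration simulates an
ensemble under the current energies, measures its contact map `p_sim`, and
moves every eligible pair by

```
eps_ij <- clip( eps_ij + eta * log((p_sim_ij + delta) / (p_target_ij + delta)),
                [eps_min, 0] )
```

Pairs seen less often than targeted become more attractive. Defaults:
`eta = 0.3` kT per log-unit, `delta = 1/(2 * ensemble size)` (a pseudocount
at the resolution the ensemble can measure), `eps_min = -5` kT. Pairs with
`|i - j| <= 1` are excluded from fitting and from the goodness-of-fit
(Pearson r over unmasked long-range pairs): bonded geometry fixes them, so
they carry no information about the wells. Each iteration draws a fresh
sub-seed so the optimization cannot overfit one Monte-Carlo sample; the stop
rule is a correlation threshold (default r = 0.98) or the iteration budget,
and an error is raised only on sustained deterioration (five consecutive
decreases in r ending clearly below the best value seen), not on the
Monte-Carlo wobble that any stochastic objective shows near its plateau.

Because experimental maps are on an arbitrary coverage-normalized scale,
`prepare_target()` converts them to probabilities with a single global
factor chosen so the mean at genomic separation 2 — the shortest separation
the wells control — matches the neutral homopolymer's simulated mean at the
same separation, then clips at 1. This makes the target invariant to global
rescaling of the input map.

The fitting ensembles use a lighter schedule than standalone sampling
(burn-in `100 n`, thinning `10 n` sweeps) because each iteration only needs
a rough probability estimate; the final analysis ensemble should be drawn
with `simulate()` at the full schedule. On the packaged 40-bead recovery
scenario (two anchor stripes at beads 6 and 19, one distal attractive block,
600-structure target, 40 iterations of 300 structures) the fitted model's
map correlates with the target at r > 0.9 and the anchor rows are recovered
as clearly deeper than background — this is exactly the check the test suite
runs.

## Ensemble statistics

All single-structure statistics use the strict `< 1.5a` contact rule and
1-based bead indices. The packaged `igh_annotation()` places the 3' CTCF
binding elements (superanchor) at bead 6, the constant/Emu block at beads
9–16, IGCR1 at bead 19, DH genes on beads 18–21 (bead 19 carries D genes in
addition to IGCR1), and VH genes on beads 24–146 (123 VH beads). The four-bead
DH span interpolates between stated landmarks; its CTCF levels and
recombination scores are seeded synthetic placeholders, not measurements.

* `partners_per_bead()` — mean number of beads within the contact radius.
* `vd_stats()` — per-conformation fraction of VH beads touching at least one
  DH bead, plus V–D contact events per DH and per VH bead. Events are
  counted as bead pairs per conformation and summed, so the per-D and per-V
  totals are equal by construction (a conservation law the tests verify on
  random ensembles).
* `center_of_mass()` / `cm_distance_profiles()` — the CM is the plain
  average of bead coordinates; CMv restricts to VH beads. Conditional
  variants (`conditional_cmv_distance()`) report the conditioning subset
  size and return an explicit `NA` when the subset is empty, never a silent
  zero.
* `cluster_conformations()` — dissimilarity is either the root-mean-square
  difference of bead-to-bead distance matrices (rigid-motion invariant) or
  one minus the Jaccard overlap of long-range contact sets ("significant"
  interactions are all pairs within `1.5a` at `|i - j| >= 2`; no sharper
  definition is available). Agglomerative clustering uses average linkage
  and a configurable cut — the choice is open in the source material, and
  average linkage is the least shape-biased default for noisy structural
  dissimilarities.
* `spearman_cor()` — rank correlation with average ranks for ties and the
  t-approximation p-value, for relating V–D contact geometry to
  recombination scores.

## Trans-interaction calling

`virtual4c_bin_counts()` extracts the other ends of pairs with at least one
end in the baited viewpoint, drops all cis pairs, and accumulates the other
ends in fixed-grid 500-kb bins genome-wide. Bins are ineligible if they lie
on a viewpoint chromosome, within the first 3 Mb of any chromosome
(centromeric repeats), or overlap a blacklist/custom exclusion interval by
at least 1 bp — a conservative, deterministic rule. Counts are raw: the
outlier score is computed on unnormalized counts.

`modified_zscore()` implements the robust score
`0.6745 (x - median) / MAD` with `MAD = median(|x - median|)`; when the MAD
degenerates to 0 the denominator falls back to `1.253314 x mean absolute
deviation`, and if that is also 0 all scores are 0. The score is computed on
the pooled set of all eligible trans bins per viewpoint and replicate (not
per chromosome). A bin is significant when its score strictly exceeds 3.5
in *every* replicate; for those bins the replicate-average Z is reported,
and `log2(averageZ + 1)` profiles feed `cluster_profiles()` (Euclidean
distance, complete linkage, rows and columns — the defaults of the heatmap
tooling this mirrors). If both ends of a pair fall in different baited
regions, each viewpoint's run counts the pair once from its own side;
viewpoints are analyzed independently.

The synthetic null uses negative-binomial background counts (mean 20, size
5 by default): overdispersion makes the caller's calibration non-trivial.
The tests check that 10x spikes are always recovered in both replicates,
that no called bin overlaps an exclusion, and that the two-replicate false
positive rate is approximately the square of the single-replicate rate, as
independence predicts.

## FISH statistics

Nuclei are kept only when every channel has exactly two spots (one per
allele). The per-cell statistic is the closest cross-channel pair distance
(minimum of the four candidates). The probability that two independently,
uniformly placed loci fall within radius `r` in a spherical nucleus of
volume `V` is approximated by the volume ratio `(4/3) pi r^3 / V` — with
`r = 1` um and `V = 60` um^3 this is ~0.0698, conventionally quoted as 6.9% —
and the three-way association probability is its square (~0.48%). This
calculation deliberately ignores nuclear-boundary truncation and the
minimum-of-four selection, exactly as the standard calculation does; the
package's Monte-Carlo validator therefore fixes the focal locus at the
nucleus center (where the 1-um ball is fully interior), making the analytic
value exact for the simulated model. Distances measured in smaller nuclei
(thymocytes) are rescaled by a multiplicative volume-adjustment factor
(1.0601699 in the motivating data) before comparison.

Distance distributions are summarized in four brackets (<0.5, 0.5–0.8,
0.8–1, >1 um), half-open on the left edge of each bracket since the
conventional notation is ambiguous at the joins. Association frequencies
between cell types are compared by two-sided Fisher exact tests with
Bonferroni correction; observed proportions are compared against the
analytic random probability by exact binomial tests; distance distributions
across groups by Kruskal–Wallis with Dunn's Bonferroni-corrected pairwise
z-tests. For three-color experiments, the "closest trio" is the
cross-channel triple minimizing the sum of its three pairwise distances (no
sharper definition is available), and a nucleus is retained when at least
two of those three distances are below 1 um.

## What the synthetic data do and do not show

The generators emulate the statistical *structure* each stage assumes: a
pro-B-like energy landscape (anchor stripes + distal block), overdispersed
trans backgrounds with spiked outliers, and spherical nuclei with controlled
association frequencies. They do not emulate capture efficiency, mappability
or fragment-length biases, chromosome territories, nuclear-boundary effects
on FISH distances, or replicate-correlated backgrounds. Passing tests
therefore demonstrate that the algorithms are correct under their stated
models, not that the models capture every property of real Capture Hi-C or
imaging data. Headline statistics of the motivating study that require its
full-depth sequencing data (per-bead partner counts of 13–22 in pro-B cells,
the fraction of VH beads contacting a D bead, the 116 Igh trans partners)
are replaced here by directional and conservation properties on synthetic
ground truth.

## Numerical choices and problem sizes

* Balancing: iterative proportional fitting with re-symmetrization each
  sweep, relative row-sum tolerance 1e-6, 200 sweeps maximum, mass rescaled
  to the input; low-coverage bins (row sum below 0.2 x the median positive
  row sum by default) are masked first and stay zero.
* Distance correction divides by the mean unmasked value per diagonal;
  empty or zero diagonals are flagged invalid rather than divided.
* The 3-bead quadrature oracle integrates on a 301 x 301 x 801 grid; the
  largest routine test simulations are 5,000 snapshots of a 3-bead chain,
  a 40-bead fit with 300-structure iterations, and 100,000 simulated
  nuclei — sizes chosen so the whole suite runs in minutes on one CPU while
  keeping Monte-Carlo standard errors well below the tested tolerances.
* Default ensemble size for locus-scale analyses is 5001 conformations,
  matching the scale at which the single-structure statistics above are
  typically reported.

## A worked miniature

```{r example, eval = FALSE}
set.seed(1)
truth <- synth_energy_truth(40, anchors = c(6, 19), anchor_depth = -1.5,
                            block = c(26, 38), block_depth = -0.6)
target <- synth_target_map(truth, n_structures = 600, seed = 2)
fit <- fit_polymer(target$map, model_params(40), seed = 3)
summary(fit)
ensemble <- simulate(fit, nsim = 1000, seed = 4)
partners <- partners_per_bead(ensemble)
head(sort(partners, decreasing = TRUE))
```

Anchor beads come out with the largest partner counts, mirroring the
anchor-centric architecture the energies encode.

## Known limitations

* The sampler is a single-chain Metropolis scheme; for very deep wells
  (eps below about -3 kT across many pairs) mixing slows and crankshaft
  acceptance drops, which the provenance diagnostics and acceptance-rate
  warnings surface but do not fix.
* `eps` values are identified only up to the information content of the
  target map: distinct energy matrices can produce indistinguishable maps
  at finite ensemble size, so recovery claims are directional (anchors
  deeper than background) rather than pointwise.
* Loop extrusion, phase separation, confinement spheres, TAD calling, and
  compartment eigenvectors are out of scope.
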