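---
title: "Methods: allele-specific Hi-C analysis with diphic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific Hi-C analysis with diphic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, the tunable parameters, the
numerical choices, and the limits of the `diphic` pipeline. It states no
empirical result beyond what the test suite and `scripts/acceptance.R`
themselves compute.

## The problem

In an F1 hybrid between two divergent mouse strains, SNPs occur roughly
every 70–96 bp, so a read end overlapping a diagnostic SNP can be
assigned to the maternal or paternal homolog. A Hi-C pair with evidence
from one parent is allele-specific; a pair with no diagnostic SNP on
either end is allele-uncertain and only assignable probabilistically.
Downstream questions — does the inactive X fold into two superdomains,
where is the boundary, are escape genes peripheral in the 3D structure,
do imprinted genes contact more on the expressed allele — all consume
the resulting diploid contact maps.

## Haplotype segregation

Pairs are filtered to both-end MAPQ at or above 30 (the conventional
unique-mapping cutoff), deduplicated (two records are redundant when
both end coordinates coincide, in either end order; the first record
survives, so survivor order is stable), and classified from per-end
evidence codes M / P / . / X. Three choices here were genuinely open:

- *Conflicting evidence* (one end matching both parents) is discarded
  rather than treated as uncertain: such reads most plausibly carry a
  sequencing error at the diagnostic base, and the discard rate is
  reported by `segregate_pairs()`.
- *Deduplication runs before classification*, so category counts refer
  to unique molecules.
- *Inter-homolog pairs* (opposite parents on the two ends) are
  tabulated but excluded from all cis maps; inter-homologous contacts
  are rare and the normalization operates on intrachromosomal contacts
  only.

## Contact maps and normalization

Bins are fixed-width, 0-based, half-open (`floor(pos / resolution)`),
with supported resolutions of 1 Mb, 100 kb, and 40 kb; strand is
ignored for binning. Preprocessing zeroes the diagonal and the +/-1
off-diagonals (self-ligation products) and masks, per chromosome, the
`floor(0.02 * n)` bins with the lowest row-sum coverage. Coverage is
measured before the tridiagonal zeroing, including the diagonal; ties
break to the lower bin index, and bins left with no contacts after
zeroing are also masked, which makes preprocessing idempotent. The 2 %
exclusion is applied per chromosome because the analyses are dominated
by single-chromosome maps.

Iterative correction divides rows and columns by their marginal
relative to the mean unmasked marginal until the maximum relative
deviation of row sums is below `tol` (default 1e-4), then scales to
unit mean row sum rather than preserving the total — the convention of
the iterative-correction literature. The default iteration cap is 1000:
strongly bipartite maps are nearly block-decomposable, and the
alternating scaling converges slowly on them (hundreds of iterations at
the default tolerance, as the pipeline run report shows). Balanced maps
feed visualization and domain-level analysis; the bipartite index and
virtual-4C stages consume raw counts, since both are defined on contact
counts.

## Empirical-Bayes EM for allele-uncertain contacts

Allelic counts are modeled as `X ~ Poisson(lambda)` with a
`Gamma(alpha_G, beta_G)` prior whose hyperparameters are shared within
genomic groups: intrachromosomal diploid bin pairs of one
chromosome-haplotype at the same binned genomic distance, and
interchromosomal pairs per chromosome pair. Moment matching on the
Gamma–Poisson marginal gives `beta = m / (v - m)`, `alpha = m * beta`
from the group mean `m` and *population* variance `v` (the plug-in
empirical-Bayes convention; the sample/population distinction vanishes
for large groups). Under-dispersed groups (`v <= m`) fall back to a
near-point-mass prior (`beta = 1e3`, mean preserved), and an all-zero
group uses a configurable mean floor (1e-6).

Each uncertain contact at pooled bins (i, j) is distributed over its
candidate diploid placements with weights proportional to the
candidates' posterior-mean rates `(alpha_G + x) / (beta_G + 1)`.
Decisions this module had to make itself:

- *Candidates are cis-only* (both ends on the same haplotype), two per
  contact, mirroring the exclusion of inter-homolog contacts from the
  maps; a trans-homolog candidate set is a configuration away but not
  the default.
- *Initialization* uses weights proportional to the certain counts of
  each candidate with a pseudocount of 0.5, preventing zero-locking
  where one haplotype has no certain reads.
- *Distance groups* are one per integer bin distance at 1 Mb; at finer
  resolutions adjacent distances are merged until every group holds at
  least 50 bin pairs (`make_distance_groups()`).
- *Convergence* is declared when the largest absolute weight change in
  one iteration falls below `tol` (default 1e-3), with an iteration cap
  (default 50) and an honest convergence flag — on deep simulations the
  weight changes decay geometrically and convergence typically needs
  ~50–80 iterations, so tests that require the fixed point raise
  `max_iter`.

Mass is conserved exactly at every iteration: the inferred maternal
plus paternal totals equal the certain totals plus the number of
uncertain contacts. Per the study design the EM-inferred maps serve
finer-resolution (100 kb / 40 kb) analyses, while 1 Mb analyses use
certain-read maps only.

## Bipartite index and boundary significance

With boundary `h` on an `n`-bin map the index is
`BI = (f1 + f2) / (2 * f_inter)` with block mean frequencies taken over
all entries of each block — diagonal included, and masked bins
contributing zero counts while remaining in the denominators, exactly
as the formula sums. Raw allele-specific 1 Mb counts are the intended
input; BI is invariant to global rescaling, so balanced maps change
only the interpretation, not the invariance. `f_inter = 0` yields an
infinite index with a flag rather than an error.

The boundary scan restricts `h` to the central 80 % of bins (margin
0.1) to avoid degenerate tiny blocks, breaking ties toward smaller `h`.
Significance comes from re-evaluating BI at boundaries drawn uniformly
from the same margin-restricted range, excluding positions within 2
bins of `h` so the null is not contaminated by the boundary itself, and
a one-sided Z-test. Two caveats are deliberate: the Z-test is exact
only to the extent the null BI distribution is near normal — for the
planted and homogeneous regimes the calibration tests bracket the
rejection rate empirically — and scanning for `h` then testing the same
map inflates significance, so the workflow locates the boundary on the
inactive homolog and scores both homologs at that fixed boundary.

## 3D structure inference

Each homolog is a chain of beads, one per bin; counts are
`C_ij ~ Poisson(beta * d_ij(X)^alpha)` with `alpha = -3` fixed and the
log likelihood maximized over coordinates and `beta`. The `beta`
maximizer is closed-form (`sum C / sum d^alpha`), and the coordinate
step is L-BFGS with the analytic gradient; four alternations of the two
steps, each exact or ascent, give a non-decreasing likelihood trace.
Numerical choices:

- *Initialization*: classical MDS on the distance-decay transform
  `d_hat = C^(1/alpha)` of observed pairs (unobserved pairs set to 1.5x
  the largest estimate), plus per-start Gaussian jitter; 5 starts by
  default (3 in the heavier tests), best final likelihood wins.
- *Distance floor* 1e-6 guards the `d -> 0` singularity of `log d`.
- *Zero-count pairs stay in the likelihood* — they contribute the
  `-beta d^alpha` repulsion term, and the sum runs over all pairs.
- *Unmappable bins* (masked or zero-marginal) are excluded from the
  likelihood and interpolated linearly between flanking valid beads
  afterwards, flagged invalid.

Structures are identified only up to rigid motion and scale, so
comparisons use Procrustes superposition with translation, rotation,
reflection, and uniform scaling (closed-form SVD solution;
`vegan::procrustes` is the independent oracle in the tests). Bipartite
structures are intrinsically harder to recover than globular ones: the
inter-superdomain contact frequency is low, so the relative orientation
of the two clusters is weakly constrained and the Procrustes error is
dominated by that degree of freedom.

## Spatial enrichment

Superdomain centers are the exact centroids of the valid beads strictly
below and strictly above the hinge bead, which belongs to neither; the
printed formula of the source analysis divides the first sum by `h`
while summing `h - 1` beads, and this package implements the exact
centroid (a deviation-by-correction, flagged here). The chromosome
center is the origin by construction.

The periphery Z-test estimates the null by repeatedly resampling
`n_sample` genes (default 100) from the background pool and recording
the mean distance; the observed focal mean is then scored one-sided.
A single null sample would match the original procedure; the resampled
null gives a stable standard deviation. The test is well calibrated
when the focal set is small relative to the pool and of comparable size
to `n_sample`; when the focal set is a large fraction of the pool, the
finite-population coupling between the focal mean and the leave-out
null inflates the rejection rate — the calibration test uses 40 focal
genes in a pool of 400. Both the chromosome-center and
own-superdomain-center distances are computed; the Xi analyses default
to the superdomain-center distance, since the bipartite geometry makes
the chromosome center a point near neither superdomain.

Feature analysis partitions valid bins into the top and bottom 25 % of
feature density (`ceiling(0.25 n)` bins, ties included, sizes
reported), compares their distance distributions by a one-sided
Wilcoxon rank-sum test for rich-more-peripheral, and returns both
empirical CDFs. A constant track makes the quartiles degenerate and is
reported as `p = 1` with a flag.

## Virtual 4C

For each gene, all map columns overlapped by the gene body are summed
per allele (the TSS-bin-only alternative is a flag) and the ratio is
`log10((maternal + 1) / (paternal + 1))`, computed as a difference of
logarithms so swapping the maps negates every ratio exactly. Imprinted
candidates are confirmed by a one-sided exact binomial test toward the
putatively expressed allele with background proportion
`p0 = r / (1 + r)`, where `r` is the mean maternal/paternal RNA count
ratio over autosomal genes (paternal count > 0 to keep `r` finite) —
the conversion from a ratio to a proportion is this module's decision —
followed by Benjamini-Hochberg at q < 0.05. Escape genes require a mean
promoter PolII SNP read count of at least 5 over the ten 100-bp
intervals spanning TSS +/- 0.5 kb, boundary inclusive. The background
excludes genes sharing a 40 kb window with any focal gene, keeps one
gene per window (lowest start), drops genes with no contacts in the
pooled map, and is split into autosomal and X-linked sets. Focal and
background log-ratio distributions are compared by a two-sided
Kolmogorov-Smirnov test with the Wilcoxon rank-sum p and the median
shift reported alongside.

## What the simulator emulates, and what it does not

`make_structure()` builds confined random walks with near-unit bead
spacing: globular mode around one center, bipartite mode as two
clusters whose centers sit two cluster radii apart (radius 2.5 bead
units by default), joined at a hinge bead placed at the gap midpoint.
Only the two hinge-adjacent bonds exceed the backbone length — the
hinge is the region of least contact between superdomains, and this
sharp construction is what makes boundary recovery testable to +/- 1
bin. Contact maps are independent Poisson draws with rate
`beta * d^alpha` (`alpha = -3`; `beta` set from the target depth). Pair
records inherit the emitting haplotype's SNP code per end at the
informative rate (default 0.3 per end, i.e. ~51 % of pairs carry
evidence), with 0.5 % conflicting-evidence pairs, MAPQ drawn from
{60 with probability 0.95, 10 otherwise} so the filter is exercised,
and duplicates copying both end coordinates exactly at rate 0.05.
Planted gene effects multiply every contact touching a gene's bins by
the allelic multiplier and redraw counts, so the virtual-4C log-ratio
converges to `log10(m)`.

The simulator is deliberately not a chromatin polymer model: no
excluded volume, no loop extrusion, no TAD substructure, no
distance-dependent SNP density, no trans contacts, and no read
sequences (evidence codes are taken as given, since alignment is
upstream of this pipeline). Passing tests therefore demonstrate that
the *inference machinery* recovers what was planted under the stated
statistical model, not that real chromatin obeys that model. Duplicate
and uncertain-read fractions of real libraries are not published in
detail; the defaults are configurable, not calibrated.

## Problem sizes

The tests and the acceptance script run at sizes chosen to make the
statistical assertions stable while keeping the suite quick on a
laptop: 100-bin chromosomes at depth 1e5 for boundary recovery (20
seeds), 50-bin diploid simulations at depth 2e4 for the EM recovery
rate (20 seeds), depth 1e6 with 50 beads for structure recovery, 200
seeds for the calibration rates, and a 1000-bin 40 kb autosome at depth
3e5 for virtual 4C. The published full-data results (the 72.8–72.9 Mb
hinge position, the Table-1 p-values, TAD counts) require the original
sequencing libraries and are reproduced here only at the level of the
worked examples and planted-recovery properties.

## Known limitations

- The EM E-step weighting (proportional to posterior means) and its
  convergence criterion are this package's choices; the source analysis
  does not state them.
- The Z-tests assume approximate normality of resampled means and of
  the shifted-boundary null; both are checked empirically only within
  the tested regimes.
- Structure inference is non-convex; multi-start mitigates but does not
  eliminate local optima, and bipartite structures' inter-cluster
  orientation is weakly identified at realistic depth.
- No multi-boundary (k > 2) segmentation, no TAD calling, no
  statistical confidence estimation for individual contacts, and no
  inter-chromosomal normalization.
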