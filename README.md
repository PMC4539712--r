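# diphic

Allele-specific Hi-C analysis of diploid genomes in R.

In F1 hybrid mouse systems, dense SNPs between the parental strains let a
fraction of Hi-C read pairs be assigned to the maternal or paternal
homolog, giving separate contact maps for the two copies of each
chromosome. The motivating application is the inactive X chromosome (Xi),
which folds into two large "superdomains" of frequent intrachromosomal
contact separated by a hinge region, unlike the active X (Xa). `diphic`
implements the full computational path from SNP-annotated pair records to
that biology, plus a seeded synthetic diploid Hi-C simulator so every
stage is testable without sequencing data:

- **Haplotype segregation** — MAPQ filtering (default `>= 30`),
  PCR-duplicate removal, and classification of pairs into maternal /
  paternal / allele-uncertain / inter-homolog / discard by per-end SNP
  evidence.
- **Contact maps** — binned symmetric count matrices (1 Mb, 100 kb,
  40 kb), self-ligation tridiagonal zeroing, exclusion of the lowest-2 %
  coverage bins, iterative correction (matrix balancing).
- **Empirical-Bayes EM** for allele-uncertain pairs. Allelic counts are
  modeled as `X ~ Poisson(lambda)` with `lambda ~ Gamma(alpha_G, beta_G)`
  shared within groups *G*: intrachromosomal bin pairs of one
  chromosome-haplotype at the same genomic distance, and interchromosomal
  pairs per chromosome pair. Hyperparameters are fit by method of moments
  and uncertain contacts are distributed over their candidate diploid
  placements proportionally to posterior-mean rates, iterated to
  convergence.
- **Bipartite index** — with boundary `h` on an `n`-bin map,
  `BI = (f1 + f2) / (2 * f_inter)` where `f1`, `f2`, `f_inter` are the
  block mean contact frequencies within superdomain 1, within
  superdomain 2, and between them. Boundary location by BI scan;
  significance by a one-sided Z-test against randomly shifted
  boundaries.
- **3D structure inference** — beads-on-a-string Poisson metric scaling:
  counts `C_ij ~ Poisson(beta * d_ij(X)^alpha)` with `alpha = -3`,
  maximizing `sum_{i<j} C_ij alpha log d_ij + C_ij log beta -
  beta d_ij^alpha` by alternating a closed-form `beta` update with
  multi-start quasi-Newton ascent on the coordinates.
- **Spatial enrichment** — superdomain centroids, radial gene distances,
  a resampling Z-test for periphery enrichment of focal gene sets, and
  top/bottom-quartile feature-density analysis with a one-sided Wilcoxon
  rank-sum test.
- **Virtual 4C** — per-gene maternal/paternal contact sums and the
  pseudocounted `log10((maternal + 1) / (paternal + 1))` ratio, with
  binomial selection of imprinted genes, PolII-based selection of escape
  genes, windowed background construction, and Kolmogorov-Smirnov /
  Wilcoxon distribution comparisons.

## Worked example

The `analysis/` directory is a numbered workflow over the package
(simulate, segregate and bin, normalize, EM, bipartite, structure,
spatial, virtual 4C), writing its tables under `results/run/`:

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

A run with the default seed prints, among other lines:

```
kept 361468 unique high-quality molecules: 91787 maternal, 91409 paternal,
  176496 allele-uncertain (41157 MAPQ-removed, 17835 duplicates)
EM converged in 61 iterations; maternal-map correlation with truth:
  0.9999 (certain reads only) -> 1.0000 (inferred)
maternal X at boundary bin 40: BI = 231.21 (f1 = 22.99, f2 = 40.59,
  f_inter = 0.14), one-sided p = 2.66e-22
paternal X at boundary bin 40: BI = 2.61 (f1 = 34.52, f2 = 21.20,
  f_inter = 10.68), one-sided p = 0.456
worked-example BIs: brain Xa = 3.69, brain Xi = 4.19, patski Xa = 2.46,
  patski Xi = 3.32
```

Reading: the simulator planted a bipartite maternal X with its hinge at
bin 40; the scan recovers exactly that boundary, the maternal homolog's
bipartite index is overwhelmingly significant against shifted boundaries
while the globular paternal homolog is not, and the EM stage recovers the
true maternal map slightly better than certain reads alone. The
worked-example lines recompute the bipartite index from published block
mean contact frequencies for brain and Patski-cell libraries, giving
3.69 / 4.19 / 2.46 / 3.32 for Xa / Xi in the two systems.

Equivalent functionality is available programmatically via
`run_pipeline(default_config())`.

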