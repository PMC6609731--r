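# mitoirg4

Analysis of mitochondrial genomes that carry a large inverted repeat (IR):
G-quadruplex (G4DNA) motif detection, IR detection and genome partitioning,
compartment enrichment statistics, a phylogenetic paired t-test, and
GC-skew profiles — with a fully ground-truthed synthetic-genome generator
for validating every stage.

## The problem

Some fungal mitochondrial genomes (40–250 kb, circular) contain an inverted
repeat covering up to half the molecule: two near-identical copies in
opposite orientation separated by two single-copy regions (SC1, containing
*cox1*; SC2, flanked by *cox3* and *rps3*). The same genomes are unusually
dense in sequence motifs capable of forming four-stranded G-quadruplex DNA.
Asking whether those motifs are enriched inside the repeat, depleted in
coding sequence, and whether the IR–SC contrast holds across species once
phylogeny is accounted for, requires a reproducible chain of analyses that
this package provides as tested R functions.

## Methods at the core

* **G4 scanning** — per-base scores (+min(k,4) for a G in a run of k,
  −min(k,4) for C, 0 otherwise) averaged over a sliding window of w = 25 nt;
  windows with |mean| ≥ s are merged into sign-homogeneous regions
  (strict s = 1.7, relaxed s = 1.2), and regions overlapping a
  previously-kept region by more than 50% of their length are eliminated.
* **IR detection** — 21-mer seeding of the sequence against its reverse
  complement, collinear chaining, ungapped X-drop extension, arm identity
  ≥ 0.99; rotation-invariant on circular genomes. A depth-track detector
  (median-normalized, 201-bp sliding median, band [1.75, 2.5]×) covers the
  collapsed-assembly case.
* **Compartment statistics** — exon/intron/intergenic partition built from
  the conserved gene set (*cox1–3*, *cob*, *nad1–6*, *atp6/8/9*, *rps3*,
  rRNAs *rns*/*rnl*); observed vs expected motif counts tested with a
  χ² goodness of fit, E_i = N·L_i/L; exonic percentages and motif densities
  inside vs outside the IR.
* **Phylogenetic paired t-test** — per-species differences d = x − y
  modeled as MVN(μ·1, σ²V(λ)) with V(λ) the Brownian tree covariance under
  Pagel's λ; λ profiled by ML over [0, 1], μ and σ² by GLS, t = μ̂/SE(μ̂)
  with df = n − 2 (n − 1 on star trees, where the test reduces exactly to
  the classical paired t-test).
* **GC skew** — per-window (G−C)/(G+C) and its cumulative curve, whose
  extrema are classical replication-origin candidates.

See `vignettes/methods.Rmd` for assumptions, parameter rationale and known
limitations (including small-sample calibration of the phylogenetic test).

## Worked example

Generate a 120-kb circular genome with a planted 30-kb IR (motif densities
1.0/kb inside the repeat, 0.4/kb outside), then run the pipeline:

```r
library(mitoirg4)

spec  <- synthetic_spec(genome_length = 120000, ir_arm_length = 30000)
truth <- generate_genome(spec, seed = 42)

ir <- find_inverted_repeat(truth$genome)
ir
#> IRAnnotation: arms 30000 bp (identity 1.0000)
#>   arm1 [0,30000)  arm2 [63000,93000)  genome 120000 bp

partition_ir(truth$genome, ir, truth$features)$borders
#>       border position gene_before gene_after
#> 1 arm1_start        0        rps3        rns
#> 2   arm1_end    30000        cox2       cox1
#> 3 arm2_start    63000        atp9       cox2
#> 4   arm2_end    93000         rns       cox3

en <- compartment_enrichment(truth$genome, truth$features, ir = ir)
en$density
#> density_IR density_SC
#>        1.0        0.4
round(en$exon_pct, 2)
#>    SC    IR
#> 15.42 31.33
```

The detector recovered the planted arm coordinates exactly; the measured
motif densities equal the planted rates (every planted motif found, no
false positives — the generator caps background G/C runs so the strict
threshold is unreachable by chance); and the exonic percentage is higher
inside the IR than in the single-copy regions, the configuration the
compartment statistics are designed to quantify.

Motif depletion in coding sequence, on a genome planted with 0 motifs/kb in
exons, 0.3 in introns and 1.5 in intergenic DNA:

```r
sp <- synthetic_spec(genome_length = 100000, ir_arm_length = 0,
                     g4_rate_per_kb = list(exon = 0, intron = 0.3, intergenic = 1.5))
tr <- generate_genome(sp, seed = 7)
compartment_enrichment(tr$genome, tr$features)$enrichment
#> Chi-square goodness of fit: X2 = 32.02, df = 2, p = 1.114e-07
#>           exon intron intergenic
#> observed  0.00   2.00     113.00
#> expected 21.45   6.32      87.23
```

And the cross-species comparison on a 12-tip tree with a true mean IR−SC
difference of 0.3:

```r
tree <- ape::rphylo(12, birth = 1, death = 0)
sim  <- simulate_paired_traits(tree, mu = 0.3, sigma = 0.1, lambda = 1, seed = 9)
phyl_paired_ttest(tree, sim$x, sim$y)
#> Phylogenetic paired t-test: mu = 0.2936 (SE 0.1112), lambda = 1.000
#>   t = 2.64, df = 10, p = 0.02472
```

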