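---
title: "Methods: inverted repeats, G4 motifs and compartment statistics in mitochondrial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inverted repeats, G4 motifs and compartment statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoirg4)
```

## The analysis this package implements

Fungal mitochondrial genomes are circular molecules of roughly 40--250 kb
that can carry a large inverted repeat (IR): two near-identical sequence
copies in opposite orientation, separated by two single-copy regions (SC1
and SC2), with the IR occupying up to about half of the molecule. Such
genomes are also unusually rich in sequence motifs capable of forming
G-quadruplex DNA (G4DNA), four-stranded structures built from stacked
guanine tetrads that are associated with double-stranded breaks and
recombination. `mitoirg4` packages the analyses needed to study the
relationship between the two phenomena:

1. a run-based sliding-window G4 motif scanner with overlap elimination;
2. inverted-repeat detection, from a finished sequence or from a read-depth
   track, and partitioning of the genome into IR/SC regions;
3. compartment statistics: observed versus expected motif counts in exons,
   introns and intergenic DNA (chi-square goodness of fit), exonic-DNA
   percentages inside and outside the IR, and IR-versus-SC motif densities;
4. a phylogenetic paired t-test for comparing paired per-species densities
   across a phylogeny under Pagel's lambda;
5. windowed and cumulative GC-skew profiles;
6. a synthetic-genome generator producing all of the above inputs with
   known ground truth.

All coordinates inside the package are 0-based half-open; conversion to and
from the 1-based inclusive conventions of GFF3 and GenBank happens only at
the I/O boundary. This keeps interval arithmetic (unions, complements,
midpoints, tiling checks) free of off-by-one ambiguity.

## G4 motif scoring

Each base receives an integer score: a `G` in a run of $k$ consecutive
guanines scores $+\min(k, 4)$, a `C` in a run of $k$ cytosines scores
$-\min(k, 4)$, and `A`/`T`/`N` score 0. A window of width $w$ (default 25
nt) slides with step 1; a window is a hit when the absolute mean of its
per-base scores reaches the threshold $s$. Two parameter sets are
conventional: *strict* ($w = 25$, $s = 1.7$) and *relaxed* ($w = 25$,
$s = 1.2$).

Overlapping or adjacent hit windows of the same sign merge into maximal
regions; a sign change terminates a region, because a G-rich and a C-rich
tract are distinct candidate quadruplexes (one on each strand). The region
score is the signed mean of its peak window rather than the whole-region
mean: the peak is stable under region extension and carries the same
threshold semantics as the window test. Positive scores mean G4 potential
on the forward strand, negative scores on the complement; both strands are
counted in all densities.

Because merged regions from nearby windows can overlap heavily, a greedy
elimination pass removes any motif whose overlap with an already-retained
motif exceeds half of its own length (strictly greater than 50%, so a
borderline exact-half overlap is kept). The default priority is descending
absolute score with ties to the smaller start, which keeps the strongest
representative of a cluster; positional priority is available
(`deduplicate_motifs(order = "position")`).

Two scanning choices are deliberate: `N` bases score 0 and never abort a
window, and circular wrap-around scanning is off by default so that a scan
of a deposited, linearized record reproduces exactly; `scan_params(circular
= TRUE)` enables wrapping, in which case regions crossing the origin are
reported with `end` greater than the genome length.

## Inverted-repeat detection

On a finished genome the two IR copies are present in full, so the IR is
findable by comparing the sequence against its own reverse complement.
Detection proceeds in three stages:

* **Seeding.** All exact matches of length $k = 21$ between the sequence
  and its reverse complement, found with a k-mer index. For a circular
  genome the sequence is doubled first, which makes the search
  rotation-invariant; candidate pairs are then normalized modulo the genome
  length and pairs overlapping on the circle are discarded.
* **Chaining.** Seeds on the same diagonal (which is where the two arms of
  one inverted pair accumulate) are clustered, tolerating gaps caused by
  isolated substitutions between the copies.
* **Extension.** Each chained block pair is extended ungapped in both
  directions under an X-drop rule (match $+1$, mismatch $-3$, drop 30) and
  trimmed back to the maximal-scoring endpoint. The candidate is kept if
  the final arm-to-arm identity reaches `min_identity` (default 0.99) and
  the arm is at least `min_arm` (default 1000 bp).

The X-drop rule deserves a note. A stopping rule phrased directly as
"extend while overall identity stays above 0.99" drifts hundreds of bases
into unrelated flanking sequence after a long exact arm, because random
sequence matches an inverted partner at 25% per base and a 30-kb exact arm
leaves a budget of 300 tolerated mismatches. X-drop with trim-to-maximum
stops at the true boundary and still crosses isolated substitutions inside
diverged arms; the global identity filter is applied to the finished arm
pair. Among surviving candidates the longest arm wins, with ties broken by
higher identity and then smaller start. Equal-length arms, disjointness,
and the tiling identity $2\,\mathrm{arm} + |SC1| + |SC2| = L$ are enforced
by construction. A genome that is one whole-length palindrome is rejected
explicitly, since its single-copy regions would be empty.

Before the copies are resolvable by assembly, the IR shows up instead as a
2-fold step in read depth (the assembler collapses the two identical
copies). `detect_duplication_from_depth()` normalizes a per-base depth
track by its median, smooths with a 201-bp sliding median, and reports
maximal runs with normalized depth in $[1.75, 2.5]$ of at least 2 kb. The
band is deliberately wide: Poisson noise at typical coverage moves
single-base values far from 2.0, and the smoothing window trades boundary
sharpness (about $\pm 100$ bp) against run stability.

SC naming follows gene content: SC1 is the single-copy region containing
*cox1* (midpoint rule) when an annotation is available, otherwise the
longer region, with a logged message. The border report lists, for each of
the four IR/SC junctions, the nearest gene on either side and flags genes
partially overlapping an arm — the pattern expected from ongoing IR
expansion and contraction.

## Compartments and enrichment

The "exon" compartment is the union of exonic spans of the conserved
mitochondrial gene set — *cox1--3*, *cob*, *nad1--6*, *atp6*, *atp8*,
*atp9*, *rps3* — plus the full spans of the two rRNA subunits (*rns*,
*rnl*), which are not protein-coding but produce large functional
transcripts. *nad4L* is included by default (it belongs to the core set of
these genomes) and can be excluded (`include_nad4L = FALSE`). Gene-name
matching is case-insensitive with a configurable alias table (`CytB` →
`cob`, `nd4` → `nad4`, `rrnL` → `rnl`, ...). The "intron" compartment is
the introns of those genes; everything else is intergenic. Priority is
exon > intron > intergenic for bases claimed by overlapping features of
different genes, and compartment lengths are asserted to tile the genome on
every run. tRNAs are deliberately not exonic: they are neither in the
conserved set nor rRNA.

Each motif is assigned to the compartment of its midpoint base
($\lfloor(start+end)/2\rfloor$) — deterministic and unbiased for motifs
much shorter than compartments. Expected counts assume an unbiased
distribution: $E_i = N \cdot L_i / L$, which sums to $N$ exactly. The test
is the plain chi-square goodness of fit, $\chi^2 = \sum_i (O_i - E_i)^2 /
E_i$ with $df$ = retained compartments $- 1$, no continuity correction;
compartments with $E_i = O_i = 0$ are dropped, $E_i = 0$ with $O_i > 0$ is
an error, and expected counts below 5 attach a small-count warning rather
than switching to an exact test, keeping the reported statistic the one
named in the analysis.

IR-versus-SC densities use single-copy counting by default: motifs with
midpoints in arm 1 divided by one arm length, against motifs in SC1 ∪ SC2
divided by the combined SC length. Since the copies are near-identical,
counting both copies over both arm lengths gives the same density for
IR-symmetric motif sets (`ir_copies = 2` is available); the choice is a
scale convention, not a substantive one. The exonic percentage inside the
IR is likewise computed over one arm.

## The phylogenetic paired t-test

Per-species paired differences $d_i = x_i - y_i$ (here: IR minus SC motif
density) are modeled as multivariate normal with mean $\mu \mathbf{1}$ and
covariance $\sigma^2 V(\lambda)$, where $V(\lambda)$ is the Brownian-motion
covariance of the tree (shared root-to-tip path lengths) with off-diagonal
entries multiplied by Pagel's $\lambda \in [0, 1]$. Given $\lambda$, $\mu$
and $\sigma^2$ have closed-form GLS/ML solutions; $\lambda$ is profiled by
bounded one-dimensional optimization (tolerance $10^{-8}$), with the
boundary values 0 and 1 evaluated explicitly because the optimum frequently
sits on a boundary the interior search never visits exactly.

Inference choices, made deliberately and documented here:

* $SE(\hat\mu) = \sqrt{\hat\sigma^2_{GLS} / (\mathbf{1}' V(\hat\lambda)^{-1}
  \mathbf{1})}$ with the bias-corrected residual variance (divisor $n-1$),
  not the ML divisor $n$;
* $df = n - 2$ by default (one each for $\mu$ and $\lambda$), configurable
  to $n - 1$;
* on a star tree all off-diagonal covariances vanish, $\lambda$ is
  unidentifiable and is not counted: $df$ falls back to $n - 1$ and the
  statistic reduces *algebraically* to the classical paired t-test, a
  reduction the test suite checks to $10^{-6}$;
* duplicate zero-length tips making $V$ singular are jittered by $10^{-10}$
  with a warning; identical $x$ and $y$ give $t = 0$, $p = 1$ rather than
  0/0.

**Known limitation.** Treating the profiled $\hat\lambda$ as known is
anti-conservative in small samples: when $\hat\lambda$ falls below 1 by
chance, $\mathbf{1}'V(\hat\lambda)^{-1}\mathbf{1}$ overstates the
information about $\mu$, especially on trees with short terminal branches.
The calibration study in the acceptance suite (1,000 null simulations under
a $\lambda = 1$ Brownian model on a 12-tip pure-birth tree) measures a
type-I error slightly above the nominal 0.05 — around 0.08--0.11 depending
on the tree — and the reference implementation of this test shows the same
behavior on the same data. With the t-form of the statistic fixed, only a
bootstrap or Bayesian treatment of $\lambda$ uncertainty would remove this,
which would no longer be the named test; users should read borderline
p-values (such as values near 0.02--0.05 at a dozen species) with that in
mind. $\hat\mu$ itself is unbiased, as the recovery simulations confirm.

Trees are read from newick via `ape`; trees without branch lengths are
rejected unless Grafen's method is requested explicitly — never silently.

## GC skew

Per-window skew is $(G - C)/(G + C)$ on the forward strand — the sign
convention is stated because tools disagree — with windows of 1 kb and
step = window (non-overlapping) by default. Windows with no G or C return
0 with a warning. The cumulative curve is the running sum of window skews;
its global extrema (ties to the first occurrence) are the classical
candidates for replication origin and terminus under strand-asymmetric
mutation pressure. For rearranged mitochondrial genomes this method is
frequently inconclusive, so extrema are reported as candidates, never as
origin calls.

## The synthetic generator: what it emulates, and what it does not

`synthetic_spec()` + `generate_genome()` produce a circular genome with a
planted IR (arm 2 an exact or noisy reverse complement of arm 1), conserved
genes with exons and introns laid out across IR/SC1/SC2, the two rRNA
subunits, and planted G4 motifs at controlled densities, either per region
(IR vs SC) or per compartment (exon/intron/intergenic). The defaults —
150 kb, 35% GC, 35-kb arms, motif template $(GGGT)_7$, densities 1.0/kb in
the IR versus 0.4/kb in the SC — mirror the genome sizes, GC range and arm
sizes of the assembled Lyophyllaceae-type genomes this pipeline targets.
The self-consistency checks use 20 genomes drawn at 100--200 kb with arms
of 20--50 kb (capped so both single-copy regions keep room for their
genes), which keeps the whole acceptance computation to a few minutes on
one core while spanning the realistic size range.

Three generator details matter for interpreting test results:

* **Background run cap.** Background sequence is i.i.d. at the requested GC
  but G/C runs are capped at length 2, which bounds any 25-nt window mean
  at 4/3 and makes background hits at the strict threshold impossible.
  Planted motif counts are therefore exact expectations, and the motif
  recall measured by the tests is a true recall, not a mixture with false
  positives.
* **Arm maximality.** Two bases flanking each planted arm end are forced to
  mismatch in inverted orientation. Without this, the maximal IR in the
  generated sequence is, with probability about 1/4 per boundary, genuinely
  one or more bases longer than the planted one, and "exact recovery"
  would be testing an off-by-chance quantity rather than the detector.
* **Mirroring.** Motifs and gene annotations planted inside arm 1 are
  mirrored into arm 2 (coordinates reflected, strand flipped), as true IR
  duplication does. Mismatches planted between arms avoid motif footprints
  and substitute G/C with A/T, preserving both motif detectability and the
  run cap.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: tRNA genes and their clustering, homing-endonuclease
ORFs inside introns, plasmid insertions, compositional heterogeneity along
the molecule, between-copy indels (the detector is correspondingly
ungapped), and realistic motif sequence diversity (one template per
genome). Depth tracks are independent Poisson per base, with the collapsed
IR modeled by dropping arm 2 and doubling the rate over arm 1; real
short-read coverage has mappability structure and overdispersion the
Poisson model lacks.

`simulate_paired_traits()` generates the phylogenetic inputs: a baseline
trait by Brownian motion on the tree and a paired difference with mean
$\mu$ and covariance $\sigma^2 V(\lambda)$, so parameter recovery and
calibration of the paired test can be measured against known truth. All
generation is seeded Mersenne-Twister; one integer seed reproduces a whole
batch bit-for-bit.

## Numerical and edge-case conventions

* Ambiguity codes other than N are mapped to N on ingest with a warning;
  N scores 0 in every scan and counts toward no compartment total.
* Multi-record FASTA/GenBank files are rejected, not silently subset.
* Wrap-around features on circular genomes are split into two features
  sharing a `group` id; on linear genomes they are an error.
* The BED writer scales scores by 1000 and truncates toward zero (BED
  scores are integers); full precision lives in the sidecar TSV.
* `chisq_enrichment` requires observed and expected totals to agree to
  $10^{-9}$; `expected_counts` sums exactly by construction.
* Depth tracks that are all zero, or with zero median, are errors — the
  2-fold criterion is meaningless without a baseline.
* Problem sizes in the default test run: 20 pipeline genomes of 100--200
  kb, 1,000 chi-square tables, 1,000 null and 200 alternative phylogenetic
  simulations on 12-tip trees, 100 random 2-kb scanner sequences. These
  are the package's chosen validation sizes; all are driven by seeds fixed
  in the tests.
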