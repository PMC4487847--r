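---
title: "Methods: simulating and processing microwell bead-based scRNA-seq"
author: "beadwell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and processing microwell bead-based scRNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beadwell)
```

# The platform in brief

`beadwell` models a microwell single-cell RNA-seq device: cells settle
into an array of ~50 µm cylindrical wells according to Poisson
statistics, each well may hold one barcoded capture bead (bead diameter
excludes a second), and the mRNA of a lysed cell hybridizes to its
bead's oligo(dT) primers. Beads are synthesized combinatorially: a
96-well round attaches a first barcode ending in a universal 6-base
anchor, the beads are pooled and split into 10 reactions that extend a
second barcode plus oligo(dT) off the anchor, yielding
96 × 10 = 960 composite barcodes. Sequencing reads arrive in pairs:
read 1 (26 cycles) carries `BC1 + anchor + BC2` followed by poly(dT);
read 2 carries an 8-base UMI, a 6-base lane barcode for the device's
five flow lanes, and transcript sequence.

The package implements the computational side only: pool design and
validation, the loading closed forms, demultiplexing, UMI-based
molecule counting with chimera removal, downsampling-based cell
calling, downstream cell-type statistics, and a seeded generative model
of the whole experiment with planted ground truth. Read alignment and
gene assignment are out of scope — the pipeline consumes a tagged
mapped-read table standing in for aligner output — as are t-SNE and
pathway analysis, for which the package emits the exact inputs
(a Spearman matrix; a per-gene ±(1−p) table) and stops.

# Loading and barcoding statistics

Two closed forms anchor the device design. With `n` bead-paired cells
drawing barcodes uniformly from a pool of `B`, the expected number of
cells whose barcode is drawn by no other cell is

$$E[\mathrm{unique}] = n\,(1 - 1/B)^{\,n-1},$$

which for `n = 100`, `B = 960` gives `r round(expected_unique_labels(100, 960), 1)`
— about 90 of 100 cells uniquely labeled. With Poisson loading at
`λ` cells per well, the multi-cell fraction among *occupied* wells is
$P(K\ge 2)/P(K\ge 1)$; at `λ = 0.1` this is
`r sprintf("%.4f", multi_cell_fraction(0.1))`, just under the 5% design
bound. The unconditional fraction ($P(K \ge 2) \approx 0.0047$ at
`λ = 0.1`) is far below the quoted bound, which is why the conditional
reading is the default; both are exposed. Both closed forms are checked
against seeded Monte-Carlo oracles in the test suite. The quoted >94%
unique-barcoding rate for ~600 cells over five lanes is not reproduced:
no documented formula yields it, so the package computes the rate under
the formula above and leaves the discrepancy alone.

# Demultiplexing

Both barcode classes tolerate one mismatch. `match_barcode()` takes an
exact hit first, otherwise the unique whitelist entry within one
substitution; ties at the minimal distance are *ambiguous* and dropped
rather than randomly assigned, for determinism and contamination
avoidance. Single-mismatch correction is collision-free exactly when
the whitelist has pairwise Hamming distance ≥ 3, which is why
`validate_pool()` defaults to that floor and `make_default_pool()`
enforces it. The cell barcode is matched as the full 20-base composite
(the anchor is physically present in read 1 and aids error detection).
Reads whose UMI contains an N are dropped as `low_quality`: an
undetermined UMI base corrupts molecule counting more than the read's
coverage is worth. Poly(dT) after the barcode is not validated. Parsing
order (parse → lane → cell) does not affect the output.

# Molecule counting

Each kept read has an address: cell barcode, gene, UMI, mapping
position. Reads mapping non-uniquely to the transcriptome are dropped;
reads also hitting the genome are kept only with correct strand
orientation. Two reads of one cell and gene are the same molecule when
their UMIs are within Hamming distance 2 **and** their positions are
within six bases (both inclusive; identical addresses are the
distance-0 case). Because that pairwise relation is not transitive, the
only order-independent reading of "collapse to a single molecule" is
connected components of the relation graph, which is what
`collapse_molecules()` computes; a sequential/greedy merge would depend
on read order. The position window exists because aligner-reported
start coordinates wobble by a few bases; no soft-clip arithmetic is
attempted. Each molecule's representative is the lexicographically
smallest (UMI, position) — a tie-break that fixes output bytes and
affects nothing else.

Molecules from *different* cell barcodes in the same lane that satisfy
the same relation are PCR chimeras (amplification joined a molecule to
the wrong barcode); since the true origin is unknowable, **all**
members of such a cross-cell cluster are removed. A `keep_dominant`
mode retaining the best-supported barcode exists but is off by default.
This counting is deliberately conservative and can only undercount:
with dense UMI collisions the pipeline's counts are provably ≤ truth,
and the test suite asserts exactly that on a collision-heavy
simulation.

# Cell calling by downsampling

Real bead-paired cells yield complex libraries; phantom barcodes
(sequencing error, cross-talk, spurious capture, PCR jumping) yield
many reads over few molecules. Downsampled to a common read total, the
log₁₀ unique-molecule distribution across barcodes is bimodal.
`call_cells()`:

1. drops barcodes with zero molecules (after chimera filtering — the
   molecule filters precede cell identification in the pipeline order);
2. caps the depth grid (default 100/300/1,000/3,000 reads) at the
   10th-percentile barcode read total, falling back to that percentile
   itself if it undercuts the whole grid;
3. at each depth, downsamples every barcode with enough reads and
   splits the log₁₀ molecule counts by two-class Otsu (the threshold
   minimizing within-class variance) — accepted only when the
   between/total variance ratio reaches 0.75. Unimodal samples land
   near 0.6–0.7 on that ratio and genuine cell/phantom mixtures near
   0.9, so the guard separates the regimes with margin on both sides;
4. votes: above-threshold barcodes vote *cell*, below-threshold vote
   *phantom*, and barcodes with too few reads for the depth vote
   *phantom* (their library could not sustain the depth). If the
   qualifiers admit no split but some barcodes were excluded,
   qualification itself is the evidence: qualifiers vote cell, the
   excluded phantom;
5. majority vote across depths decides; if no depth produced any vote
   the population is unimodal and the caller returns `"no_split"` with
   all barcodes reported as a single population instead of an
   arbitrary bisection. That choice is what lets a phantom-free
   (zero-noise) run return exactly the planted cell set.

The split statistic is a design choice (no distributional assumption,
deterministic); the depth grid likewise. Calls are invariant to
barcode input order because barcodes are processed sorted.

# Downstream statistics

Expression is `log10(1 + 10^6 · count / total)` per cell. The matrix
contains unique molecules, so the denominator is molecules; a
read-based denominator is available by flag. Log base 10 is a
convention choice; the 0.5 expression floor used in bulk comparisons is
applied on the log₁₀ scale. For bulk correlation, genes qualify when
the single-cell median *or* the bulk value exceeds 0.5 (literal OR);
Pearson r is computed over qualifiers, and `saturation_curve()` repeats
random cell subsets 10 times per size, by default **without**
replacement. Differential expression is the two-sided Wilcoxon rank-sum
test per gene (R's `wilcox.test`: exact where sample sizes and ties
allow, normal approximation with tie correction otherwise); constant
genes get p = 1 by convention. The ±(1−p) signed score, positive for
group-A-biased genes, is exported for pathway tools. The CV-ratio
statistic compares sd/mean per marker gene between mixed-population
and pure-population cells. The classifier score ranks all genes within
a cell and reports `log2((a+1)/(b+1))` where `a`, `b` count
type-specific genes above the average rank; the +1 pseudocount keeps
the score finite at realistic depths and the score is exactly
antisymmetric under swapping the gene sets.

# The generative model

`simulate_run()` draws, under one seed: Poisson cells and Bernoulli
beads per well (one bead max — size exclusion); uniform barcode draws
from the pool; a cell type per cell from its lane's mixture (defaults:
lane 1 pure type A, lane 2 pure type B, three mixed lanes, mirroring a
two-cell-line experiment); log-normal molecules per cell; genes from
the type's expression profile; PCR duplicates; chimeric reads that swap
the cell barcode within a lane while preserving gene, UMI and position
(matching what the chimera filter detects); per-base substitution
errors on barcodes and UMIs; and a 0–3 base position jitter emulating
aligner start-offset variation — the very artifact the ±6-base collapse
window absorbs. The mapped-read table is produced by actually running
the single-mismatch correction against the pool, so ≥2-error barcodes
are lost or (rarely) misassigned exactly as in a real run.

Default study conditions, chosen once: 1,000 wells over 5 lanes at
λ = 0.1 (≈100 cells), bead fill 0.95, a 96 × 10 pool (8 + 6 nt halves,
6-base anchor: composite 20 nt + 6 dT fill the 26-cycle read 1),
250 genes of length 500, ~2,000 molecules per cell (lognormal,
sdlog 0.3), 25 + 25 marker genes at 4-fold up in their own type and
4-fold down in the other (markers drawn from a moderately expressed
base so they are detectable at this depth, as real cell-line markers
are), PCR duplicate mean 0.5, 1% chimeras, 0.5% per-base barcode/UMI
errors, and 100 phantom barcodes per lane carrying 1/200 of the cell
median molecule count with ~30-fold duplication. Phantoms are modeled
phenomenologically as low-complexity emitters rather than
mechanistically (the real sources — sealing leaks, free RNA, PCR
jumping — are not individually resolved); their heavy duplication is
what lets them reach the downsampling depths while exposing few
molecules, reproducing the observed bimodality and a ~200-fold median
molecule deficit.

Two deliberate idealizations. First, planted molecules of one lane and
gene are redrawn until pairwise outside the collapse relation
(UMI Hamming ≤ 2 and Δposition ≤ 6 + jitter), across barcodes as well:
this makes the zero-noise pipeline exactly lossless, so every molecule
lost downstream is attributable to a planted artifact rather than to
confounded truth. `allow_umi_collisions = TRUE` restores raw uniform
draws for studying undercounting. Second, transcripts are windows of
random per-gene sequences; there is no sequence-level realism (quality
models, GC bias) and no diffusion physics behind cross-talk. Passing
tests therefore demonstrate the pipeline's correctness under the
model's statistical structure — loading, barcode errors, duplication,
chimeras, library-complexity contrast — not robustness to alignment
artifacts or biological expression structure beyond two types with
planted markers.

# Numerical choices and degenerate inputs

Ambiguous barcode matches are dropped; all-N UMIs never reach
counting. The Otsu bimodality guard (0.75) and the ≥ 0.5 majority rule
are the only thresholds in cell calling; degenerate inputs (all
barcodes identical) return an explicit no-split status rather than a
partition. Zero-total cells are excluded from normalization with a
warning; CV ratios exclude zero-mean or zero-sd genes with a message;
correlations require at least three qualifying genes. All seeded
operations restore the caller's RNG state.

# Problem sizes

The shipped tests run the full default configuration once
(~100 cells, 500 phantoms, ≈4.5 × 10⁵ mapped reads) plus smaller
zero-noise and chimera-only runs (200–500 wells), and validate the
collapse against an exhaustive oracle on 1,000 random groups of up to
200 reads — sizes at which every check completes on a single CPU in a
few minutes while exercising the same code paths as a full-scale run.

# Known limitations

The >94% barcoding-rate figure is not derivable from the documented
model (left as an open discrepancy). Imaging-based cell counts enter
only as external integers; no image analysis is included. The cell
caller assumes the phantom population, when present, differs from
cells in library complexity — phantoms with cell-like complexity would
be inseparable by construction. Whitelist quality weighting,
quality-score-aware correction, and multi-mapper rescue are out of
scope.
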