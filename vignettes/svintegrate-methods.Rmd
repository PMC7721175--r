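---
title: "Integrative SV filtering: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative SV filtering: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Conventional short-read whole-genome sequencing (cWGS, here "SR") and
linked-read sequencing (10x-style, here "LR") see structural variants (SVs)
through different evidence: discordant pairs, split reads and local assembly
on the one hand; barcoded high-molecular-weight (HMW) molecules supplying
long-range linkage on the other.  Multi-caller ensembles on either
technology are sensitive but carry a high false-discovery rate, and the two
technologies disagree on much of their output.  `svintegrate` re-implements
an integrative filtering strategy: quantify, for every candidate SV, how
much raw read evidence actually supports its predicted junction —
independently of the caller that reported it — then combine those
quantities in per-technology logistic-regression filters and a union-based
combined model.

## The pipeline and its models

### Merging and comparison

Calls from multiple callers of one technology are merged when they share SV
type, junction orientation (`3to5`, `5to3`, `3to3`, `5to5`) and both
breakpoints within a 500-bp window — the window reflecting the fragment
scale at which short-fragment evidence can localize a breakpoint.  A merged
call is *high-confidence* when at least one member was reported with FILTER
`PASS`.  Across technologies, SVs larger than 50 bp are compared under the
same type/orientation/500-bp rule; duplications and inversions participate
in matching only above 10 kb because the linked-read pipeline reports those
types in that range only.  Matches become COMMON, the rest ONLY_SR /
ONLY_LR.

Two clustering details are deliberate choices, since a merge rule alone
does not fix them:

* **Anchored greedy clustering.**  Within a (type, orientation, chromosome
  pair) group, calls are sorted canonically and a cluster absorbs calls
  within the window *of its first member* (the anchor).  Single-linkage
  chaining could otherwise merge a long run of calls each 400 bp apart into
  one event spanning kilobases.  The canonical sort makes the partition
  order-invariant, which the test suite asserts under random permutations.
* **Representative breakpoints** are those of the first PASS member (the
  anchor if none is PASS): stable, and favoring coordinates from calls that
  passed the caller's own quality filter.

### Breakpoint-fusion templates

For an SV with breakpoints $A$ and $B$, a synthetic *fusion template* is
built from the reference: 500 bp of flank on either side of each
breakpoint, joined according to the SV's orientation (giving the 1-kb
template for SVs of 1 kb and larger, and for all translocations).  A
deletion joins the 3' flank ending at $A$ to the sequence resuming after
$B$; a tandem duplication joins the 3' end of the segment back to its own
5' start; an inversion has two junctions, head-to-head and tail-to-tail,
each reverse-complementing one flank; translocation breakends follow the
VCF breakend semantics, in which the recorded positions are themselves the
fused bases.

For intra-chromosomal SVs *below 1 kb* the stated rule is only that the
template shrinks to "at least twice the SV size"; we take flank =
min(500, size), the smallest template satisfying that bound while keeping
the junction exactly central.  Templates with more than 50 % `N` are
flagged and skipped.  One coordinate convention is worth stating: an
inversion's stored coordinates are (last base before the segment, last base
of the segment), and the second (5'-to-5') junction is built from those
coordinates shifted by +1.  With a single unshifted coordinate pair, the
two junction templates cannot *both* match an in-place inversion
base-exactly; with this convention the test suite verifies that every
implanted SV's templates occur verbatim in the simulator's rearranged
genome.

### Requantification

Prepared reads (see below) are aligned to every template and two counts are
taken per SV:

* **Junction reads (JR):** alignments covering the fusion point with at
  least 15 aligned bases *on each side*.  The one-sided reading of the
  15-bp rule would count reads that end at the junction and carry no
  junction information, so the two-sided reading is used.
* **Spanning pairs (SP):** pairs with one mate entirely on each side of the
  junction, facing each other (innie) with an implied insert of at most
  2 kb, neither mate being a junction read.

Both counts admit only reads with at least 70 % of their bases aligned to
the template.  Counts are normalized to library size:

$$\mathrm{JR}_{norm} = \frac{\mathrm{JR}}{\text{total reads}} \times 10^8,
\qquad
\mathrm{SP}_{norm} = \frac{\mathrm{SP}}{\text{total pairs}} \times 10^8,
\qquad
\mathrm{JRS} = \mathrm{JR}_{norm} + \mathrm{SP}_{norm}.$$

The totals are those of the read set actually passed in (post-trimming,
post-downsampling), supplied explicitly so the operation stays pure.

Read preparation mirrors the two libraries: linked reads are *debarcoded*
(the 16-bp droplet barcode adjacent to read-1 is cut and both mates are
truncated to 125 bp — whether the original protocol also trimmed read-2 is
unstated; symmetric trimming equalizes mate lengths) and short reads may be
*downsampled* (pairs kept independently with fixed probability, mates
together) to match linked-read coverage.

The aligner is an internal k-mer-seeded, banded, affine-gap local aligner
(match +1, mismatch −1, gap open −3, gap extend −1, score floor = half the
read length, 13-mer seeds, band half-width 10, at least 3 seed hits to
trigger the dynamic program).  It replaces an external short-read aligner
to keep the operation desk-scale and dependency-free; its scores are pinned
against `Biostrings::pairwiseAlignment` in the tests, and the JR/SP counts
against a brute-force literal re-scan of the counting rules.

### GEM (barcode) support

From a barcoded LR alignment file, read pairs *without a normal alignment
flag* — not proper-pair, inter-chromosomal, or carrying a
split/supplementary alignment — are extracted.  An SV is supported by a
barcode when at least one of that barcode's anomalous pairs anchors both
breakpoints within a window $w$ *and* implies the SV's junction
orientation.  The geometry mapping is the standard discordant-pair
convention: a forward-strand anchor contributes its breakpoint's 3' flank,
a reverse-strand anchor the 5' flank (so +/− long-insert pairs support
deletions, −/+ pairs tandem duplications, +/+ and −/− pairs the two
inverted junctions).  The anchor position is the read end facing the
junction.

The window is data-derived: $w = \text{average molecule length} /
\text{N50 reads per molecule}$ — the typical spacing between consecutive
reads of one molecule, i.e. the positional uncertainty of molecule-level
evidence — floored at 200 bp to avoid degenerate windows on toy
simulations.  Barcodes are counted with set semantics (once per SV) and
normalized per million distinct barcodes in the sample ("total GEMs
detected" is read literally as distinct barcode values).  Molecule
statistics may be supplied or estimated by grouping reads per barcode and
chromosome with a 50-kb gap rule.

### Annotation

Each breakpoint is annotated with its RepeatMasker-style repeat class
(priority on overlap: Satellite > Simple_repeat > Low_complexity > SINE >
LINE > LTR > DNA > Other, most SV-artefact-prone first), a mappability flag
(not overlapping a poor-mappability interval; BED intervals are half-open),
and the mean per-base depth in a 400-bp window centered on the breakpoint,
normalized by the sample's mean depth.  The classifier uses one coverage
feature per SV — the mean of its two breakpoints — keeping the feature
symmetric in the breakpoints.

### The logistic filters

Per technology, features are: SV type (one-hot over DEL/DUP/INV/TRA),
normalized JR, normalized SP, SV size (0 for translocations), and
normalized local coverage; the LR model adds the normalized GEM count.
`UNK`-type calls pass through merging and comparison but are excluded from
classification.  Numeric features are `log1p`-transformed before fitting —
their supports are heavy-tailed (counts and sizes over orders of
magnitude), and no transform is prescribed, so this is a package choice.

Training splits the labelled data 70:30 (stratified by label — a choice for
reproducibility on small sets), fits unpenalized maximum-likelihood
logistic regression on the training split *without class re-weighting*
(the original filter was trained on unbalanced data after re-sampling
strategies showed no benefit), and reports test metrics as the mean over 10
bootstrap resamples of the test split (mean rather than median over
resamples; unstated in the source).  An SV is retained when its fitted
probability *strictly exceeds* 0.60.  When a tiny synthetic training set
separates perfectly — common in simulations where decoys have exactly zero
support — the fit falls back to a weak ridge (penalty $\lambda = 10^{-3}$
per observation, intercept unpenalized) solved by IRLS, which keeps the
standard errors finite for the importance computation.

The **combined model** keeps an SV if it is COMMON, or accepted by either
technology's model (union rule; whether COMMON SVs should additionally be
re-thresholded is unstated — the union reading keeps them, and the test
suite asserts combined positives are a superset of COMMON).

Feature importance is the absolute Wald statistic $|\hat\beta_j /
SE_j|$ rescaled to max 100.  Relative importance uses **dominance
analysis**: for each feature, the increment in McFadden pseudo-$R^2$ when
added to a subset model, averaged over subsets of each size and then over
sizes; the weights sum exactly to the full model's $R^2$.  The SV-type
one-hot block is treated as a single grouped feature, as factor terms are
in the field's dominance implementations, keeping the $2^p$ subset fits
small.

### Benchmarking

Against a PCR-style truth table (sv_id, category, PCR result), the package
reports tp/fp/fn, sensitivity $tp/(tp+fn)$, FDR $fp/(tp+fp)$ (NA when
nothing is predicted) and precision — computed over PCR-*tested* SVs only,
with all PCR-positives in the sensitivity denominator regardless of
category.  Per-category confirmation rates and window-based recall against
external call sets complete the module.

## The synthetic-data generator

The generator is first-class, tested code; it emulates the stated
experimental world rather than a tunable benchmark:

* reference genome: i.i.d. bases, GC 0.41, default 1 Mb over 4 chromosomes;
* SVs: deletions 2–8 kb, tandem duplications and inversions 12–20 kb
  (above the 10-kb LR reporting floor so all types can become COMMON), and
  reciprocal translocations as tail swaps between dedicated chromosome
  pairs (each event contributes its two junctions to the truth set);
* short reads: fragments Normal(550, 60) truncated at 300 bp, 2×150 bp
  innie pairs, per-base substitution error 0.001, 30× coverage;
* linked reads: molecules Uniform(50–100 kb) placed to a 30× *physical*
  coverage target, each with a unique 16-bp barcode, sheared to ~0.5-kb
  fragments sequenced 2×150 bp with the barcode prepended to read-1, one
  read pair per kb of molecule (a realistic sparse shearing rate; the
  resulting sequence coverage is ~9×, below the physical coverage, as in
  real linked-read libraries);
* truth alignments: emitted directly from known provenance in reference
  coordinates through a block map, so no external aligner is needed —
  reads crossing junctions become soft-clipped records, SV-spanning pairs
  become discordant, and the proper-pair flag is recomputed from mapped
  geometry (innie, insert 100–1200 bp, same chromosome, no split);
* labelled call sets: truth SVs jittered by at most 100 bp per breakpoint
  (so two technologies' representatives, each jittered at most twice via a
  second pseudo-caller, always stay within the 500-bp window), with
  per-technology dropout of 0.15 creating ONLY_* categories, and decoy SVs
  at random non-implanted coordinates as the negative class — matching the
  semantics of a PCR-negative junction (no product at the predicted
  fusion), rather than mis-genotyped positives.

What the generator does **not** model: GC/coverage bias, chimeric
molecules, barcode collisions or sequencing-error barcodes, indel
sequencing errors, micro-homology at junctions, and non-tandem duplication
topologies.  A green end-to-end test therefore establishes that the
pipeline's machinery is self-consistent at realistic coverages — not that
its operating characteristics on real tumor genomes are reproduced.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere except at BED boundaries
  (half-open, converted on import).  Deletion records use VCF symbolic-ALT
  semantics (POS = last retained base, END = last deleted base).
* Zero normalization denominators are errors, not zeros.
* FDR with an empty prediction set is reported as NA.
* Non-convergent dominance subset fits are excluded with a warning and the
  weights re-normalized to the full-model $R^2$.
* Ties in repeat-class overlap resolve by the fixed priority above;
  template flanks are clipped at chromosome ends with the junction offset
  adjusted.
* All simulator output is bit-identical for a fixed seed and configuration
  (asserted in tests).

## Known limitations

* The aligner is substitution-oriented (band half-width 10); long indels
  near a junction will be soft-clipped rather than gapped through.
* Chained or nested SVs sharing breakpoints get partial or no
  requantification support — a limitation inherited from the
  template-per-junction design.
* The bundled PCR table is a synthetic reconstruction from published
  aggregate counts; per-SV analyses on it (beyond the category marginals it
  encodes exactly) are illustrative only, and the per-set
  sensitivity/FDR figures of the source cannot be reproduced from any
  single table consistent with those marginals — the corresponding
  acceptance check is intentionally left failing with that analysis
  recorded.
* Genotyping, phasing and multi-sample merging are out of scope.
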