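---
title: "Methods: mitogenome characterization with MitoCircle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitogenome characterization with MitoCircle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MitoCircle)
```

# Scope and data model

MitoCircle implements the standard descriptive analysis of an annotated
animal mitochondrial genome. The central object is a `MitoAnnotation`:
the genome length, a circularity flag, an ordered feature table over the
canonical 37-gene vocabulary (13 PCGs, 22 tRNAs, 2 rRNAs) plus the
control region (CR), and optionally the heavy-strand sequence as a
Biostrings `DNAString`. Coordinates are 1-based inclusive, as in GenBank
records and published gene-organization tables, and a feature may wrap
the circular origin (`end < start`), in which case its length is
`genomeLength - start + 1 + end`. The CR is carried as a positional
feature but never counted as a gene: strand tallies and per-class totals
run over the 37 genes.

Gene names arriving from GenBank files or feature tables are
canonicalized through a synonym table (`COI`/`COX1` to `cox1`,
`16S`/`l-rRNA` to `rrnL`, `tRNA-Leu2`/`trnL(UUR)` to `trnL2`, `D-loop`
to `CR`, and so on). Canonicalization is idempotent; unknown names are
kept verbatim and flagged, never dropped, so downstream steps can decide
what to do with them. Duplicated genes receive occurrence suffixes
(`trnQ#2`) so that gene orders with duplications remain representable.

The package does not annotate: it consumes existing annotations (its
own generator, GenBank flat files, or plain tables). De novo gene
finding, read assembly, alignment, tRNA secondary-structure folding and
tree inference are out of scope.

# Composition and strand asymmetry

For a region with base counts $A, T, G, C$:

$$\mathrm{AT\text{-}skew} = \frac{A - T}{A + T}, \qquad
  \mathrm{GC\text{-}skew} = \frac{G - C}{G + C}.$$

Both statistics are scale invariant, so they accept raw counts or
percentages interchangeably; `skew()` refuses the degenerate case
$x + y = 0$.

Strand conventions are the one genuinely open design point, because
published composition tables rarely state them. MitoCircle counts the
whole-genome row on the heavy strand, and per-gene rows on each gene's
reading sense (reverse complement for light-strand genes). Class rows
(PCGs, tRNAs, rRNAs, CR) concatenate the reading-sense sequences of
their members in annotation order. The reading-sense choice for class
rows is deliberate: in published tables the pooled-PCG skew is close to
the average of the per-gene reading-sense skews, which is only possible
if the light-strand genes are reverse-complemented before pooling
(pooling on the heavy strand would let the A-rich light-strand genes
cancel much of the T-richness of the rest). Ambiguous bases (N) are
excluded from every numerator and denominator and reported in a separate
column. Percentages are held at full precision internally and rounded
only at serialization (2 decimals for percentages, 3 for skews, the
precision such tables are conventionally printed at).

Adjacency accounting scans consecutive features around the circle
(ordered by start, wrapping last to first) and reports the signed gap
`start(next) - end(prev) - 1`: positive values are intergenic spacers,
zero is an abutment, negative values are overlaps of `|gap|` bp. On any
annotation whose features do not wrap, feature lengths plus signed gaps
sum exactly to the genome length, a conservation property the tests
exercise.

# Codon usage and RSCU

The genetic code defaults to NCBI translation table 5 (invertebrate
mitochondrial): AGA/AGG encode serine (an eight-member Ser family), UGA
encodes tryptophan, and the stop codons are {UAA, UAG}. The stop codons
form their own two-member family for RSCU purposes. For codon $c$ in
synonymous family $F$,

$$\mathrm{RSCU}(c) = \frac{n_c}{\frac{1}{|F|}\sum_{f \in F} n_f},$$

so within every family with nonzero total the RSCU values sum exactly to
the family size, RSCU is invariant to scaling all counts, and a uniform
family sits at 1. All-zero families are assigned RSCU 0 and flagged
rather than producing 0/0.

Codon counting tallies every complete in-frame triplet across the input
CDS set, ignoring trailing partial codons and skipping (with a count)
triplets containing ambiguity characters. Stop triplets are tallied by
default: published whole-PCG codon tables include internal and terminal
stop triplets, and the default reproduces that table structure; pass
`includeStop = FALSE` for a sense-codon-only table. Codons are reported
in the RNA alphabet, as such tables are conventionally printed.

Start/stop detection reads the first triplet as the start and the last
complete in-frame triplet as the stop when it is one under the code;
otherwise the trailing 1–2 nucleotides are reported as an incomplete
stop (the mitochondrial T/TA convention, completed to UAA by
polyadenylation). A full-frame CDS without a terminal stop is reported
with its last codon and flagged. CDS whose length is not a multiple of
3 are flagged at extraction and handled codon-wise, since real
annotations contain them (the bundled MK681888 table has a 982 bp
*nad2*).

# Ka/Ks by the Nei–Gojobori method

The selection analysis re-implements the classical counting method
(Nei & Gojobori 1986) rather than calling an external tool, with two
conventions stated explicitly because published descriptions often omit
them:

1. **Sites.** Each codon position contributes the fraction of its
   *viable* one-step mutations that are synonymous; mutations creating a
   stop codon are excluded from the denominator. $S$ is the sum of the
   fractions, $N = 3 - S$, so each compared codon contributes exactly
   three sites. Site counts are averaged between the two sequences.
2. **Differences.** Between two aligned codons, all orderings of the
   differing positions are enumerated as mutational pathways; pathways
   passing through a stop codon are discarded and the synonymous /
   nonsynonymous step counts are averaged over the survivors with equal
   weights ($s_d + n_d$ equals the Hamming distance). If every pathway
   crosses a stop, the average is taken over all pathways and the result
   flagged.

Proportions $p_S = S_d/S$ and $p_N = N_d/N$ are Jukes–Cantor corrected,
$K = -\tfrac34 \ln(1 - \tfrac43 p)$; $p \ge 3/4$ is reported as a
saturated (`NA`) rate and $K_s = 0$ leaves the ratio undefined rather
than infinite. Codon pairs containing ambiguity characters or a stop in
either sequence are skipped pairwise with a diagnostic count. The
statistic is symmetric in its arguments, and the implementation is
checked against a literal brute-force oracle (explicit enumeration of
all one-step mutants and all pathways) to $10^{-12}$ in the tests.

Panels are averaged per gene over all species pairs (or focal-vs-others)
with undefined ratios excluded from the mean and counted. Alignment is
assumed given: mitochondrial PCGs are routinely codon-aligned upstream,
and re-implementing an aligner would add nothing to the analysis.

# Gene-order rearrangement

Gene orders are signed circular token sequences; two orders describe the
same arrangement iff one is a rotation of the other. `normalizeOrder()`
fixes the rotation deterministically by anchoring `cox1(+)` first
(flipping the circle if the anchor lies on the light strand) — the
anchor is arbitrary but fixed, which is all determinism needs.

**Breakpoints** are the signed adjacencies (ordered token pairs with
orientations) of the derived order absent from the reference. The count
is zero iff the orders are rotation-equal and is invariant under
rotation of either order; one single-gene translocation changes at most
three adjacencies, so $k$ translocations give at most $3k$ breakpoints.

**Event detection** searches exhaustively over removal subsets of at
most `maxMoved` shared tokens (default 3 — large enough for every
published caridean rearrangement while keeping the search trivial) for
the smallest set whose removal leaves the orders rotation-equal.
Several minimal sets can explain the same rearrangement: a tRNA hopping
across a gene is indistinguishable, order-wise, from the gene hopping
the other way. The tie-break prefers the solution with the fewest
non-tRNA members — tRNAs are overwhelmingly the mobile elements in
mitogenome rearrangement — and then the lexicographically first set, so
results are deterministic. Inversions are tokens whose orientation
differs (the CR, which has no reading sense of its own, is excluded);
duplications are tokens more frequent in the derived order than in the
reference. If no subset within `maxMoved` explains the difference the
report is flagged complex and carries the breakpoint count only. For
non-complex reports the recorded moves replay onto the reference to
reproduce the derived order, a round-trip property the tests check.

**TDRL reachability.** A tandem duplication/random loss event duplicates
a contiguous segment and randomly loses one copy of each duplicated
gene. The survivors of the first copy (in reference order) are followed
by the survivors of the second copy (in reference order), so the orders
reachable in a single event are exactly those whose genes, mapped to
reference positions, form **at most two increasing runs** — at most one
descent in the index sequence — and no gene changes strand (a TDRL can
never invert). An equivalent characterization sometimes quoted for this
test — decomposability into two increasing *subsequences*, i.e. longest
decreasing subsequence at most 2 — is strictly weaker and wrong:
`a,c,b,d,f,e` versus `a,b,c,d,e,f` has no decreasing triple yet needs
two events, because the two ascending copies must be concatenated, not
interleaved. MitoCircle uses the descent criterion, which agrees with
exhaustive enumeration of every loss pattern (a property test runs 500
seeded trials against that oracle). When whole circular orders are
compared (`segment = NULL`), all rotations of both orders are searched
before declaring an arrangement unreachable, since the duplicated
segment may sit anywhere on the circle; an explicit `segment` is
compared linearly.

The ancestral decapod arrangement (and the identical caridean one) ships
as a built-in signed order; it is entered in a single place
(`ancestralGeneOrder`) so any transcription question is isolated there.

# The synthetic-data generator

The generator exists so that every stage has inputs with known ground
truth. `generateGenome()` lays the 38 features along a template order
(ancestral decapod by default, optionally rearranged by explicit
translocate/invert/duplicate operations) with, by default, the observed
MK681888 gene sizes (each PCG length rounded to a multiple of 3, e.g.
981 for the published 982 bp *nad2*), tRNAs drawn from 63–70 bp, 1 bp
spacers, and the observed whole-genome base composition
(A 32.51, T 31.91, G 14.24, C 21.33 %) as the sampling target. PCGs are
clean ORFs on their reading strand — ATG start, interior codons drawn
from a codon distribution, TAA stop, no internal stops by construction —
and light-strand genes are placed as reverse complements, which
preserves A+T content on the heavy strand exactly in expectation.
Because stop codons are A/T-rich, excluding them from the codon
distribution would bias coding sequence away from the composition
target; `calibratedCodonWeights()` therefore recalibrates the
per-base weights iteratively so the expected composition of *sense*
codons matches the target. At ~16 kb the binomial sampling error on
A+T% is about 0.37 points (1 sd), so realized composition lands within
±0.75 of target with ~95% probability, the tolerance the tests use.

`evolvePair()` draws an ancestral CDS from the codon distribution and
evolves a descendant by acceptance–rejection at the codon level:
proposals are uniform over positions and then uniform over the *viable*
(non-stop) target bases at that position; synonymous proposals are
always accepted, nonsynonymous ones with probability $\omega$, stops
never arise. Restricting proposals to viable targets matters: under
uniform proposals over all nine neighbours with stop-rejection, the
NG86 estimate is biased upward by several percent, because NG86 counts
sites as syn/viable per position. With the viable-uniform proposal the
mutational opportunity model matches the estimator and
$\hat\omega \to \omega$ in the low-divergence regime, with a residual
upward drift of order 1% from multiple hits. The default branch length
(`subsPerCodon = 0.5` expected proposals per codon) gives both
substitution classes on the order of a hundred events at 2000 codons —
enough for a stable ratio — while keeping $p_S \approx 0.1$, far from
Jukes–Cantor saturation. Panels are star-shaped (every species evolved
independently from the gene's ancestor): the analysis averages pairwise
values, so tree-induced correlation structure would add realism the
estimators never use.

What the generator deliberately does **not** emulate: real tRNA/rRNA
secondary structure, indels and alignment error, within-genome
composition heterogeneity (real light-strand genes have their own skew
regimes), replication-driven skew gradients, and codon-position-specific
composition. Passing tests therefore demonstrate the correctness of the
arithmetic and the estimators under the stated models — not robustness
to annotation error or alignment noise in real data.

# Numerical and degenerate-input choices

- Rounding happens only in report writers (percent 2 dp, skew 3 dp,
  RSCU 2 dp); all internal values are full precision, and reports are
  byte-identical across reruns.
- `skew(0, 0)`, empty region selectors, missing sequences, stop codons
  passed to site counting, and mismatched alignment lengths all raise
  informative errors; panel processing isolates per-gene failures.
- Saturated rates ($p \ge 3/4$) and $K_s = 0$ produce flagged `NA`s,
  never infinities.
- All simulation functions take an integer seed and are bit-reproducible
  under it.

Problem sizes in the shipped tests were chosen to make sampling checks
meaningful at interactive speed: $\omega$-recovery at 2000 codons,
panel rank recovery at 280 codons × 6 species, TDRL oracle agreement
over 500 random orders of length ≤ 7, NG86-vs-oracle on pairs of ≤ 5
codons, and full-genome (~16 kb) generation for composition and
round-trip properties.

# Known limitations

- The GenBank reader is a minimal flat-file parser aimed at mitogenome
  records (single record; CDS/tRNA/rRNA/D-loop/misc_feature; simple and
  origin-wrapping join locations). It is not a general GenBank parser.
- NG86 with Jukes–Cantor correction is the classical counting method;
  it ignores transition/transversion bias and codon frequencies, and
  underestimates rates at high divergence. For deep comparisons a
  maximum-likelihood dN/dS method should be preferred.
- Event detection reports *a* minimal translocation set under a stated
  tie-break; rearrangement history is generally not identifiable from
  two orders alone.
- `detectEvents` is exhaustive over subsets, so `maxMoved` beyond ~5 on
  38-token orders becomes expensive; multi-event TDRL scenario
  reconstruction and rearrangement-based phylogenetics are out of
  scope.
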