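---
title: "Methods: detecting and characterising a retrotransposition burst from long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and characterising a retrotransposition burst from long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(teburst)
```

# Scope and model

`teburst` analyses the aftermath of an LTR retrotransposon mobilisation
burst: novel insertion discovery from long-read alignments, reconstruction
of each inserted sequence and of a per-sample *pseudoreference*,
parental-copy assignment through diagnostic SNPs, cytosine-context
methylation metaplots, positional/chromatin-state statistics, and
classification of transposon–gene transcript events. Alignment, basecalling
and methylation model inference are out of scope: the package consumes
coordinate-sorted SAM/BAM, bedMethyl pileups and transcript models, and
produces tables, profiles and figures.

A deterministic synthetic-data generator is a first-class component. It
plants insertions with known positions, donors, target-site duplications
(TSDs), zygosity, methylation regimes and transcript scenarios, so that
every downstream stage can be validated against truth without any external
download.

# Insertion discovery

A read crossing an insertion junction either aligns through it, leaving the
inserted sequence as an `I` CIGAR operation, or terminates at it, leaving a
soft clip (`S`). One signal is emitted per qualifying operation (default
minimum 200 bp, mapping quality ≥ 20; secondary/supplementary/unmapped
records are excluded throughout, mirroring the conventional `-F 2308`
filter). Signals are clustered by single linkage with a 50 bp window — the
scale of long-read breakpoint jitter — and the cluster breakpoint is the
(lower) median signal position.

Support is tested against the genome-wide background clip rate
`p = clip signals / primary alignments` (floored at 0.01 so the null is
never degenerate) with the exact one-sided binomial tail
`P(X >= s | n = local depth, p)`, summed in log space. Calls pass when
support ≥ 4, p ≤ 0.05 and support/local depth ≥ 0.3. These three gates are
the package defaults and can be varied; raising the support threshold can
only shrink the call set (a property the tests assert).

**TSD refinement.** Integration duplicates a short host motif. The inserted
block carried by a junction read therefore ends with a copy of the
reference bases immediately left of the breakpoint. `detect_tsd` scans
match lengths from 20 down to 3 and reports the longest exact suffix match.
When the reference happens to continue the duplication by chance the
reported TSD can exceed the planted one by a base or two — the well-known
boundary ambiguity of TSD calling; breakpoint accuracy is therefore always
assessed *within TSD length*.

**Zygosity.** With local depth `d` and carrier reads `s`, the carrier
fraction `f = s/d` calls `hom` at `f >= 0.8`, `het` at `0.2 <= f < 0.8`,
`unknown` below that or when `d < 6`. At depth 40 a true heterozygote is
mis-called in well under 5% of cases (binomial tail at p = 0.5), which the
tests verify by simulation.

# Pseudoreference and liftover

All clipped/inserted segments within 50 bp of a retained breakpoint are
collected (SAM stores SEQ in reference orientation, so segments need no
strand flip). The longest segment anchors the consensus: every other
segment is aligned to it globally with free ends on the anchor
(match +1, mismatch −1, gap −2), truncated segments vote only on columns
they cover, per-column majority wins with ties resolved to the anchor, and
a column where the anchor is gapped is kept only when a strict majority of
segments supports an identical inserted string. For high-identity long-read
segments this reproduces what a multiple aligner would give,
deterministically and without external tools. Exact substrings of the
anchor short-circuit the alignment, so the noise-free path is fast.

The inserted block written into the reference is *consensus + one extra
TSD copy*, so the duplication flanks the element on both sides, exactly
inverting the generator's construction — on noise-free simulations the
pseudoreference reproduces the planted genome byte-for-byte, and the tests
assert this identity. All insertions per chromosome are applied in one
`Biostrings::replaceAt` call, with coordinates interpreted on the original
reference (positionally equivalent to applying them right-to-left).

The liftover stores one (chromosome, breakpoint, inserted length) row per
insertion. Mapping is bijective outside inserted blocks (property-tested on
10,000 random positions); pseudo positions inside a block map to `NA`
toward the reference. Annotation shifting maps each feature's first and
last base independently: features wholly downstream shift by the cumulative
inserted length, features spanning a breakpoint are widened to include the
insert (that is how an intronic insertion appears inside a gene model), and
non-spanning features keep their length.

# Parental assignment

The reverse-transcriptase (RT) segment is the most conserved part of the
element, so donor identity is read there. A fixed RT reference (one donor's
segment) is located in each consensus by local alignment (match +1,
mismatch −1, gap open −2, extend −1), trying the reverse complement when
the forward orientation fails; hits below 80% identity over the full RT
reference are rejected, which is what a 5′-truncated insert produces. The
TEI base aligned to each diagnostic column gives a genotype vector
(deletions/uncovered positions are unknown); the assignment is the set of
donors attaining the maximal agreement over covered positions. TEIs with
fewer than 8 covered positions or a best match fraction below 0.9 stay
unassigned — these two thresholds are package choices (the original
curation of such panels is manual); they are deliberately permissive so
that only genuinely unreadable RTs drop out. Donors that share all panel
alleles are reported as an ambiguity *set*, never split fractionally;
summaries count them in a separate "shared" bucket so that per-donor
counts, shared and unassigned always partition the TEI set.

# Methylation profiles

Records are context-annotated from the genome (+ strand: CG if the next
base is G, CHG for C-H-G with H ∈ {A,C,T}, else CHH; − strand symmetric),
each cytosine an independent record — strands are not merged. Coverage
filtering drops records with fewer than 3 reads, then trims records whose
coverage falls strictly outside the empirical 5%/95% quantiles of the
remainder, applied per sample and context in that order.

Profiles use fixed 50 bp bins over 2 kb flanks (40 per side) and 100
proportional bins over the element body (`floor(offset x 100 / length)`,
so elements shorter than 100 bp still bin uniformly). A bin value is the
unweighted mean fraction over its cytosines, pooling replicates; empty bins
are `NA`, never zero. Minus-strand elements are flipped so bin 1 is always
the element 5′ side. Metaplots average profiles per bin with SD (0 when a
single profile contributes) and smooth the mean with a centered 10-bin
rolling mean, truncated at the edges (for the even window, 4 bins left and
5 right of centre). One specific element in real data needs its start
shifted to skip an unannotated hypomethylated head; this is supported as a
per-element start offset in the element table rather than hard-coded.

Control subtraction lifts each pseudo flank bin back to reference
coordinates base by base; positions inside inserted blocks (the element's
own duplicated TSD, or a neighbouring insertion) do not map and are
skipped, and a bin with fewer than half its bases mapping is empty. The
spread distance is the contiguous run of difference bins at or above 0.05
starting at the element boundary, times 50 bp. Edge/body ratios divide the
mean over the terminal-repeat-covering body bins by the mean over the
central 20 bins; the simulated euchromatic regime (CHH edge peaks — the
RdDM signature) and heterochromatic regime (uniform low CHH) separate
cleanly at a ratio threshold of 2.

# Genome statistics

All interval logic is 0-based half-open, converted to `GenomicRanges` at
the boundary, so site 100 hits the feature `[100, 200)` while site 200
falls outside it. Chromatin-state enrichment uses an exact one-sided binomial test with
the state's genome-wide base-pair fraction as background — the natural null
for point insertions under uniform integration; Benjamini–Hochberg adjusted
p-values are reported alongside the raw ones across the 36 states. The
two-sample Kolmogorov–Smirnov comparison normalizes positions by chromosome
length and pools chromosomes (chromosome identity is deliberately
discarded; only the along-arm distribution is compared), with the
asymptotic Kolmogorov p-value under the standard effective-sample-size
correction; its type-I error at n = 50 per sample sits near 0.04, which the
tests check over 1000 null replicates. Fisher's gene-overlap test
enumerates the hypergeometric support exactly; the gene universe is an
explicit required argument. Summary tables render intragenic percentages
half-up to one decimal, and totals are column sums over plants — when a
published total disagrees with its own column sum, the column sum is what
this function reports.

# Transcript events

Classification works per expressed transcript against the inserted block
(TE + duplicated TSD), with a 10 bp splice-boundary tolerance: an intron
matching the block boundaries is intronization (subtype `existing_intron`
when the wild-type model already had an intron across the host site, else
`exonic`); a 3′-terminal exon ending inside the TE is ATT; a first exon
starting inside it is ATS; a gene showing both (in one transcript or
across transcripts) is `ATS_and_ATT`; partial TE sequence inside an exon is
`exonization_other`; an expressed gene whose transcripts never touch the TE
is `unaffected`; zero primary reads over the gene is `not_transcribed`. The
gene-level category follows the majority-support transcript, ties broken
toward the more disruptive category (ATS_and_ATT > ATT > ATS >
exonization_other > intronization > unaffected). Classification is
strand-correct: mirrored scenarios on the minus strand yield the same
category, with the TEI orientation recorded as sense/antisense.

Isoform splitting counts a read as TEI-derived when any aligned block
overlaps the insertion; normal counts are the complement, so
`normal = total − tei` holds identically. RPKM is
`count x 1e9 / (length x library size)`; TPM normalizes per-base rates to
a million, so TPM always sums to 1e6. ORFs are predicted on the transcript
sense strand from ATG to the first in-frame stop (or the last complete
codon), minimum 75 nt including the stop, nested starts sharing a stop
reported once from the 5′-most ATG — transcripts are oriented molecules, so
the antisense frames are not searched; widen the minimum or scan the
reverse complement explicitly if needed. Protein classes follow the
junction: an ORF spanning the gene/TE junction is chimeric, one fully
inside the TE is TE-internal, a fully gene-derived ORF shorter than 90% of
the wild-type CDS is truncated, otherwise wild-type-like.

# The synthetic-data generator

Defaults describe the study conditions the generator emulates at desk
scale: 2 chromosomes × 200 kb with arm/pericentromere/centromere
compartments (20% pericentromeric, 10% centromeric), 12 three-exon genes
per chromosome on the arms, 8 donor elements of 4 kb (300 bp identical
LTRs; a GAG–PR–INT–RT–RH internal layout) with 16 diagnostic SNPs in the
RT segment and one intentionally allele-sharing donor pair, 20 plantings
with 4–6 bp TSDs, half heterozygous, 80% genic (the remainder
pericentromeric, which is what gives them a heterochromatic regime), 10
reads per locus plus 4× plain background coverage, and a transcript
scenario mix of 25% intronization, 15% ATT, 10% ATS, 10% unaffected and
40% not transcribed. Methylation targets are Beta-distributed around
per-regime levels (euchromatic: CG body 0.85, CHG 0.40, CHH body 0.08 with
0.55 LTR edges; heterochromatic: CG 0.90, CHG 0.10, CHH 0.05 uniform;
flanks at 0.05, concentration 60), with an asymmetric CHH spread of 0, 0.5,
1 or 2 kb into the right flank of euchromatic elements. A single global
seed drives every stage through derived per-stage seeds; identical
configurations give byte-identical artifacts.

Design notes worth recording:

* **Alignments are synthesized directly** as SAM records with exact CIGAR
  signatures — no error model, no aligner — because the discovery stage
  consumes CIGAR structure, not base quality. Carrier reads rotate through
  internal-insertion, right-clip and left-clip representations, all
  carrying the full inserted block.
* **Background reads never span a planted junction.** Junction-crossing
  coverage is modeled entirely by the per-locus reads: in real data a read
  crossing a homozygous insertion junction cannot align straight through,
  so letting tiled background reads do that would deflate every carrier
  fraction. Background reads exist to anchor the genome-wide background
  clip-rate estimate (and receive spurious clips at the configured noise
  rate).
* **Heterozygosity is a per-read Bernoulli(0.5) draw**, matching the
  diploid expectation. A consequence is that a het locus at depth 10 drops
  below 4 carrier reads with probability ≈ 0.17, so *no* caller with the
  min-4 support filter can guarantee full recall there: the 100%-recovery
  guarantee is therefore stated — and verified — for homozygous plantings,
  while zygosity calling is validated separately at depth 40 where the
  binomial bounds are sharp.
* **What the generator does not emulate:** base errors and quality scores,
  chimeric/split reads, 5′-truncated or solo-LTR insertion structures,
  polyploid genotypes, chromatin-state-biased integration (sites are
  uniform within genes/arms per the configuration), replicate-level batch
  effects beyond Beta noise, and methylation spread whose direction varies
  per element (spread is planted downstream only). Passing tests therefore
  demonstrate the correctness of the algorithms on clean signals, not
  robustness to every artefact of real nanopore data.

# Numerical choices and degenerate inputs

Exact binomial and hypergeometric tails are summed in log space and agree
with high-precision enumeration to 10⁻¹² relative error for the sizes used
(n ≤ 100, universe ≤ 500; the tests assert this). Zero local depth returns
p = 1 with a warning; zero-support candidates get p = 1. Empty inputs
(no signals, no calls, empty methylation tables, zero-read genes) return
typed empty results rather than errors. A single consensus segment is
returned unchanged; assemblies with no qualifying segments are skipped with
a warning. Division corner cases are pinned: edge/body ratio is `Inf` when
only the centre is zero and 1 when both are; correlation with a
zero-variance vector warns and returns `NA`. Percentages render half-up at
one decimal. Test-scale problem sizes (200 kb chromosomes, 20 insertions,
depth 10, 1000-replicate null calibrations) were chosen as the smallest
sizes at which every contrast of interest is unambiguous.

# Known limitations

Discovery assumes breakpoint-local clip signatures; nested insertions,
insertions closer than a read length, and structural variants other than
insertions are out of scope. The consensus stage assumes segments of a
single allele per locus. The KS p-value is asymptotic and slightly
conservative at n ≈ 50. The binomial enrichment background is base-pair
fraction, not region count — an explicit, documented choice; with
region-level backgrounds the p-values would differ. The parental panel for
real data must be supplied by the user; the generator builds its own.
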