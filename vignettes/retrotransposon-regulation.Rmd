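---
title: "Methods: locus-resolved L1 methylation and promoter activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locus-resolved L1 methylation and promoter activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retroepi)
```

## The analysis problem

Full-length mouse LINE-1 (L1) elements carry a promoter built of tandem
~200 bp monomers in their 5′UTR. In most somatic cells this promoter is
silenced by CpG methylation; in specific lineages — the motivating case is
parvalbumin (PV) interneurons — individual loci escape silencing, transcribe
full-length L1 mRNA, and can drive chimeric transcripts into neighboring
genes from the L1 antisense promoter. retroepi implements the computational
stages needed to characterize this behavior from long reads: per-CpG
methylation call aggregation, per-locus differential methylation between
sorted cell populations, 5′RACE transcription start site (TSS)
classification, chimeric transcript detection with reading-frame
verification, and targeted bisulfite amplicon scoring — together with a
simulator that generates all inputs with known ground truth.

## Coordinates and element structure

All internal coordinates are 0-based half-open on the forward strand; the
RepeatMasker `.out` convention (1-based inclusive, `C` for minus strand) is
converted once at parse time. CpG sites are strand-collapsed to the
forward-strand position of the C, matching common long-read call
conventions, so a CpG contributes one site regardless of which strand a
read covered.

Family-level analyses use strict length cutoffs for "full-length" elements:
L1 > 6000 bp, SINE B1 > 140 bp, SINE B2 > 185 bp, MERVL MT2 > 470 bp,
IAP > 320 bp. The 5′UTR of an L1 is delimited by tandem monomer detection:
gap-free anchored stepping of a monomer consensus from the element 5′
terminus, counting every window with per-base identity ≥ 0.75 (our choice;
young-subfamily monomers diverge far less than 25%, so the threshold is
insensitive over a wide range). The monomeric region generally understates
the functional 5′UTR, which extends through a nonmonomeric linker to ORF1;
because no universal linker annotation exists, the ORF1 start is an
optional input (`orf1_start`) that extends the 5′UTR when available.

## Methylation model

A per-CpG call is a log-likelihood ratio (llr) for methylated versus
unmethylated at one site on one read. States are assigned with a symmetric
threshold τ = 2.0: methylated when llr ≥ τ, unmethylated when llr ≤ −τ,
ambiguous otherwise; τ = 2 is the community convention for
nanopolish-derived calls. Grouped calls covering k motifs expand to k
per-CpG calls sharing the group's llr, with positions taken from the CpG
spacing in the call's sequence context — dropping groups instead would
discard coverage disproportionately from CpG-dense promoters, the very
regions of interest.

Aggregation (`segment_methylation`) counts non-ambiguous, primary-alignment
calls per segment and population; for full-length L1 segments only 5′UTR
CpGs count, because promoter methylation is the regulatory quantity and
element bodies are uniformly methylated. A segment's methylation fraction
is `n_meth / (n_meth + n_unmeth)`.

### Differential methylation

Loci enter testing only when every compared population supplies ≥ 4 reads
and ≥ 20 calls; below that, Fisher's test is dominated by sampling noise.
Each tested locus gets a two-sided Fisher's exact test on the 2×2 table of
methylated/unmethylated counts across populations. The p-value sums
hypergeometric point probabilities of all tables with the observed margins
that are no more probable than the observed table (point-probability
extremity, ties included, with a 1e−7 relative guard against
floating-point tie loss). We correct by Bonferroni over the number of loci
*tested* (post-filter), not annotated — only covered loci are comparable —
and call significance at corrected P < 0.01. Results are ordered by
absolute methylation change to support top-k rankings
(`top_differential`).

The test treats calls as independent Bernoulli draws. Calls on the same
read are correlated in reality; with the coverage filter in place, the
effective inflation is modest, and the Bonferroni family-wise criterion at
0.01 leaves headroom, but borderline loci should be read with this caveat.

### Profiles

Composite profiles average call states per strand-oriented element-relative
position over the first 2000 bp of six-monomer elements (the dominant
promoter architecture; mixing monomer numbers would smear monomer-phase
structure). Positions with fewer than 5 calls are masked — an arbitrary but
conservative floor below which a per-position mean is mostly noise. Locus
profiles report per-CpG fractions over an element ± flank, smoothed by a
centered 28 bp sliding window in genome space, plus a CpG-space track
indexed by CpG ordinal whose length always equals the CpG count of the
region (uncovered sites are `NA`, not dropped).

## 5′RACE TSS classification

Reads are retained when (i) primary, (ii) uniquely best-placed, and
(iii) carrying the element-specific primer at one terminus and the
universal RACE primer at the other. Primer matching allows ≤ 2 mismatches,
searches both orientations within the terminal 40 nt, and ignores indels —
tolerances chosen for SMARTer-style adapter trimming variability. A
retained read is assigned to an overlapped full-length element whose body
contains the alignment's 3′ terminus in element-strand sense (the
element-specific primer sits in the L1 body, so a genuine L1 mRNA must end
there); reads tied between two qualifying elements stay unassigned. The 5′
terminus is the putative TSS: `upstream` when 5′ of the element within
1000 bp (our bound; 1 kbp covers plausible read-through
without swallowing neighboring loci), `utr5` inside the 5′UTR, `body`
beyond it. Transcript length is summed aligned block length (adapters
excluded), and "full-length" means > 6000 bp.

## Chimeric transcripts and frame checking

A spliced transcript is chimeric for an element/gene pair when it starts
inside the element 5′UTR, carries ≥ 1 splice junction whose acceptor
matches an annotated exon start within ± 2 bp (long-read splice wobble),
runs on the gene's strand, and overlaps the element by ≥ 20 bp. Transcripts
antisense to the element represent the L1 antisense-promoter configuration
and are flagged `antisense_to_element = TRUE`; sense-promoter events are
reported but flagged, not dropped. The frame check takes the chimera's
longest AUG-initiated ORF (≥ 50 codons, a floor against spurious uORFs) and
declares it in frame when the translated C-terminal region is identical to
the canonical protein over every codon lying fully downstream of the first
shared exon; `novel_nterm_aa` is the residue count unique to the chimera.
Codons spanning the junction are excluded from the comparison, so genes
whose shared exon starts mid-codon are handled conservatively. The
genome-wide screen restricts elements to young subfamilies
(TFI/TFII/TFIII/GF/A by default, configurable) and reports one row per
element with read support counts.

## Bisulfite amplicons

At each reference CpG a read's C means methylated, T unmethylated, anything
else missing; per-read conversion efficiency is the fraction of non-CpG
reference cytosines read as T, and reads under 0.95 are rejected (standard
bisulfite QC). Reads are deduplicated by exact sequence before the seeded
sampling of 100 nonidentical reads; no fuzzy PCR-duplicate collapsing is
attempted. Classes: fully unmethylated (mCpG = 0), nearly unmethylated
(0 < mCpG < 5), plus the combined mCpG < 5 class used by dashed-line
lollipop conventions. Per-read mCpG% uses scored (non-missing) CpGs as the
denominator.

## What the simulator emulates — and what it does not

`build_genome()` plants, per configuration: a cohort of L1 elements
(default 500) with six tandem copies of a bundled 206 bp toy monomer
(five CpGs per copy, 2% substitution noise), a CpG-free linker, and a body
carrying the RACE primer site; SINE/LTR decoys above their family cutoffs;
and gene cassettes whose first intron holds a full-length antisense L1
driving a chimeric transcript into gene exon 3 — in frame by default, or
frameshifted by a 4 bp deletion in its unique region. Methylation calls
draw per-CpG Bernoulli states at per-locus probabilities with a 5%
ambiguous-call rate and llr magnitude 5; the population defaults are the
study's printed monomer methylation means (PV⁺ 83.9%, PV⁻ 91.8%), escapee
loci sit at 2%, and depth is 10 reads/locus (~30 5′UTR CpGs/locus, ~300
calls). RACE reads (default 1000) follow a TSS mixture of 0.1 upstream /
0.8 5′UTR / 0.1 body with the full-length share set by allocating 5′UTR
TSSs above or below the 6 kbp span point (presets: 76.0% sorted-PV, 63.8%
bulk). Everything is deterministic per seed.

The simulator does **not** emulate: sequencing error in read bases or
alignment (blocks are exact), within-read call correlation, copy-number or
mapping ambiguity among near-identical young elements, litter-level
biological replication, or mm10-scale genome context. Passing tests
therefore demonstrate correctness of the statistical and bookkeeping
machinery under the stated generative model — not robustness to mapping
artifacts in real young-L1 analysis, where unique-placement filters carry
most of the weight.

## Numerical and design choices

- Fisher p-values are computed by direct hypergeometric summation
  (`stats::dhyper`), exact for all practical table sizes; Bonferroni via
  `stats::p.adjust`.
- `delta = fraction(popB) − fraction(popA)`; `direction` names the
  population with lower methylation, so the hypomethylation claim can be
  read off without sign conventions.
- Degenerate inputs: all-zero Fisher tables error; empty composite
  selections warn and return empty profiles; reads tied between elements,
  non-numeric llr rows, and unalignable amplicon reads are dropped with
  logged counts rather than silently.
- Validation scales (chosen to keep the default suite fast): 500-locus
  cohorts for parameter recovery, 100 seeded null cohorts for
  family-wise-error calibration, 1000-read RACE sets, exhaustive Fisher
  enumeration over all tables with margins ≤ 40, and 50 random fixtures for
  the aggregation/profile oracles.

## Limitations

Real-data quantities that depend on deposited sequencing archives (locus
counts among differentially methylated elements, subfamily shares of
top-ranked loci, genome-wide chimera counts) are outside what synthetic
cohorts can reproduce and are not claimed by this package's tests. The
monomer detector assumes tandem, gap-free monomer copies; elements with
large 5′UTR indels will undercount. The bisulfite caller expects
amplicon-aligned, forward-orientation reads.
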