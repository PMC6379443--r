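---
title: "Detecting linked bystander structural variants at CRISPR-edited loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting linked bystander structural variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Paired Cas9 cuts around a regulatory element are expected to yield a clean
deletion. Repair, however, can also produce large structural rearrangements
*adjacent* to the on-target site — here the case of interest is a tandem
duplication of the sequence immediately downstream of a deleted intronic
enhancer. Such a **bystander mutation** travels with the intended edit
through breeding (it is physically linked), and a junction-spanning PCR
genotyping assay across the deleted element still produces the expected
band, so it escapes routine screening. Whole-genome sequencing reveals it
through two independent signals, which this package implements:

1. **Read depth.** A duplicated segment has twice the copy number. With
   windowed depth $d_w$ and a robust normalizer $\hat m$ (the sample's
   median window depth), the ratio $r_w = d_w/\hat m$ is $\approx 2$ for a
   homozygous and $\approx 1.5$ for a heterozygous gain, with binomial
   sampling noise at 30× of roughly $\mathrm{sd}(r_w) \approx
   \sqrt{r_w/(30 \cdot 500)} \cdot \sqrt{30} \approx 0.1$ per 500-bp
   window — comfortably separated from 1.
2. **Read pairs and the junction.** A head-to-tail duplication of
   $[s, e)$ creates a novel junction joining position $e$ back to $s$.
   Fragments spanning it align as *everted* (outward-facing) pairs —
   leftmost mate reverse, rightmost forward — and reads crossing it are
   soft-clipped. Assembling those reads reconstructs the junction contig,
   whose flanks anchor $e$ and $s$ at base-pair resolution.

The repair signature is quantified by **microhomology**: the largest $m_L$
with $\mathrm{ref}[e-m_L, e) = \mathrm{ref}[s-m_L, s)$ plus the largest
$m_R$ with $\mathrm{ref}[e, e+m_R) = \mathrm{ref}[s, s+m_R)$. The total
$m_L + m_R$ is also the interval over which the breakpoint is inherently
ambiguous: any cut position within it reconstructs the identical allele.
We report the left-aligned (smallest $e$) representative plus the range.
An **extended homology** scan (maximal exact matches ≥ 10 bp between a
±200 bp cut-site window and the junction windows, both strands)
distinguishes microhomology-mediated repair from homology-directed events;
on i.i.d. sequence a ≥ 10 bp chance match in two 200-bp windows has
probability ≈ $200^2/4^{10} \approx 0.04$, so an empty result is the
expected negative.

Downstream consequences are assessed on the transcript: a duplicated
internal exon (here exon 2) shifts the reading frame when its length is
not a multiple of 3, so the exon-chain `E1-E2-E2-E3-…` acquires a
premature termination codon, while correctly spliced single-exon-2
transcripts remain productive. Junction k-mer counting on raw RNA reads
(exact substring, one count per read) measures the ratio of the two
isoforms without alignment.

## Modules and the decisions behind them

### Synthetic locus (`locus_forge`)

The generator *is* the stated world the tests run in: a 100-kb locus, an
8-exon gene, a 360-bp enhancer in intron 1 at [10000, 10360), Cas9 cut
sites at both enhancer edges, and a 24,000-bp duplication span starting
immediately downstream of the enhancer at [10360, 34360) with 3 nt of
planted left microhomology. WGS simulation uses 150-bp FR pairs, insert
400 ± 60 bp (the library's stated 400-bp target; the 60-bp spread is a
typical hybrid-capture-free prep value), substitution-only errors at
0.1%, and `round(depth × L / (2 × read_length))` pairs so the requested
depth is exact by construction. Fragment lengths are normal, truncated to
`[2 × read_length, L]`; note the truncation lifts the realized mean by
about 6 bp, which the tests account for explicitly.

Two generator choices deserve justification:

* **Microhomology planting.** The spec'd idea of verifying that the
  planted string "does not recur within 50 bp" cannot work for a 3-mer —
  any 3-mer recurs in a random 50-bp window with probability near 1. What
  actually makes the junction placement unambiguous is *divergence
  immediately flanking the planted homology*, so `build_locus` enforces
  `ref[s-mL-1] != ref[e-mL-1]` and `ref[s+mR] != ref[e+mR]` instead
  (mutating one base deterministically when needed). The planted
  microhomology is then exactly (mL, mR) by construction.
* **Crafted coding sequence.** Exon 2 is built to start `AACTGTGTCT` and
  end `ACCAGCAACT`, and exon 3 to start `CCCATGACAA`, so the gene model's
  junction 20-mers equal the two assay k-mers. The wild-type frame is
  opened by resampling any stray stop codon (never touching planted
  bases), and a stop is planted at an exon-2 offset that is codon-aligned
  only in the frame adopted by a *second* exon-2 copy — making the
  premature-stop prediction deterministic rather than left to the ~88%
  chance that a random frameshifted tail contains one.

The cohort generator plants one private exonic candidate and six decoy
categories (shared, background-panel, low-depth, multiallelic,
missing-genotype, private non-exonic), plus six background variants within
±5 bp of predicted off-target sites, mirroring the structure of the real
screen's inputs. Off-target site *prediction* is out of scope; sites are
consumed as a ranked table (49 per guide).

### Aligner and depth (`align_depth`)

Exact 21-mer seeds vote for (diagonal, strand); the top candidates are
rescored by a local affine-gap Smith–Waterman (match +1, mismatch −4, gap
open −6, extend −1; a gap of length $L$ costs $6 + L$) in a ±16 bp window,
implemented in C++. Local alignment gives the junction soft-clip behaviour
for free, and ties resolve to the lowest reference position, then the
forward strand, so output is deterministic. Limits worth knowing: with
21-mer seeds, two substitutions less than 21 bp apart on a ≤ 60-bp read
can eliminate every exact seed (the property tests construct interior,
well-separated errors for exactly this reason), and terminal mismatches
are clipped rather than aligned — both standard behaviours for
seed-and-extend aligners.

Windows default to 500 bp: a 24-kb event spans 48 windows, large enough
for segmentation statistics and small enough for ± one-window boundary
recovery. Elevated blocks are maximal runs of windows with ratio ≥ 1.4
(detects 1.5× heterozygous gains at 30× while rejecting single-window
noise), bridging at most one sub-threshold window, reported at ≥ 5
windows. These thresholds are this package's decisions — the original
analysis called the block by eye from pileups, and no numeric threshold
exists to inherit. Normalization defaults to the intra-sample median
(robust while the event occupies < 50% of the locus); a control-profile
ratio mode mirrors a case-versus-control comparison.

### Breakpoints (`sv_breakpoint`)

Candidates are alignments with ≥ 20 bp soft-clip plus both mates of
everted pairs, oriented to the forward reference strand. Assembly is a
minimal de Bruijn unitig walk (k = 31, reduced for short reads; k-mers
with count 1 are dropped when ≥ 10 reads are available). Because an
edited locus can carry *several* genuine junctions — here the on-target
deletion junction and the bystander duplication junction — the assembler
seeds one unitig per novel-k-mer component (novel = absent from the
reference) and returns all placed junctions, with the best-supported one
as primary and the rest retrievable via `all_junctions()`. The pipeline
then selects the tandem-duplication junction consistent with the elevated
block, which is the discovery logic the depth signal motivates.
"No junction" (too few reads, or contig fully reference-mappable) and
"ambiguous" (branching graph with no unique path) are flagged distinctly.

### Variant filters (`variant_filter`)

Two open questions in the source methods were resolved as follows, with
both options exposed: "sufficient average coverage (≥ 10 reads)" is read
as *cohort-mean* DP ≥ 10 (per-sample minimum available via
`per_sample = TRUE`), and "unique or in excess" is operationalized as
strict inequality of alternate-allele counts (affected > every unaffected
sample; genotype dosage 0/1/2). Background subtraction matches on
position + ref + alt, not position alone — conservative in the sense of
subtracting only what the panel actually contains. Exonic overlap is
any-overlap against half-open BED intervals. Stages 1–3 and 5–6 are set
intersections and therefore order-insensitive; the trace records each
stage count and is non-increasing by construction.

### Isoforms and PCR (`isoform`)

K-mer counting is read-level and forward-only by default, matching a
plain-text grep of raw FASTQ; reverse-complement matching is a flag
because library strandedness varies. Normalization is per total reads
(per-million available for reporting). Premature-stop classification
anchors the annotated terminal stop from the transcript 3′ end (the
terminal exons are shared across chains), so it is well defined on chains
whose absolute coordinates shift; the 50-nt junction rule for
nonsense-mediated-decay candidacy is reported as an annotation only. In
silico PCR requires exact, unique, convergent primer matches within a
1-kb product cap; two candidate products yield "ambiguous" rather than a
guess.

## What a green test does and does not establish

The generator emulates read geometry, copy-number signal, junction
structure, isoform mixtures and cohort genotype patterns. It deliberately
omits: PCR duplicates, GC bias, quality-score models, indel sequencing
errors, repetitive reference structure (background is i.i.d.), multi-contig
genomes, and genome-scale variant counts (the real screen's 2407 surviving
variants depend on a full genome and a strain panel, and are explicitly
out of the desk-scale acceptance surface). Green tests therefore establish
correctness of the detection logic under its stated model, not calibrated
performance on real libraries — thresholds tuned here (ratio ≥ 1.4,
min 5 windows) would need re-examination under real noise.

## Numerical conventions

All coordinates are 0-based half-open internally; 1-based only in
VCF/SAM serialization. Random draws are seeded explicitly everywhere;
identical configuration and seed give byte-identical FASTQ, VCF and
report output (timestamps are excluded from reports for this reason).
Degenerate inputs fail loudly: `s == e` junctions, missing start codons,
no-proper-pair libraries, out-of-range features (named in the error), and
affected samples absent from the cohort all raise errors rather than
returning defaults.
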