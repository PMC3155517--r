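---
title: "Methods: small-RNA discovery from mixed 454 and SOLiD libraries"
author: "srnapipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-RNA discovery from mixed 454 and SOLiD libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`srnapipe` implements a discovery pipeline for small non-coding RNAs in
a compact genome, designed around a mixed sequencing strategy: one
library of adapter-flanked long reads (454-style base space) and two
libraries of short fixed-length colorspace reads (SOLiD-style, 35
colors per read). The pipeline takes raw reads plus a genome with gene,
repeat, and structural-RNA annotation, and produces:

* a non-redundant set of genome-mapped small-RNA *tags* with per-library
  counts,
* strand-aware binned coverage profiles per library,
* miRNA candidate loci passed through hairpin-structure filters and a
  cross-library evidence rule,
* repeat-associated siRNA (rasiRNA) and natural-antisense siRNA
  (nat-siRNA) classifications for the remaining tags,
* miRNA target predictions under both a plant-style and an animal-style
  pairing model, with GO functional-bias ratios for the target genes.

A paired synthetic-data generator plants loci of every class with a
complete truth manifest, so the whole pipeline can be scored for recall
and false positives on data whose answers are known exactly.

# Read processing

## 454-style reads: adapter excision

Each long read must contain a 5' linker
(`ATCGTAGGCACCTGAAA`) and a 3' linker (`ACTGTAGGCACCATCAAT`); the
insert is the subsequence strictly between the two matches. An adapter
match may lack up to 3 terminal nucleotides from either end (internal
mismatches are not tolerated); a read whose best adapter match would
require 4 or more missing bases is rejected, as are adapter-only reads.
Variants are tried longest first, so the fullest adapter match wins.

## SOLiD-style reads: colorspace decoding and alignment trimming

SOLiD reads are dibase-encoded: each color is the XOR of the 2-bit
codes of adjacent bases (A=0, C=1, G=2, T=3), seeded by a primer base.
Decoding is the running XOR of the color stream; a single color error
corrupts every decoded base downstream of it, which is why the pipeline
treats decoded SOLiD reads conservatively.

Because 35-cycle reads usually run through the insert into the 3'
adapter, reads are trimmed *by alignment*: a decoded read is kept when

1. it matches the genome full-length exactly (0 mismatches), or
2. it matches full-length with exactly one mismatch (rescuing reads
   whose single color error decodes into a tail that still aligns), or
3. a 100%-identity genomic prefix of at least the minimum insert length
   exists; the read is trimmed to the longest such prefix.

Candidate locations come from a 16-mer index over both genome strands;
priority is in the order above, so a full-length one-mismatch hit is
preferred over a shorter exact prefix. Reads failing all three are
rejected.

## Redundancy clustering

Kept inserts are clustered at 100% identity with a length-similarity
floor of 0.8: a shorter sequence joins a cluster when it is an exact
substring of the representative and its length is at least 80% of the
representative's. Representatives are processed longest first (ties
broken lexicographically), mirroring greedy incremental clustering.
Each cluster becomes one tag carrying per-library occurrence counts.

## Degradation filtering and genome mapping

Tags are screened against a structural-RNA reference (rRNA/tRNA): a tag
whose best local alignment covers at least 70% of the tag at 90%
identity or better is removed as a probable degradation fragment —
unless its best hit is an annotated miRNA, which exempts it. Surviving
tags are mapped to the genome allowing at most 1 mismatch; all
occurrences on both strands are recorded.

# Coverage profiles

Alignments are accumulated into fixed-width bins (default 10,000 nt)
keyed by the 0-based start coordinate of the alignment, separately per
strand and per library, and normalized by the library's total tag
count so libraries of different depth are comparable. Raw counts are
retained alongside. Exports are a per-chromosome histogram table
(minus-strand values negated, so they plot below the axis) and a
library-by-bin heatmap matrix.

# miRNA calling

For each alignment of a candidate tag (length 18–24 nt, no overlap with
annotated repeats), the surrounding region ±100 nt is excised in both
the tag-upstream and tag-downstream orientation and folded with a
nearest-neighbor-free additive model (G:C = −3, A:U = −2, G:U = −1
kcal/mol, +4 per hairpin closure, minimum loop 3), computed by dynamic
programming in C++ with traceback. A candidate precursor passes when:

* the mature sequence lies on one arm of a stem-loop,
* predicted folding energy is strictly below −20 kcal/mol,
* the loop between the mature arm and its partner spans at least 10 nt,
* no bulge larger than 3 nt interrupts the mature/star duplex; the
  bulge statistic is the largest of (i) unpaired gaps between
  consecutive paired mature positions, (ii) the span skipped between
  consecutive star-side partners, and (iii) the unpaired overhang at
  the mature ends.

A locus is reported when the mature tag is seen in at least 2 of the 3
libraries, **or** a star tag is observed: a distinct tag aligning
within ±3 nt of the predicted star interval (the reverse-complement
partner positions plus the canonical 2-nt 3' overhang). Mature/star
pairs that each pass independently are merged into a single locus
(the higher-count arm is reported as mature). Each call is labeled
exonic/intronic/intergenic by majority over its alignments, and its
first 10 nt are compared against known mature miRNAs, calling a seed
match at ≤1 mismatch.

# siRNA classification

Tags that are not miRNA calls are partitioned:

* **rasiRNA** — at least 1 nt overlap with an annotated repeat;
  per-library repeat-family composition tables are emitted. Sequence
  sharing between libraries is assessed with ungapped best-scoring
  local matches (match +1, mismatch −3) under a Karlin–Altschul
  E-value with λ = 1.33, K = 0.621, at E ≤ 1e−5.
* **nat-siRNA** — classified against full gene spans as sense,
  antisense, or intergenic per alignment; tags with alignments in
  multiple categories are `mixed`, and a locus overlapped on both
  strands counts as sense.

# Target prediction

Transcript sequences are spliced from the annotation (strand-aware,
with CDS boundaries derived from the UTRs). Two site models are
scanned:

* **animal** — exact antisense match of the miRNA seed, nucleotides
  2–7, anywhere in the transcript; overlapping occurrences all count.
* **plant** — near-perfect ungapped duplex over the full miRNA: at most
  1 defect in the 8-nt 5' seed, at most 3 defects elsewhere, G:U wobble
  counted as a defect but still scoring −1, and hybrid energy of
  −20 kcal/mol or better. Overlapping plant sites are resolved to the
  lowest-energy one.

Sites are assigned to 5' UTR / CDS / 3' UTR by their midpoint. GO
functional bias is the ratio of the term's frequency among target
genes to its genome-wide frequency, ranked descending.

# The synthetic-data generator

`sim_config()` defaults define the reference experiment: 4 chromosomes
of 30 kb; 40 genes; 30 repeat loci over four transposon families; 20
miRNA loci; 20 antisense loci; 4 rRNA and 4 tRNA genes; 10 planted
target sites; 3 libraries (one 454, two SOLiD); 10% of reads drawn from
structural-RNA degradation; color-error rate 0 (settable, e.g. 0.02).
All randomness flows from a single seed and the same configuration
reproduces identical bytes.

Design choices worth knowing when interpreting results:

* **Hairpins are provably optimal under the fold model.** Planted
  precursors use G/C-only arms with A-only loops and flanks, so the
  designed stem is the mathematically best structure the simplified
  energy model can find, and the planted mature/star duplex is exactly
  what the caller sees. Two interior G→A star defects keep the star
  from cross-mapping to the mature arm at ≤1 mismatch while staying
  within the bulge tolerance. Real pre-miRNAs are of course not
  GC-pure; this is a property of the *generator*, not the caller.
* **Negative controls are vetted.** Antisense loci are
  rejection-sampled until their genomic context does *not* pass the
  hairpin filters, so a correct caller must score zero false positives
  on them.
* **Adapter-extension artifacts are avoided by construction.** Tag
  positions whose genomic continuation begins with the 3' adapter's
  first base are resampled, since alignment trimming of a 35-cycle
  read would otherwise legitimately extend the insert past the
  planted boundary.
* **Planted target sites** are the antisense of a planted mature with
  two mismatches placed outside both seed definitions, packed into CDS
  exons without overlap.
* The generator does **not** simulate quality scores, indels,
  polymerase artifacts, chimeric reads, or expression-level dispersion
  beyond Poisson depth.

# Numerical and coordinate conventions

* All genomic intervals are 1-based and closed (the Bioconductor
  `IRanges` convention) in every API and output table; BED inputs are
  converted on read, GFF3 is used as-is.
* The folding DP resolves ties toward outer stem pairs (pair first,
  then shift the 5' end, then the 3' end, then bifurcate), making
  tracebacks deterministic.
* Problem sizes (genome size, locus counts, depths) are package
  defaults chosen so a full run completes in well under a minute on one
  core; they are configuration, not constants.

# Limitations

The fold model is a maximum-weighted-matching surrogate, not a full
nearest-neighbor thermodynamic model: absolute energies are not
comparable to ViennaRNA/mfold values, and the −20 kcal/mol cutoff is
meaningful only within this model. Discrimination between real hairpins
and background relies mainly on the duplex-geometry filters (loop,
bulge, star pairing), which is why those are tested exhaustively.
Clustering is greedy and order-dependent by design (longest-first);
alternative orders can yield different representatives for borderline
clusters. The E-value model for cross-library matching assumes ungapped
local alignment statistics.

# Reproducing a full run

```{r demo}
library(srnapipe)
res <- run_synthetic_demo(sim_config(seed = 17), dir = "demo_out")
res$recovery
```

`scripts/acceptance.R --seed <int> --out <path>` wraps exactly this and
writes the headline quantities as JSON.
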