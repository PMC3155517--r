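# srnapipe

Discovery and classification of small non-coding RNAs from mixed
sequencing libraries: one adapter-flanked long-read (454-style)
library and short fixed-length SOLiD colorspace libraries, against an
annotated compact genome. The package covers the full path from raw
reads to biology:

1. **Read processing** — 454 adapter excision (both linkers required,
   up to 3 missing terminal bases tolerated per adapter); SOLiD
   colorspace decoding (running XOR of the dibase color stream) with
   alignment-based trimming against the genome (full-length exact,
   full-length 1-mismatch rescue, or longest 100%-identity prefix);
   redundancy clustering at 100% identity with a 0.8 length-similarity
   floor; degradation filtering against rRNA/tRNA (≥70% coverage at
   ≥90% identity removes a tag, annotated miRNAs exempt); genome
   mapping at ≤1 mismatch, all occurrences.
2. **Coverage profiles** — strand-aware 10-kb binning per library,
   normalized by library totals; histogram and heatmap exports.
3. **miRNA calling** — each candidate's ±100-nt context is folded with
   an additive stem-loop model (G:C −3, A:U −2, G:U −1, +4 per hairpin
   closure; DP with traceback, in C++). A precursor passes when the
   mature lies on one stem arm, MFE < −20, loop ≥ 10 nt, and no duplex
   bulge > 3 nt. A locus is called with mature tags in ≥2 of 3
   libraries *or* an observed star tag (±3 nt around the predicted
   star with its 2-nt 3' overhang); repeat-overlapping tags are
   excluded; calls are checked against known miRNAs by a ≤1-mismatch
   match over the first 10 nt.
4. **siRNA classification** — repeat-associated siRNAs (≥1 nt repeat
   overlap, per-library family composition, cross-library sequence
   sharing under Karlin–Altschul E-values with λ = 1.33, K = 0.621 at
   E ≤ 1e−5) and natural-antisense siRNAs (sense/antisense/intergenic
   against full gene spans).
5. **Target prediction** — animal-style (exact antisense seed match,
   miRNA nt 2–7) and plant-style (ungapped duplex, ≤1 defect in the
   8-nt seed, ≤3 elsewhere, wobble counts as a defect, energy ≤ −20;
   overlapping sites resolved by energy), with 5'UTR/CDS/3'UTR
   assignment and GO functional-bias ratios.

A paired synthetic-data generator plants miRNA, rasiRNA, and
nat-siRNA loci with a full truth manifest, so the pipeline's recall
and false-positive behavior can be measured exactly. See
`vignettes/methods.Rmd` for the model details and the generator's
design guarantees.

## Worked example

Generate the default synthetic experiment (4 × 30 kb chromosomes, 20
planted miRNA loci, 30 repeat-derived and 20 antisense loci, one 454
plus two SOLiD libraries) and run the whole pipeline on it:

```r
library(srnapipe)
res <- run_synthetic_demo(sim_config(seed = 17), dir = "demo_out")

res$recovery
#>      class planted tp fn fp recall precision
#> 1    mirna      20 20  0  0      1         1
#> 2  rasirna      30 30  0  0      1         1
#> 3 natsirna      20 20  0  0      1         1

res$log$unique_tags[1]
#> [1] 80

head(res$mirna_calls[, 1:5], 3)
#>                sequence length chrom start   end
#> 1 CCCGCCCGGCCCCCGGGGCGC     21  chr3 18505 18525
#> 2 CCCGGGGCCCCGGCCGGGGGC     21  chr4 18876 18896
#> 3 CCGCCGCCGGCGGCCCGCGCC     21  chr2 20456 20476

subset(res$sirna$summary_tags, library == "L454")
#>   library         class percentage
#> 1    L454         mirna   16.66667
#> 2    L454       rasirna   50.00000
#> 3    L454     nat-sense    0.00000
#> 4    L454 nat-antisense   33.33333
#> 5    L454    intergenic    0.00000
#> 6    L454         mixed    0.00000

res$targets$summary
#>     mode frac_transcripts pct_five_utr   pct_cds pct_three_utr
#> 1 animal            0.925     5.691057  86.17886      8.130081
#> 2  plant            0.250     0.000000 100.00000      0.000000

head(res$known_hits, 2)
#>                sequence           known offset mismatches
#> 1 CCCGGGGCCCCGGCCGGGGGC known-planted-1     12          1
#> 2 CCGGCGCGGGCCCGGCCGGGG known-planted-3      1          0
```

All result tables (tags, rejected reads, coverage, miRNA calls, siRNA
distribution, targets, GO ratios, recovery) are also written as TSV
files under `demo_out/out/`; `res$files` lists them.

To run on your own data, build a `run_config()` with paths to the
genome FASTA, GFF3 gene models, repeat/ncRNA annotation, and the read
files, then call `run_all(cfg)`. A command-line wrapper is installed
at `inst/cli/srna.R`:

```sh
Rscript inst/cli/srna.R demo --seed 17 --out demo_dir
Rscript inst/cli/srna.R run --genome g.fa --gff genes.gff3 \
  --reads-454 LIB1=reads.fa --reads-solid EF=ef.csfasta,EC=ec.csfasta \
  --out out_dir
```

## Package layout

- `R/formats_io.R` — FASTA/GFF3/BED/csfasta readers and writers, the
  `tag_set` container, genome bundle validation.
- `R/colorspace.R` — SOLiD dibase encoding and decoding.
- `R/synthetic_data.R` — the planted-truth generator.
- `R/preprocess.R` — adapter excision, alignment trimming, clustering,
  degradation filtering, genome mapping.
- `R/coverage.R` — binned strand-aware profiles and exports.
- `R/fold.R`, `src/fold.cpp` — stem-loop folding (DP + traceback).
- `R/mirna.R` — precursor assessment and miRNA calling.
- `R/sirna.R` — rasiRNA/nat-siRNA classification and cross-library
  statistics.
- `R/targets.R` — plant/animal target scans and GO ratios.
- `R/pipeline.R` — orchestration, recovery scoring, the demo driver.
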