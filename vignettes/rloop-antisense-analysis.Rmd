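---
title: "Methods: strand-aware analysis of R-loop-driven antisense transcription"
author: "rloopas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strand-aware analysis of R-loop-driven antisense transcription}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rloopas)
```

## The question and the analysis

R-loops are three-stranded structures formed co-transcriptionally: an
RNA:DNA hybrid plus the displaced single-stranded DNA. The hypothesis this
package's analysis is built around is that R-loops are not merely
by-products of transcription but can act as *promoters* of antisense (AS)
transcription: lower-level non-coding transcripts initiating near gene
promoters (5'AS / PROMPTs), inside gene bodies (gene AS), near terminators
(3'AS), and at enhancers (eRNA). The computational signature of that
hypothesis has three parts:

1. R-loop peaks, mapped strand-specifically, concentrate at TSS and TES
   regions of genes;
2. AS transcript 5' ends lie close to R-loop peaks (within a few hundred
   bp);
3. removing R-loops by overexpressing RNase H1 — which degrades the RNA
   moiety of the hybrid — preferentially reduces those AS transcripts
   (a "sensitive" transcript is one whose expression drops at least
   1.5-fold).

`rloopas` implements every computational stage of that argument as a
reusable, tested pipeline: peak calling, genomic classification, stranded
quantification, sensitivity scoring, association, metagene profiling,
capped-5'-end cluster analysis, and bisulfite ssDNA footprint mapping —
driven by a synthetic-data generator with machine-readable ground truth, so
that every stage's precision and recall can be measured rather than
assumed.

The experimental designs emulated are: an R-loop IP track from a
catalytically dead, hybrid-binding RNase H1 mutant (D210N) with a
non-binding mutant (WKKD) as background; chromatin RNA sequencing (a
nascent-transcription proxy) with and without RNase H1 overexpression; and
cap-selected 5'-end sequencing giving single-nucleotide TSS positions.

## Data model

All tracks are **5'-end single-position tags**: a tag is one
(chromosome, position, strand) triple. Every statistic in the pipeline
consumes position counts, so this representation is lossless for the
analysis while keeping the generator's expectations analytic (per-class
Poisson counts with uniform or triangular positions). Paired-end fragment
geometry, read errors and alignment are out of scope; the pipeline consumes
aligned tag files (BED6).

Coordinates are 0-based half-open internally (BED convention); GTF I/O
converts to and from 1-based closed form. The TSS of a gene is its 5' end
in the direction of transcription (`start` for `+`, `end - 1` for `-`) and
the TES its 3' (poly(A)) end. Gene spans read from GTF run from the most 5'
TSS to the most 3' TES over the gene's transcripts, and RPKM uses the
longest isoform's length.

## Peak calling

`call_peaks()` is a simplified MACS-style local-Poisson caller:

* sliding windows (default 200 bp every 50 bp) are scored, with strands
  pooled, by the Poisson upper tail `P(X >= k)` where
  `lambda = max(genome-wide rate, 1 kb local rate, 10 kb local rate)`
  estimated from the background track and scaled by the IP/background depth
  ratio. The local-maximum rule protects against locally elevated
  background;
* Benjamini–Hochberg adjustment is applied across *all* tested windows;
  windows with `q < 0.05` are merged when at most 100 bp apart;
* retained peaks must satisfy `fold_enrichment > 5` **and** `q < 0.05`;
* strands are assigned post hoc by majority vote of the stranded IP tags
  overlapping each peak; exact ties give `"."` and the peak is excluded
  from strand-specific analyses (and counted).

Two numerical choices deserve comment.

**Fold enrichment is the summit-region fold**: the maximum windowed
IP/expected ratio among a peak's significant windows, not the average over
the merged interval. Merging necessarily appends partially overlapping
flank windows to each peak; averaging over the merged interval would dilute
a genuinely 10-fold enrichment to roughly 4.5-fold and the retention rule
(fold > 5) would reject essentially every true peak. The summit-region
fold is also what MACS-style callers report and filter on.

**The summit** is the tag position with the maximum smoothed pileup (tags
within ±50 bp), leftmost on ties. With sparse single-position tags the raw
positional mode is degenerate; the ±50 bp smoothing makes the summit
concentrate at the true density peak.

There is no read-shifting model: 5' tags are used as-is. Whether the
background track or only the genome-wide rate is used as the null is
configurable; the default uses the matched background track (WKKD), which
is the stronger control.

## Genomic categories

After the non-overlapping gene filter — genes longer than 2 kb with no
other gene within 2 kb — each strand-assigned peak receives exactly one
category, windows oriented in the host gene's direction of transcription:

| category | window | strand |
|---|---|---|
| TSS | 2 kb upstream to 1 kb downstream of the TSS | gene strand |
| TES | 1 kb upstream to 2 kb downstream of the poly(A) site | gene strand |
| genebody | remaining genic region | gene strand |
| AS | gene span padded 2 kb both sides | opposite strand |
| intergenic | none of the above | — |

Conflicts are resolved by the fixed priority TSS > TES > genebody > AS
(the listing order above); among several genes offering the same category
the nearest anchor wins. A peak is "in" a window when its summit is
(`mode = "summit"`, the default, since peak summits are the downstream
currency); an any-overlap mode is also provided. Classification is exactly
symmetric under genome mirroring, which the test suite asserts.

## Quantification and sensitivity

`quantify()` counts tags by their stored position and normalises to RPKM
(per kb per million mapped tags) and RPM. Sense means the region's strand;
regions with strand `"."` (eRNA windows) pool both strands. The
promoter-window comparison (`tss_sense_antisense()`) takes sense tags in
the 3 kb downstream of the TSS and antisense tags in the 3 kb upstream —
the PROMPT geometry, matching the 3 kb PROMPT region definition.

Sensitivity to RNase H1 overexpression is a plain fold-change rule, by
design without a dispersion model:

`fold = (control_RPKM + pc) / (oe_RPKM + pc) ; sensitive <=> fold >= 1.5`

with pseudocount `pc = 0.1` RPKM stabilising low-expression ratios.
Sensitivity means *reduction* upon overexpression; increases of at least
1.5-fold are reported separately as `"up"`. An optional minimum-control
floor (`min_control_rpkm`, default 0) can exclude barely expressed
regions. Association uses the documented windows: AS 5' end within
±250 bp of a peak summit, any peak within ±500 bp of an eRNA region, a
peak summit within ±2 kb of a TES; the nearest peak is reported on ties.

## Metagene profiles and rank tests

Profiles use bins *centred* on offsets `-w, …, -b, 0, b, …, +w` (edge bins
half-width), so that the zero-offset bin straddles the anchor
symmetrically: a symmetric peak density then has its mode in the zero bin
instead of splitting across two bins, and orientation-corrected offsets
are exactly invariant under genome mirroring. Defaults are ±2 kb windows
with 50 bp bins. The peak-density profile attributes each summit to its
nearest anchor; `sum(density * binsize)` equals the fraction of peaks
within the window, exactly. Coverage metagenes report sense and antisense
per-anchor means scaled per million mapped tags. Group comparisons use the
standard rank tests (Wilcoxon rank-sum, Kruskal–Wallis) via their stats
implementations, cross-checked in the tests against an exhaustive
permutation oracle.

## Cap clusters

Capped 5'-end clusters are called by positional single-linkage: same-strand
positions at most 150 bp apart merge; clusters with fewer than 5 tags are
dropped; the mode position (most frequent 5' end, leftmost on ties) is the
cluster's TSS estimate. This is a deliberate, documented stand-in for
tss-style peak finding in HOMER: all downstream claims depend only on
cluster positions and counts. Cluster sensitivity counts tags over the
cluster interval per condition, normalises per million, and applies the
same 1.5-fold rule.

## Bisulfite ssDNA footprint

Bisulfite converts cytosine to uracil (read as T) only in single-stranded
DNA, so the displaced strand of a plasmid R-loop acquires C→T changes (or
G→A on the complementary strand). `call_conversions()` compares each clone
to the reference gap-free (clones are PCR amplicons of a fixed region, so
no aligner is needed): reference C with clone T is a conversion, clone C
unconverted; any other mismatch is a sequencing error, excluded from the
informative set, and clones with over 5% such errors are dropped.
Frequencies are computed over informative positions only. The footprint is
the longest contiguous run of informative positions whose running-mean
frequency (window of 5 informative positions) reaches `freq_threshold`.
The 0.5 default threshold is this package's choice — reported footprint
widths depend on it, which is why `footprint_interval()` also returns the
full smoothed track. Raising the threshold never widens the footprint, and
GA mode on reverse-complemented input reproduces CT results at mirrored
coordinates (both asserted in the tests).

## The synthetic-data generator

`generate_annotation()` + `simulate_tags()` define the study conditions
under which the pipeline is validated. Defaults:

| parameter | default | rationale |
|---|---|---|
| genome | 2 chromosomes × 2 Mb | small enough for seconds-scale runs, large enough for ~80k test windows |
| genes | 200, lengths 2–5 kb, gaps > 2.5 kb | every gene survives the 2 kb filters; one AS transcript each (n = 200) |
| enhancers | 20 intergenic centres | eRNA windows clear of genes |
| `depth` | 40,000 background tags/track | pooled background rate λ_bg = 0.01/bp; a 200 bp window then expects 2 background tags |
| `peak_fold` | 10 | pooled in-peak rate is exactly `peak_fold × λ_bg`; `peak_fold = 1` is an exact null used for FDR calibration |
| peak width | 400 bp, triangular | sub-kilobase peaked signal; a flat plateau would make summit positions arbitrary |
| `sense_rate` | 0.8/bp × lognormal(sdlog 0.2) | gives AS transcripts ~100–150 expected tags, enough for the 1.5-fold rule to separate 2-fold reductions from Poisson noise |
| `as_rate_ratio` | 0.1 | AS abundance is described only as "lower level"; one tenth of sense is a modelling choice, exposed in the config |
| AS transcripts | 1.2–1.8 kb; classes 5'AS/geneAS/3'AS at 50/25/25% | the three AS categories; in promoter-coupled mode (default) each 5' end is planted within 150 bp of a peak summit as a positive control for the ±250 bp association |
| `frac_as_sensitive` | 0.5 | Bernoulli per transcript; sensitive loci drop `oe_reduction_factor`-fold (default 2) in the overexpression track |
| cap tags | 400/TSS, 120/AS 5' end, jitter sd 10 bp | cluster counts high enough that the per-million-normalised fold rule recovers sensitive AS cap clusters |

`depth` is interpreted as the *expected background* tag count per track
(λ_bg = depth / genome bp, pooled over strands); sense and cap signal
loads are controlled by their own rates, since a single total could not
fix the background rate that every null distribution depends on.
Planted peaks add `(peak_fold − 1) × λ_bg` on the peak's strand, so the
pooled in-peak rate is exactly `peak_fold × λ_bg` and setting
`peak_fold = 1` yields an exact null. Each assay/condition pair draws from
its own RNG stream derived from the seed, so adding a track never changes
another track's tags, and identical configs give byte-identical output.

What the generator does **not** emulate: overdispersion (all class counts
are Poisson — real chromatin libraries are overdispersed, so real-data
false-positive rates will exceed the calibrated ones), splicing and
isoform structure, mappability and GC bias, copy-number variation,
read-level errors, and overlapping/nested genes (the generator plants only
well-separated genes, i.e. the favourable regime of the 2 kb filter).
Passing recovery tests therefore demonstrates correctness of the
*computations* under the stated model, not performance on real libraries.

## Problem sizes and determinism

The test suite and the acceptance script run, by the package's own choice
of scale: oracle equivalence of the caller on a 50 kb chromosome
(brute-force direct-summation scan, agreement to 1e-12); FDR calibration
over 100 null simulations; recovery of the 420 planted peaks and 200 AS
sensitivity labels under the default conditions above; 1,000-replicate
null calibration of the Kruskal–Wallis p-values; 100-seed bisulfite
footprint recovery at (p_in, p_out) = (0.9, 0.01) with 10 clones; and a
byte-determinism check of two identical pipeline runs. Every random draw
flows from a single integer seed.

## Limitations

The caller has no fragment-length model, no duplicate filtering (the
generator emits unique-ish tags) and no broad-peak mode; the sensitivity
rule is a fold change, not a test — with real replicate structure a
dispersion-based model would be preferable; classification assumes one
TSS/TES per gene; and the bisulfite module assumes gap-free clones.
These are scope decisions, not accidents: each matches the analysis this
package sets out to make reproducible.
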