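---
title: "Measuring Pol II promoter-proximal pausing with polpause"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring Pol II promoter-proximal pausing with polpause}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polpause)
```

## The statistic

RNA polymerase II frequently initiates transcription and then stalls 20-60 bp
downstream of the transcript start site (TSS) until a release signal lets it
elongate through the gene body. In a Pol II ChIP-seq experiment this pausing
shows up as a sharp pileup of coverage just downstream of the TSS relative to
the rest of the gene. polpause quantifies it with the **traveling ratio**
(TR, also called the pausing index):

$$ \mathrm{TR} = \frac{\mathrm{TSS} + \mathrm{BC}}{\mathrm{TU} + \mathrm{BC}} $$

* **TSS** — mean per-base pileup over the promoter-proximal window, −30 bp to
  +300 bp around the TSS in transcription direction;
* **TU** — mean per-base pileup over the remaining gene body, +300 bp to the
  annotated transcript end, *including introns* (Pol II occupies nascent
  chromatin, so no exon masking is wanted);
* **BC** — a background constant, the genome-wide average per-base coverage,
  computed as `total mapped reads × read length / genome size`.

BC acts as a pseudocount: it stabilizes the ratio over regions of very low or
zero coverage, and because it is itself a per-base coverage it keeps both
numerator and denominator in the same units. The estimator therefore assumes
the pileup track and the library statistics are on the **same scale** — raw
pileups with raw read counts, or per-million tracks with per-million counts,
never mixed. TR > 1 indicates promoter-proximal accumulation; TR > 2 is the
conventional census threshold for calling a gene "paused".

An isoform enters the analysis only if

1. it is at least 650 bp long (strictly shorter is excluded; exactly 650 bp
   is kept), and
2. the interval from 30 bp upstream of its TSS to its transcript end shares
   at least one base with a called peak for that sample.

Both filters are evaluated per sample: the peak-overlap filter restricts the
census to genes with detectable Pol II signal in that library, and the length
filter removes transcripts whose body window (which requires > 300 bp past
the TSS) would be tiny or empty. Exclusion reasons are checked in the order
*min_length*, then *no_peak*, and only the first failure is recorded.
Gene-level TR is the arithmetic mean over the gene's kept isoforms; genes
with no kept isoform are absent rather than zero.

### Minus-strand genes and coordinates

All coordinates are 0-based half-open throughout (BED convention); refFlat
input maps directly because UCSC refFlat `txStart`/`txEnd` already use that
convention. For a minus-strand transcript the TSS is its genomic *end*, so
the promoter window `[TSS−30, TSS+300)` in transcription direction
materializes genomically as `[end−300, end+30)`, and the body as
`[start, end−300)`. Windows are clamped to `[0, chromosome length]` and
means are taken over the clamped width, so bases that do not exist in the
assembly contribute nothing. A window that is empty after the ±300 bp
arithmetic (only possible for transcripts ≤ 300 bp, which the length filter
removes anyway) is flagged degenerate and the isoform excluded rather than
scored.

## Parameters and defaults

| parameter | default | units | meaning |
|---|---|---|---|
| promoter window | −30 / +300 | bp around TSS | pause-peak capture window |
| body offset | +300 | bp past TSS | start of the gene-body window |
| minimum isoform length | 650 | bp | shorter isoforms excluded |
| pausing census threshold | 2.0 | TR, strict `>` | a gene counts as paused if TR > 2 |
| TR fold-change threshold | 1.5 | ratio, inclusive `≥` | increase/decrease classification |
| expression fold threshold | 2.0 | linear fold, inclusive | "Up" group: log2FC ≥ 1 |
| metagene margin | 0.07 | fraction of gene length | flank on either side of the plotted span |

`run_config()` carries exactly these defaults and validates overrides; every
run writes them into a manifest so outputs are reproducible from the config
alone.

## Cross-condition comparison

`classify_tr_change()` joins two gene-level tables on gene id and labels each
jointly observed gene by `ratio = TR_treated / TR_control`: *increase* if
ratio ≥ 1.5, *decrease* if ratio ≤ 1/1.5, else *no change*. The inclusive
boundaries follow the "at least 1.5-fold" reading of the thresholds; the
census threshold TR > 2.0, by contrast, is strict. Only genes passing the
filters in **both** conditions are classified — the intersection is the only
universe on which the ratio is defined — and genes detectable in just one
condition are reported separately rather than silently dropped. Each sample
uses its own BC, computed from its own library statistics. Classification
operates on gene-level TR by default; callers wanting isoform-level
comparison can pass isoform tables, since only the `gene_id`/`tr` columns
are consumed.

For distribution displays, `group_distributions()` extracts the TR values of
named gene sets plus the complement, `random_gene_set()` draws seeded
size-matched random control sets (uniform, without replacement), and
`classify_expression_response()` splits genes at a twofold induction
boundary (`log2FC ≥ 1`, inclusive). `tr_density()` bins `log10(TR)` into 50
equal bins over the observed range — the display scale is a choice, not part
of the statistic, and is configurable.

## Metagene profiles

`metagene_coverage()` extracts the per-base pileup over a gene plus a margin
of `round(0.07 × gene length)` bases on either side, reverses minus-strand
profiles so position 0 is always the 5′ margin edge, optionally rebins by
mean into equal-width bins, and normalizes last (`raw` by default — figure
units are pileup units; `max1` and `per_million` are available). Margin
bases clamped off the chromosome are zero-filled and counted in
`n_clamped`, keeping profile lengths comparable across genes.

## The synthetic-data generator

`simulate_sample()` builds the statistical structure the TR statistic
assumes, with exact ground truth:

* a promoter component at density `a` reads/base over exactly the −30..+300
  window of each gene;
* a gene-body plateau at density `b` over +300..end;
* genome-wide background elsewhere;
* peaks emitted over every promoter window whose designed `a` exceeds the
  background, so the eligibility filter keeps exactly the intended genes;
* optional deliberately short (< 650 bp) and unbound (background-density,
  peak-free) genes to exercise the filters.

Three bookkeeping identities hold simultaneously and exactly at zero noise:
the designed BC equals `compute_bc()` of the emitted library statistics, the
total pileup mass equals `total_reads × read_length`, and per-base coverage
equals the designed densities over every analysis window. These constrain
each other: if the intergenic background were simply set equal to BC, genes
elevated above background would push the genome-wide mean above BC. The
generator therefore treats BC as the genome-wide mean and *solves* for the
intergenic background level that makes the mean come out exactly, rejecting
configurations whose designed gene mass exceeds what the intergenic space
can absorb (the fix is a higher `background`/`depth`, wider `gap`, or lower
densities). Chromosome lengths are rounded up to a multiple of 1 kb so
common depth choices give an integer read count.

With `noise = "poisson"` every base draws an independent Poisson count with
the designed density as mean — the natural count model for pileup depth.
All randomness flows through R's default Mersenne-Twister generator under
`withr::with_seed`, so identical configurations give byte-identical outputs
on any platform; a handful of sub-seeds are derived from the configured seed
by small fixed offsets (keep seeds below 2³¹ − 10).

### Default study conditions

The defaults describe a realistic desk-scale Pol II library: gene bodies at
20-40 reads/base (a deeply covered ChIP), genome-wide mean coverage 5
reads/base, 50 bp reads, gene lengths 1-3 kb, 30 kb intergenic gaps (genes
occupy a small fraction of the genome, as in mammalian assemblies, and the
gaps give the background solver room), 60% of genes designed paused with
pausing indices drawn from 2.5-8 and the rest from 1.05-1.8 — both ranges
kept clear of the census threshold 2.0 so designed classes are unambiguous.
`simulate_pair()` shares the layout and body densities between conditions
and scales the promoter density to hit a designed per-gene TR fold change
(`a_t = p·mult·(b + BC) − BC`), re-solving the background per sample;
increase multipliers default to 1.6-2.2, entirely above the 1.5-fold
classification boundary.

### What the simulation does and does not show

The generator reproduces the *contract* of the pipeline inputs — window
geometry, pileup units, peak/annotation/coverage dialects — with known
truth, so passing tests demonstrate that the implementation computes the
statistic it defines, recovers designed pausing indices under Poisson
counting noise, and classifies designed contrasts correctly. It does not
emulate mappability or GC bias, fragment-size smearing of the pause peak
beyond the designed window (a `smeared` promoter is deliberately out of
scope; the designed and measured windows coincide), overdispersion beyond
Poisson, input-control subtraction, or peak-caller behavior. Agreement on
synthetic data therefore validates the arithmetic and the plumbing, not the
biology of any particular real library.

## Validation problem sizes

The package's own validation uses a 1000-gene Poisson sample for parameter
recovery (≥ 95% of gene TRs within 5% of design is the expected behavior at
body depth ≥ 20 reads/base: the TR sampling error there is below 1.5%
relative), 300-gene condition pairs over 20 seeds for contrast recovery, and
1000 randomized window/track cases for checking the interval-mean kernel
against a brute-force per-base loop. These sizes give comfortable
statistical resolution for the tolerances being checked.

## Numerical notes and limitations

* Coverage tracks are run-length encoded (`S4Vectors::Rle`); split versus
  merged equal-valued bedGraph intervals are indistinguishable by
  construction, and window means come from `IRanges::viewMeans` in one pass.
* Overlapping bedGraph intervals are an error, not summed: a pileup is a
  function of position, and overlap almost always indicates a malformed
  track.
* Coverage values are accepted as non-negative reals, not only integers, so
  normalized tracks work — provided the library statistics match the scale.
* `read_length` for mixed-length libraries should be the mean read length,
  which preserves total sequenced bases in BC.
* Replicate merging, input subtraction, peak calling and alignment are out
  of scope: the pipeline consumes pileups and peak calls as produced
  upstream.
* Multiple isoforms sharing a gene id are averaged as given; no TSS
  clustering or symbol aliasing is attempted.
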