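---
title: "Models and methods behind traelr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind traelr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traelr)
```

`traelr` processes TrAEL-seq libraries, which ligate an adaptor to free
single-stranded 3′ DNA ends and sequence into the adjacent genomic DNA. In
proliferating cells the dominant such end is the 3′ terminus of the
replication-fork leading strand, so the data carry two signals at once: the
**polarity** of each read reports the direction of the fork that produced
it, and the **density** of reads reports how long forks dwell per unit
length. This vignette describes the models and numerical choices behind
each stage, what the bundled simulator does and does not emulate, and the
problem sizes used for validation.

## Read structure and demultiplexing

Each raw read is laid out as

```
[8-nt UMI] [4-nt inline barcode] [poly-T run >= 0] [genomic insert]
```

The UMI is ligated with the adaptor and distinguishes PCR duplicates from
independent molecules. The inline barcode sits at the ligation junction and
permits pooling up to six samples early in the protocol; barcodes are
specified on the adaptor strand, and because sequencing traverses the
complementary strand the in-read barcode defaults to the reverse complement
of the adaptor sequence (configurable, `barcode_table()`). The poly-T run
is templated by the terminal-transferase A-tail on the broken 3′ end, so a
DNA-derived read carries at least one leading T; reads with none are
segregated into a "noT" class that serves as a quality-control channel for
putative RNA-derived signal, and the main tracks use T reads only.

Choices where the protocol leaves latitude:

* **Mismatch tolerance 1, unique-best rule.** One-mismatch barcode rescue
  is standard for inline barcodes. The six bundled barcodes include one
  pair at Hamming distance 2, so a single corruption can be equidistant
  from two entries; the unique-best rule sends such reads to UNASSIGNED
  rather than ever misassigning them, and `barcode_table()` warns when a
  table is not fully separable at the configured tolerance.
* **Poly-T trimming** removes the maximal run of literal T after the
  barcode, with no mismatches tolerated inside the run — strict,
  reproducible, and conservative (an early sequencing error costs a few
  trimmed bases, never a wrong coordinate).
* **Minimum insert 20 nt** (configurable): shorter inserts are unlikely to
  map uniquely and are discarded (and tallied — assigned + unassigned +
  discarded always equals the input count).
* **UMI placement**: the UMI is appended to the read name after an
  underscore, so downstream files remain standard FASTQ/SAM and any aligner
  passes it through.

## Copy-number-aware deduplication

High-quality alignments (MAPQ above 20, i.e. uniquely placed) are
deduplicated by *(sample, chromosome, break position, strand, UMI)*:
identical molecules landing at genuinely distinct genomic copies survive as
distinct records. Alignments with MAPQ at or below 20 have unreliable
positions, so only the UMI can anchor deduplication — but the 8-nt UMI
keyspace is `4^8 = 65,536`, smaller than typical library complexity, so the
first 10 bases of the read sequence are appended to the key. Both
thresholds are independently configurable; records at exactly MAPQ 20 fall
in the sequence-keyed class while the separate analysis filter
(`filter_by_mapq()`, default ≥ 20) still retains them. The survivor within
a duplicate group is the first read in coordinate-sorted order with the
read name as tie-break, which makes the output deterministic and testable
against a brute-force group-by oracle.

## RFD tracks

With R reverse-strand and F forward-strand break counts per window,

$$\mathrm{RFD} = \frac{R - F}{R + F} \in [-1, +1],$$

positive values meaning forks moving left→right (TrAEL-seq captures the
leading-strand 3′ end, which points back toward the origin). Defaults
follow common practice for mammalian RFD: 20 kb windows spaced every 2 kb,
anchored at coordinate 0 with the final partial window kept. Windows with
fewer than `min_reads` (default 1) total reads are reported missing and
omitted from bedGraph output; the track is computed directly on the
−1..+1 scale. Within a multiplexed set no normalization is applied — the
within-set count distribution is itself the signal — while across sets each
whole set is rescaled by a single factor to the mean set total, preserving
within-set ratios exactly (`normalize_sets()`).

## Initiation-zone segmentation

Published IZ callers segment RFD with a hidden Markov model; `traelr`
ships a self-contained, equivalent-function segmenter rather than
reproducing any external tool bit-for-bit, and accepts externally produced
IZ BED files wherever zone centres are consumed. The model is a three-state
Gaussian HMM over per-window RFD increments Δrfd: UP (mean +μ), DOWN
(−μ) and FLAT (0) with shared σ and a sticky symmetric transition matrix
(`p_stay = 0.99` by default). Ascending runs of at least `min_zone_bins`
(default 3) become IZs, descending runs TZs.

Numerical choices: decoding is exact Viterbi in log space with ties broken
toward FLAT; μ and σ are initialized by method of moments from the tails
of the increment distribution (upper/lower deciles for μ, central 80% for
σ) and refined by at most 20 Baum–Welch iterations with transitions held
fixed; missing increments emit a neutral value (mean 0, σ inflated 10×)
so the chain stays connected across coverage gaps while leaning slightly
toward FLAT. Validation checks Viterbi against exhaustive enumeration of
all `3^n` paths on instances of up to 12 bins, and recovery of ten planted
zones (RFD rising −1→+1 over five 50-kb bins, increment noise σ = μ/4)
with centres within 100 kb.

## Fork-speed profiling

In an unsynchronized population every position replicates exactly once per
cell cycle, so if forks moved at uniform speed, fork density — and hence
TrAEL-seq read density — would be uniform. Deviations from uniformity
therefore measure residence time: expected read density is proportional to
1/v(x). The profiling stage quantifies this as the mean read count of
non-overlapping 50 kb windows as a function of distance from the nearest
IZ centre, in 100 kb distance bins truncated at 3 Mb (beyond which windows
are too rare for a useful interval; 2 Mb is conventional when restricting
to the earliest-firing zones via `feature_subset`).

* **Confidence intervals** are t-based on the per-bin window counts; the
  default level is 0.95 and is configurable.
* **Aberrant windows** (copy-number variants, peri-centromeres) are flagged
  by a robust rule — count outside median ± 5·MAD — plus an optional
  exclusion BED. Flagged windows stay in the table, marked. The rule is a
  guard against artefacts, so analyses of simulated genomes, which contain
  none, disable it (`mad_k = Inf`) rather than let a genuinely bimodal
  density landscape be mistaken for artefact.
* **Stratification** flags the top fraction of windows by an external score
  (e.g. a nascent-transcription proxy) using the type-7 quantile, ties at
  the threshold dropped, so profiles can be recomputed on transcriptionally
  quiet windows.
* **AUC comparisons** integrate the piecewise-constant profile over a
  distance range and compare replicate groups by two-sided t-test, paired
  by default (replicate time courses are matched); Welch unpaired is
  available. A flat profile of height 1 over 1 Mb has AUC 1e6.
* **Gene metaplots** average read density over genes ± 100 kb flanks, with
  the body rescaled to a fixed bin count and minus-strand genes reversed.
  Each stratum profile is normalized so the mean over the outer halves of
  both flanks is 1, making background levels comparable across strata;
  genes shorter than one base per body bin are skipped and tallied.

## The replication simulator

`fork_model()` defines ground truth: chromosome lengths, IZ intervals with
firing efficiency e ∈ (0,1] and truncated-normal firing times, a speed
profile v(x) (base speed × piecewise factor of distance from the nearest
IZ centre × optional per-region factor), and library parameters (cells,
reads per cell, duplicate rate, noT fraction). Per cell, each zone fires
with probability e at a uniform position within it; every position is
replicated by whichever fork arrives first, with travel time the integral
of 1/v along the path, evaluated on a 1 kb residence grid — passive
replication of unfired zones falls out of this sweep, and chromosomes where
nothing fired are resampled. Termination points sit where converging forks
meet; with synchronous origins that is the midpoint, and a firing delay Δt
displaces it by vΔt/2, which the tests verify against the closed form.

Reads are placed by **residence-time sampling** — positions drawn with
density ∝ 1/v, strand set by the replicating fork's direction (rightward
fork ⇒ reverse-strand read). This is mathematically equivalent to
snapshotting fork positions at random times for all read-density and
polarity expectations, and far cheaper. The emitted FASTQ reproduces the
full read layout (random UMIs, sample barcodes, poly-T lengths
1 + Geometric(0.5), a configurable noT fraction whose first insert base is
substituted with a non-T base while the truth coordinate is kept), and
`emit_alignments()` bypasses mapping with perfect alignments plus a
two-component MAPQ model so both deduplication paths are exercised.

What the simulator deliberately does **not** emulate: sequencing errors,
sequence-context break hotspots, fork stalling and reversal dynamics,
checkpoint signalling, and mechanistic competition for replication factors
— v(x) is imposed, not emergent. Passing tests therefore demonstrate that
the pipeline recovers the quantities the model encodes (polarity, zone
positions, 1/v density structure), not that real libraries are free of the
artefacts the simulator omits; the aberrant-window filter and the noT
channel exist for those.

## Validation problem sizes

The test suite and `scripts/acceptance.R` run entirely from simulation, at
sizes chosen to give each stochastic check a comfortable margin while
staying desk-scale:

* demultiplexing: a six-plex pool of ~60,000 reads (10,000 per index);
* deduplication: 1,000 reads against the brute-force oracle;
* RFD: a 10 Mb chromosome, five IZs of mixed efficiency, ~100,000 reads
  (≥ 200 per 20 kb), Pearson r against the truth track > 0.95;
* segmentation: ten planted IZs on a 12 Mb track at 50 kb bins;
* fork speed: four replicate 24 Mb genomes with v doubling beyond 1 Mb of
  an IZ centre (~70,000 reads each); the far/near density ratio recovers
  0.5 within the pooled confidence intervals, and a uniform-speed control
  stays flat;
* metaplots: twenty 100 kb genes, the top-scoring half with 1.2× planted
  residence time, recovered as a body/flank ratio of 1.2 ± 0.05.

## Known limitations

* The HMM segmenter is a functional stand-in for published RFD HMM tools;
  concordance with any specific external caller can only be assessed
  qualitatively, and replication-timing inference is out of scope (timing
  ranks for "earliest-firing" subsets are consumed as a user-supplied
  score).
* Deduplication of the low-MAPQ class is genome-wide and exact-key (no UMI
  error correction, no directional networks).
* Alignment is out of scope; alignments are consumed as coordinate-sorted
  SAM/BAM with the UMI in the read name or a tag.
* `segment_rfd()` requires non-overlapping windows; compute a dedicated
  non-overlapping track for segmentation rather than thinning a sliding
  one.
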