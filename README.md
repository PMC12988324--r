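# traelr

Processing and analysis of multiplexed **TrAEL-seq** data in R.

TrAEL-seq (Transferase-Activated End Ligation sequencing) captures free
single-stranded 3′ DNA ends genome-wide. Because the exposed 3′ end of the
replication-fork leading strand is by far the most abundant such end in
proliferating cells, TrAEL-seq read polarity reports **replication fork
directionality (RFD)** and read density reports **fork residence time** —
all from unsynchronized, unlabelled cells. `traelr` is aimed at genomics
groups who run (or simulate) TrAEL-seq libraries and want to go from raw
multiplexed FASTQ to RFD tracks, initiation-zone calls and fork-speed
profiles.

## What it computes

* **Demultiplexing and read-structure parsing** — each raw read is
  `8-nt UMI | 4-nt inline barcode | poly-T run | genomic insert`. Reads are
  split per sample and into T (DNA-derived; at least one templated T) and
  noT (putatively RNA-derived) classes, with the UMI carried in the read
  name (`parse_read()`, `demultiplex_fastq()`).
* **Copy-number-aware UMI deduplication** — uniquely mapped reads
  (MAPQ > 20) deduplicate by *(position, strand, UMI)*; multi-mapping reads
  (MAPQ ≤ 20) by *(UMI, first 10 bases of the read sequence)*, because the
  8-nt UMI keyspace (4⁸ = 65,536) is smaller than library complexity
  (`deduplicate_reads()`).
* **Single-base break mapping** — every alignment is reduced to the base
  immediately 5′ of the captured strand break (`reduce_to_break()`).
* **RFD tracks** — per-window `RFD = (R − F) / (R + F)` over reverse (R)
  and forward (F) strand counts, +1 meaning all forks move left→right;
  default 20 kb windows every 2 kb (`count_breaks()`, `compute_rfd()`),
  with whole-set total-count normalization across multiplexed sets
  (`normalize_sets()`) and bedGraph output (`write_tracks()`).
* **Initiation/termination-zone segmentation** — a three-state Gaussian HMM
  on RFD increments (UP / DOWN / FLAT) decoded by Viterbi; ascending runs
  become IZs, descending runs TZs (`segment_rfd()`). External IZ BED files
  can be used instead.
* **Fork-speed profiling** — mean read count in 50 kb windows as a function
  of distance from the nearest IZ centre, with t-based confidence
  intervals, truncation at 3 Mb, aberrant-window filtering, score-based
  stratification, AUC t-tests and strand-aware gene metaplots
  (`build_window_table()`, `distance_profile()`, `stratify_windows()`,
  `auc_compare()`, `gene_metaplot()`).
* **A replication-fork simulator** — per-cell origin firing inside defined
  IZs, position-dependent fork speed v(x), residence-time read sampling
  (density ∝ 1/v), PCR duplicates, the full read layout and truth tables,
  so every stage above is testable end-to-end (`fork_model()`,
  `simulate_replication()`, `emit_fastq()`, `emit_alignments()`).

## Worked example

Simulate a lone efficient initiation zone, run the pipeline, and read the
RFD off both sides of the origin:

```r
library(traelr)

model <- fork_model(
  genome = c(chr1 = 2e6),
  izs = data.frame(chrom = "chr1", start = 9e5, end = 1.1e6,
                   efficiency = 1, t_mean = 1, t_sd = 0.1),
  n_cells = 10, reads_per_cell = 3000
)
sim <- simulate_replication(model, samples = "s1", seed = 4)
breaks <- sim_break_records(sim)
rfd <- compute_rfd(count_breaks(breaks, binning_scheme(20000, 20000),
                                model$genome))
rfd$rfd[rfd$start == 1200000]   # right of the origin
#> [1] 1
rfd$rfd[rfd$start == 700000]    # left of the origin
#> [1] -1
```

All forks right of the origin move left→right, so every captured
leading-strand end there is a reverse-strand read and RFD saturates at +1;
the mirror holds on the left. Segmenting the same track calls one IZ over
the planted zone:

```r
zones <- segment_rfd(rfd)
zones[zones$type == "IZ", c("start", "end", "centre")]
#>    start     end  centre
#> 1 960000 1060000 1010000
```

A shell interface covering the same steps ships in `inst/cli/trael`
(`trael demux`, `trael dedup`, `trael rfd`, `trael segment`,
`trael profile`, `trael simulate`).

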