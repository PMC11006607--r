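# locusforge

Design and interrogation of evolutionarily naive DNA loci.

## The problem

What does a genome do with DNA it has never seen? A locus written
*backwards* — the base string read right-to-left, **without**
complementing — keeps the composition of its natural template (length,
GC content, homopolymer runs, repeat density) while destroying every
evolved coding and regulatory element. Integrated into a host genome,
such a sequence reports the host's *default genomic state*: in a
permissive host it acquires accessible chromatin, transcription start
sites and transcripts everywhere; in a restrictive host it stays silent
and may acquire repressive chromatin driven purely by composition, most
notably by CpG dinucleotides.

locusforge implements the computational side of such an experiment, for
people who design large synthetic loci and quantify their activity from
sequencing data:

* **Design transforms.** `reverse_sequence()` (reversal without
  complementation); `scrub_cpg()` — iterative stochastic CpG
  elimination: scan for `CG`, delete the C or the G with a fair coin,
  and reiterate, because a deletion can create a new `CG` at the
  junction, until none remain; `plan_segments()` /
  `minimal_segment_count()` — tile a locus into ≤ `target_len` synthesis
  segments with ≥ `overlap` bp shared between neighbours, using the
  minimal count `n` with `n·target − (n−1)·overlap ≥ L`;
  `design_insertion()` — payload flanked by 40-bp homology arms.
* **Composition statistics.** `dinuc_profile()` (mono- and overlapping
  dinucleotide counts), `cpg_stats()` with the classic expectation
  `E[CpG] = n_C·n_G / L` and observed/expected ratio,
  `predict_reversed_profile()` (reversal maps each dinucleotide XY to
  YX, so the reversed-locus composition is computable without touching
  the sequence), `find_cpg_islands()` (windowed GC / O-E thresholding),
  `gc_track()`, `iupac_scan()`.
* **Activity quantification.** Sliding windows (`make_windows()`),
  depth (`mean_depth()`), copy number from sequencing depth ratios
  (`estimate_copy_number()`), RPGC 1× normalization, copy-corrected
  relative coverage, peak density per 100 kb, geneless background
  windows, SAM-flag-filtered read counting (`-F 2308` semantics), and
  binned log1p Pearson replicate correlation.
* **TSS machinery.** `tss_from_cage()` (TSS = 5′ boundary of a stranded
  CAGE peak), `promoter_intervals()` (200 bp up / 100 bp down),
  strand-aware TSS metaplots with standard errors (`metaplot()`).
* **Simulation.** Seeded generators (`simulation_spec()`,
  `make_genome()`, `make_locus_trio()`, `simulate_signal()`,
  `make_default_state_fixture()`) that produce a host genome, a locus
  trio (forward / reversed / CpG-scrubbed), planted TSSs with
  sequencing-like signal, CAGE peaks and read intervals — with full
  truth tables, so the whole pipeline is testable without any download.
* **Pipeline.** `run_pipeline()` chains all stages over a fixture
  directory and writes a TSV report plus a JSON manifest.

Coordinates are `GRanges` (1-based, closed) inside the package; BED and
bedGraph files keep their native 0-based half-open convention on disk.

## Worked example

Design a locus trio and read off its composition:

```r
library(locusforge)

spec <- simulation_spec(seed = 7, locus_length = 20000L)
trio <- make_locus_trio(spec)          # forward, reversed, CpG-scrubbed

cpg_stats(dinuc_profile(trio$sequences[1]))
#> CpG observed 856, expected 847, O/E 1.01
cpg_stats(dinuc_profile(trio$sequences[3]))
#> CpG observed 0, expected 682, O/E 0.00

plan_segments(trio$sequences[2], target_len = 4000, overlap = 300)
#> Segment plan for 'locus_R' (20000 bp)
#>   6 segments, length <= 4000 bp, overlap >= 300 bp
```

An i.i.d. random locus is composition-random, so its O/E CpG ratio sits
near 1 in both orientations. A natural mammalian template behaves very
differently: mammalian DNA is CpG-depleted, and reversal converts every
GpC into a CpG. Feeding the published composition of a 100,667-bp human
locus through the same statistics:

```r
fwd <- new_cpg_stats(observed = 1202, expected = 4291)   # natural template
rev <- new_cpg_stats(observed = 4499, expected = 4291)   # reversed locus
round(fwd$ratio, 2)                  #> 0.28
round(rev$ratio, 2)                  #> 1.05
oe_fold_enrichment(rev, fwd)         #> 3.75
minimal_segment_count(100667, 4000, 300)  #> 28
```

The reversed locus is 3.75-fold CpG-enriched over its template — the
composition signal that drives Polycomb-style silencing in restrictive
hosts — and needs 28 synthesis segments of ≤ 4 kb with 300-bp overlaps.

End-to-end, on a generated two-host fixture:

```r
fx_dir <- file.path(tempdir(), "fixture")
make_default_state_fixture(seed = 1, dir = fx_dir)
report <- run_pipeline(fx_dir, file.path(tempdir(), "out"))
subset(report, stage == "peak_density")
#>         stage           metric     value
#>  peak_density  locus_per_100kb 24.000000
#>  peak_density genome_per_100kb  8.097561
#>  peak_density            ratio  2.963855
```

Host A carries 12 planted TSSs on the 50-kb locus (24 per 100 kb)
against a host genome planted at 8 per 100 kb; the pipeline recovers
the 3× contrast. The same report shows the planted 2-copy integration
(`copy_number: estimate 2.000`) and, for the silent host B, a locus
read count (1) far below the geneless-window median (19).

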