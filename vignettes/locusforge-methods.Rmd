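---
title: "Methods: designing and quantifying evolutionarily naive loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: designing and quantifying evolutionarily naive loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locusforge)
```

## Scope and model

locusforge supports experiments that probe a host genome's *default
state* with DNA that carries no evolved information. The design side
produces such DNA from a natural template; the analysis side quantifies
what the host does with it. This vignette documents the procedures, the
parameters that matter, the numerical choices, and the places where a
design decision was genuinely open.

## Design transforms

**Reversal without complementation.** `reverse_sequence()` writes the
template right-to-left. Unlike the reverse complement, this is not a
biologically equivalent molecule: it destroys codons, splice signals
and factor binding sites while preserving length, every mononucleotide
count, GC content, homopolymer runs and repeat positions. At the
composition level the transform is fully predictable: every
dinucleotide XY becomes YX. `predict_reversed_profile()` encodes this
identity, and the suite checks it against direct counting on random
sequences — it is the package's central consistency check between the
design and statistics modules. One important consequence: in
CpG-depleted DNA (mammalian O/E near 0.2–0.3), reversal converts the
abundant GpC dinucleotides into CpGs, so the reversed locus becomes
strongly CpG-enriched even though nothing was "added".

**CpG scrubbing.** `scrub_cpg()` removes every CpG by stochastic
deletion: scan for `CG`, delete the C or the G with an independent fair
coin, and — because a deletion can juxtapose a new C and G — reiterate
until no `CG` remains. The procedure terminates: every scan that finds
an occurrence shortens the sequence by at least one base. Within one
scan, occurrences (necessarily ≥ 2 bp apart) are processed
right-to-left with one coin per occurrence. Whether a scan should
handle occurrences simultaneously or one at a time is not dictated by
the problem; the two conventions have different reachable-output sets.
We chose the simultaneous right-to-left pass because it keeps indices
stable and is easy to audit; it is documented here as our convention,
not inferred as anyone else's. The result records every deletion
(iteration, position in the then-current sequence, base), and
`replay_scrub()` reconstructs the output from the audit;
`scrub_position_map()` lifts coordinates across the scrub. The realized
output is one sample from the reachable set — two runs with different
seeds legitimately differ — so only the zero-CpG postcondition, the
length bookkeeping and seeded determinism are contractual. The test
suite enumerates *all* coin-flip paths for short adversarial inputs and
verifies that seeded runs realize exactly the enumerated set. An
iteration cap (default 100) guards against implementation error; the
worst observed depth on random kilobase sequences is far below it
(long C-runs ending in G are the slow case, scrubbing one C per
iteration when the coin repeatedly hits C).

**Synthesis segmentation.** Commercial synthesis needs a long locus cut
into segments with overlapping junctions for assembly. The contractual
quantity is the segment count: the smallest `n` with
`n·target − (n−1)·overlap ≥ L` (`minimal_segment_count()`). How the
length is distributed across segments within that count is not
determined by any obvious rule (real designs often carry one short
remainder segment). `plan_segments()` balances all segments to
`ceil((L + (n−1)·overlap)/n)` — never exceeding the target, provably
satisfying the overlap bound — because equal segments are
synthesis-friendly and make the plan a pure function of `(L, target,
overlap)`. Reconstruction by overlap-deduplicated concatenation is an
invariant of the suite.

**Insertion design.** `design_insertion()` flanks a payload with exact
homology arms copied from the target locus (default 40 bp, the standard
arm length for PCR-mediated yeast integration). Placing the payload at
the 5′ boundary of an experimentally called TSS is how candidate
promoters are functionally tagged.

## Composition statistics

`dinuc_profile()` counts overlapping dinucleotides; pairs containing N
are skipped and N is excluded from the GC denominator (design
transforms reject N outright — synthesized DNA cannot contain it). The
CpG expectation is the classic composition expectation
`n_C·n_G/L`, with O/E ratio 0 when the expectation is 0. Ratios are
stored at full precision and displayed at two decimals (round-half-even).
`oe_fold_enrichment()` divides O/E ratios after rounding each to two
decimals by default, matching the convention of quoting O/E values at
two decimals; `ratio_digits = NULL` gives the full-precision quotient.
The two conventions differ in the third significant digit (e.g. 3.75
vs 3.74 for a typical reversed-vs-forward mammalian comparison).

`find_cpg_islands()` reimplements the classic sliding-window island
caller: 100-bp windows at 1-bp shift, window-level thresholds GC ≥ 0.5
and O/E ≥ 0.6, maximal runs of qualifying windows merged, islands
shorter than 200 bp discarded. The per-window expectation uses the same
`n_C·n_G/window` formula as the global statistic, for internal
consistency. Reported island means are means over the qualifying
windows of the run, which guarantees they satisfy the thresholds. A
scrubbed sequence can never satisfy O/E ≥ 0.6 (observed is 0
everywhere), so island calls on scrubbed output are empty by
construction unless the O/E floor is explicitly set to 0.

## Quantification

**Windows.** `make_windows()` reproduces the standard 100-kb/10-kb
sliding grid. Truncated terminal windows are dropped by default so all
windows share one denominator; the locus denominator is always the
supplied interval's own length, never a constant.

**Copy number.** Mean sequencing depth over the locus divided by the
genome-wide mean, excluding the mitochondrial contig (its copy number
does not track the nuclear genome) and excluding the locus's own contig
when the locus spans it entirely (an episome on its own reference
contig must not contribute to its own background). Both the real-valued
estimate and a nearest-integer call are reported; what estimate
qualifies a clone is left to the user, since any threshold encodes a
QC policy rather than a statistic.

**Relative coverage.** `(locus_mean / copy_number) / genome_mean`,
where the genome mean is the mean of per-window means. The statistic is
invariant to global rescaling of the track, so it can be computed
before or after RPGC normalization (`rpgc_normalize()`, which scales a
track so mean coverage over an effective genome size is 1×; 12 Mb is
the conventional effective size for budding yeast).

**Peak density.** Peaks are assigned to windows by midpoint, because
overlapping sliding windows would otherwise count one peak up to
`size/step` times; any-overlap assignment is available for single
regions. Densities are scaled to peaks per 100 kb.

**Geneless background.** Windows overlapping any annotated transcript
or excluded feature (blacklist, centromere, telomere) by ≥ 1 bp are
removed; read counts over the survivors give the transcription-free
background against which a silent locus is judged. Read counting
follows the `-F 2308` flag convention: unmapped, secondary and
supplementary alignments are excluded, and — deliberately, because the
mask says so — duplicates are *not*. The window median uses the lower
median for even counts, making reports deterministic.

**Replicate correlation.** Per-bin means, drop bins zero in both
tracks, drop bins deviating from their track median by more than
k·MAD, `log(1+x)`, Pearson. The MAD multiplier of the upstream
convention is not documented anywhere we could find; we use k = 10,
exposed as a parameter, which removes only gross artefacts while
leaving the dynamic range intact.

## TSSs, promoters, metaplots

A TSS is the 5′ boundary of a stranded CAGE peak: the start on `+`, the
end on `−`; unstranded peaks are rejected rather than guessed.
Promoters span 200 bp upstream and 100 bp downstream, with the TSS base
counted as the first downstream base; on the minus strand the interval
is mirrored so promoters have exactly 300 bp on either strand. The
minus-strand off-by-one convention is not uniquely determined by the
definition; ours is chosen for strand symmetry and documented here.

`metaplot()` extracts ±`flank` bp around each TSS (offset 0 = the TSS
base), flips minus-strand windows so upstream is always left, averages
within 10-bp bins (the bin size typical of smoothed coverage tracks),
and aggregates mean ± s.e. (sd/√n) across TSSs. TSSs whose window
crosses a contig edge are dropped and counted rather than zero-padded:
padding would bias the mean toward zero exactly where data end. An
optional centred 100-bp moving average reproduces track-level
smoothing; it is off by default so the statistic is the data's own.

## Simulation: what it emulates and what it does not

The generators produce the full input set of a two-host experiment at
desk scale: a host genome of two 500-kb contigs (genes in a dense block
over 40% of each contig, a centromere, telomeres — so that 100-kb
geneless windows exist), a 50-kb locus at GC 0.41 (the GC content of
the natural mammalian template in this experimental design), and
sequencing-like signal: per-base Poisson background (shot noise),
Gaussian accessibility bumps of width 150 bp at planted TSSs, CAGE
peaks whose 5′ boundaries are exactly the planted TSSs, and 75-bp
background reads at ~20 per 100-kb window — the regime reported for
geneless mammalian windows — with 2% secondary and 5% duplicate flags.
The two-host fixture plants 24 TSSs per 100 kb on the locus in host A
against 8 per 100 kb in its genome (a 3× contrast, the magnitude
reported for a permissive host), and no locus TSSs in host B with a
locus read rate of 2 × 10⁻⁵/bp, placing the locus count below the
geneless median by construction. A depth track carries the locus at two
copies for the copy-number stage. All scales were chosen once as
desk-realistic and are stated here; every generator is a pure function
of `(seed, spec)`.

The base model is i.i.d.: no repeat structure, no codon structure, no
autocorrelated coverage, no mappability or GC bias. Passing tests
therefore certify the *statistics* — window arithmetic, flag masks,
strand flips, normalizations, estimator calibration under shot noise —
not robustness to the correlated noise of real libraries. One visible
consequence: an i.i.d. locus has O/E CpG ≈ 1 in both orientations, so
the dramatic 0.28 → 1.05 ratio shift of a reversed mammalian template
appears only when real composition tables are supplied (the package
accepts published counts through `new_dinuc_profile()` /
`new_cpg_stats()` for exactly that purpose).

## Numerical and interface choices

* Internal coordinates are `GRanges` (1-based, closed), the native
  convention of the R genomics stack; BED/bedGraph I/O converts at the
  boundary, and `parse_region_1based()` is the single entry point for
  browser-style 1-based inclusive region strings.
* Strict validating readers: BED rejects `start ≥ end` and negative
  coordinates with line numbers; bedGraph rejects overlapping
  intervals, out-of-bounds spans, and negative or non-finite values;
  FASTA rejects non-ACGTN characters naming the offender. Unstranded
  (`.`) BED features become `*`; functions where orientation matters
  either reject them (CAGE) or treat them as `+`.
* Problem sizes in the test suite (1-kb scrub draws, 100-replicate
  estimator calibrations, megabase correlation tracks, the 1-Mb + 50-kb
  fixture) were chosen so the whole suite certifies each property at
  meaningful statistical resolution while remaining a desk-scale run.

## Known limitations

* `scrub_cpg` materializes the sequence as a character vector; loci far
  beyond a few hundred kilobases would deserve a compiled
  implementation.
* CpG-island calling follows the windowed-threshold definition; other
  island definitions (hidden-Markov or clustering-based) are out of
  scope.
* No BAM/bigWig readers: alignments and signal enter as BED-like text
  and bedGraph. Converting from binary formats is one `samtools` /
  `bigWigToBedGraph` call away and deliberately outside the package.
* Peak calling, motif discovery and TFBS database scans are consumed,
  never produced, here.
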