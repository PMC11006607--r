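# Seeded generators that emulate the inputs of a default-genomic-state
# experiment: a host genome with annotation, a locus trio (forward,
# reversed, CpG-scrubbed), sequencing-like signal with planted TSSs, CAGE
# peaks, and read intervals. Every generator is a pure function of its
# seed and spec, so reruns are byte-identical and truth tables make each
# downstream statistic checkable.

#' Specification for a simulated experiment
#'
#' Collects every knob of the simulators in one validated object. The
#' defaults describe a desk-scale caricature of the real experimental
#' design: a small host genome, a ~50-kb naive locus at GC 0.41 present at
#' `copy_number` copies, shot-noise (Poisson) sequencing signal with
#' Gaussian accessibility bumps at planted TSSs, and sparse background
#' reads (~20 per 100-kb window).
#'
#' @param seed Integer seed; the single source of randomness.
#' @param genome data.frame with columns `contig`, `length`, `gc`.
#' @param locus_length Locus length in bp.
#' @param locus_gc Locus GC fraction.
#' @param locus_contig Name of the contig carrying the integrated locus.
#' @param background_rate Background signal rate (expected signal per bp).
#' @param peak_kind `"gaussian"`, `"delta"` or `"flattop"` bump shape.
#' @param peak_width Bump width parameter in bp (sd for gaussian, span for
#'   flattop; ignored for delta).
#' @param peak_height Bump height (signal units) scaling each TSS's
#'   strength.
#' @param copy_number Locus copy number (scales locus signal and reads).
#' @param read_rate Background read density (reads per bp) on host
#'   contigs.
#' @param locus_read_rate Read density on the locus contig.
#' @param read_length Simulated read length in bp.
#' @param cage_peak_width CAGE peak width in bp.
#' @param flag_secondary_rate,flag_dup_rate Fractions of reads flagged as
#'   secondary (256) or duplicate (1024).
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(seed,
                            genome = data.frame(
                              contig = c("chrI", "chrII"),
                              length = c(500000L, 500000L),
                              gc = c(0.40, 0.40)
                            ),
                            locus_length = 50000L,
                            locus_gc = 0.41,
                            locus_contig = "synlocus",
                            background_rate = 0.2,
                            peak_kind = c("gaussian", "delta", "flattop"),
                            peak_width = 150,
                            peak_height = 20,
                            copy_number = 1L,
                            read_rate = 2e-4,
                            locus_read_rate = read_rate,
                            read_length = 75L,
                            cage_peak_width = 50L,
                            flag_secondary_rate = 0.02,
                            flag_dup_rate = 0.05) {
  peak_kind <- match.arg(peak_kind)
  stopifnot(
    is.data.frame(genome),
    all(c("contig", "length", "gc") %in% names(genome)),
    all(genome$length > 0), all(genome$gc >= 0 & genome$gc <= 1),
    locus_length > 0, locus_gc >= 0, locus_gc <= 1,
    background_rate >= 0, peak_width > 0, peak_height >= 0,
    copy_number >= 0, read_rate >= 0, locus_read_rate >= 0,
    read_length >= 1, cage_peak_width >= 1,
    flag_secondary_rate >= 0, flag_dup_rate >= 0,
    flag_secondary_rate + flag_dup_rate <= 1
  )
  structure(
    list(seed = as.integer(seed), genome = genome,
         locus_length = as.integer(locus_length), locus_gc = locus_gc,
         locus_contig = locus_contig, background_rate = background_rate,
         peak_kind = peak_kind, peak_width = peak_width,
         peak_height = peak_height, copy_number = as.integer(copy_number),
         read_rate = read_rate, locus_read_rate = locus_read_rate,
         read_length = as.integer(read_length),
         cage_peak_width = as.integer(cage_peak_width),
         flag_secondary_rate = flag_secondary_rate,
         flag_dup_rate = flag_dup_rate),
    class = "simulation_spec"
  )
}

# i.i.d. bases at a requested GC; no repeat structure (the statistics
# under test are composition- and coverage-level).
random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Simulate a host genome with annotation
#'
#' Draws i.i.d. bases at each contig's requested GC and lays down a
#' deterministic annotation: a gene-dense region (2-kb genes every 10 kb)
#' over the first 40% of each contig, a 5-kb centromere just past it, and
#' 2-kb telomeres at both ends. The remaining ~half of each contig is
#' feature-free, so 100-kb geneless windows exist.
#'
#' @param spec A [simulation_spec()].
#' @param dir Optional directory; when given, writes `genome.fa`,
#'   `genes.bed` and `excluded.bed` there.
#' @return List with `sequences` ([Biostrings::DNAStringSet]),
#'   `contig_lengths`, `genes` and `excluded` ([GenomicRanges::GRanges]).
#' @export
make_genome <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  g <- spec$genome
  seqs <- with_seed(spec$seed, {
    vapply(seq_len(nrow(g)), function(i) random_dna(g$length[i], g$gc[i]),
           character(1))
  })
  sequences <- DNAStringSet(seqs)
  names(sequences) <- g$contig
  contig_lengths <- setNames(as.integer(g$length), g$contig)
  genes <- excluded <- list()
  for (i in seq_len(nrow(g))) {
    len <- g$length[i]
    ct <- g$contig[i]
    gene_region_end <- as.integer(0.4 * len)
    gene_starts <- if (gene_region_end >= 7000L) {
      seq.int(5001L, gene_region_end - 1999L, by = 10000L)
    } else {
      integer(0)  # contig too short to carry the gene block
    }
    if (length(gene_starts)) {
      genes[[ct]] <- GRanges(ct, IRanges(gene_starts, width = 2000L),
                             strand = rep_len(c("+", "-"), length(gene_starts)))
    }
    cen <- as.integer(0.45 * len)
    excluded[[ct]] <- GRanges(ct, IRanges(
      start = c(1L, cen, len - 1999L),
      end = c(2000L, cen + 4999L, len)
    ))
  }
  genes <- if (length(genes)) {
    suppressWarnings(do.call(c, unname(genes)))
  } else {
    GRanges()
  }
  if (length(genes)) names(genes) <- paste0("gene", seq_along(genes))
  excluded <- suppressWarnings(do.call(c, unname(excluded)))
  out <- list(sequences = sequences, contig_lengths = contig_lengths,
              genes = genes, excluded = excluded)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(sequences, file.path(dir, "genome.fa"))
    write_bed(genes, file.path(dir, "genes.bed"))
    write_bed(excluded, file.path(dir, "excluded.bed"))
  }
  out
}

#' Simulate a locus trio: forward, reversed, CpG-scrubbed
#'
#' Draws a forward locus at the spec's length and GC, reverses it with
#' [reverse_sequence()], and scrubs the reversed sequence with
#' [scrub_cpg()]. Optionally lifts planted TSS positions (given in the
#' integrated, i.e. reversed, frame) into all three coordinate frames.
#'
#' @param spec A [simulation_spec()].
#' @param tss_positions Optional integer positions on the reversed locus.
#' @param dir Optional directory; writes `trio.fa` and `tss_frames.tsv`.
#' @return List with `sequences` (3-record [Biostrings::DNAStringSet]:
#'   forward, reversed, scrubbed), `scrub` (the [scrub_cpg()] result) and
#'   `tss_frames` (data.frame mapping each planted position to the
#'   forward, reversed and scrubbed frames; `NA` where the base was
#'   deleted).
#' @export
make_locus_trio <- function(spec, tss_positions = integer(0), dir = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  fwd_seq <- with_seed(spec$seed + 1L, random_dna(spec$locus_length, spec$locus_gc))
  fwd <- DNAStringSet(fwd_seq)
  names(fwd) <- "locus"
  rev <- reverse_sequence(fwd)
  scrub <- scrub_cpg(rev, seed = spec$seed + 2L)
  L <- spec$locus_length
  tss_frames <- NULL
  if (length(tss_positions)) {
    stopifnot(all(tss_positions >= 1L & tss_positions <= L))
    map <- scrub_position_map(L, scrub$deletions)
    tss_frames <- data.frame(
      name = paste0("tss", seq_along(tss_positions)),
      reversed = as.integer(tss_positions),
      forward = L + 1L - as.integer(tss_positions),
      scrubbed = map[as.integer(tss_positions)]
    )
  }
  sequences <- c(fwd, rev, scrub$scrubbed)
  out <- list(sequences = sequences, scrub = scrub, tss_frames = tss_frames)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(sequences, file.path(dir, "trio.fa"))
    if (!is.null(tss_frames)) {
      write.table(tss_frames, file.path(dir, "tss_frames.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }
  out
}

#' Simulate sequencing-like signal, CAGE peaks and reads
#'
#' Per contig, draws Poisson background signal at `background_rate`
#' (split evenly between strands) and adds a deterministic bump of the
#' spec's shape at every planted TSS on the TSS's strand, scaled by the
#' TSS `score` (strength) -- everything on the locus contig additionally
#' scaled by `copy_number`. Emits CAGE peaks whose 5' boundaries are
#' exactly the planted TSSs, and background read intervals at the spec's
#' per-bp read rates with SAM-style flags drawn from the spec's mixture.
#'
#' @param spec A [simulation_spec()].
#' @param contig_lengths Named contig lengths (host contigs plus the
#'   locus contig).
#' @param tss Width-1 stranded [GenomicRanges::GRanges] of planted TSSs
#'   with a numeric `score` strength column (may be empty).
#' @param seed Seed for this draw (defaults to the spec seed).
#' @return List with `tracks` (list of `fwd`/`rev` per-base
#'   [IRanges::RleList]), `cage_peaks` ([GenomicRanges::GRanges]),
#'   `reads` ([GenomicRanges::GRanges] with `flag`), and `truth` (planted
#'   TSSs and per-contig expected read counts per 100 kb).
#' @export
simulate_signal <- function(spec, contig_lengths, tss = GRanges(),
                            seed = spec$seed) {
  stopifnot(inherits(spec, "simulation_spec"),
            is.numeric(contig_lengths), !is.null(names(contig_lengths)),
            is(tss, "GRanges"))
  if (length(tss) && is.null(mcols(tss)$score)) {
    mcols(tss)$score <- 1
  }
  with_seed(seed, {
    fwd <- rev <- list()
    for (ct in names(contig_lengths)) {
      len <- as.integer(contig_lengths[[ct]])
      copies <- if (ct == spec$locus_contig) spec$copy_number else 1L
      lam <- spec$background_rate * copies / 2
      f <- if (lam > 0) rpois(len, lam) else numeric(len)
      r <- if (lam > 0) rpois(len, lam) else numeric(len)
      here <- tss[seqnames(tss) == ct]
      for (i in seq_along(here)) {
        p <- start(here)[i]
        h <- spec$peak_height * mcols(here)$score[i] * copies
        bump <- switch(spec$peak_kind,
          delta = {
            pos <- p
            val <- h
            list(pos = pos, val = val)
          },
          gaussian = {
            w <- spec$peak_width
            off <- seq.int(-3L * as.integer(w), 3L * as.integer(w))
            list(pos = p + off, val = h * exp(-off^2 / (2 * w^2)))
          },
          flattop = {
            half <- as.integer(spec$peak_width %/% 2)
            list(pos = seq.int(p - half, p + half), val = rep(h, 2L * half + 1L))
          }
        )
        ok <- bump$pos >= 1L & bump$pos <= len
        if (as.character(strand(here))[i] == "-") {
          r[bump$pos[ok]] <- r[bump$pos[ok]] + bump$val[ok]
        } else {
          f[bump$pos[ok]] <- f[bump$pos[ok]] + bump$val[ok]
        }
      }
      fwd[[ct]] <- Rle(f)
      rev[[ct]] <- Rle(r)
    }
    tracks <- list(fwd = RleList(fwd, compress = FALSE),
                   rev = RleList(rev, compress = FALSE))

    cage_peaks <- GRanges()
    if (length(tss)) {
      st <- as.character(strand(tss))
      pos <- start(tss)
      cw <- spec$cage_peak_width
      lens <- contig_lengths[as.character(seqnames(tss))]
      s <- ifelse(st == "+", pos, pmax(1L, pos - cw + 1L))
      e <- ifelse(st == "+", pmin(as.integer(lens), pos + cw - 1L), pos)
      cage_peaks <- GRanges(seqnames(tss), IRanges(s, e), strand = st)
      mcols(cage_peaks)$score <- mcols(tss)$score
    }

    reads <- list()
    lambda <- numeric(0)
    for (ct in names(contig_lengths)) {
      len <- as.integer(contig_lengths[[ct]])
      copies <- if (ct == spec$locus_contig) spec$copy_number else 1L
      rate <- if (ct == spec$locus_contig) spec$locus_read_rate else spec$read_rate
      lam <- rate * copies * len
      lambda[ct] <- rate * copies * 1e5
      n <- rpois(1L, lam)
      if (n > 0) {
        starts <- sample.int(max(1L, len - spec$read_length + 1L), n, replace = TRUE)
        u <- runif(n)
        flag <- integer(n)
        flag[u < spec$flag_secondary_rate] <- 256L
        flag[u >= spec$flag_secondary_rate &
               u < spec$flag_secondary_rate + spec$flag_dup_rate] <- 1024L
        gr <- GRanges(ct, IRanges(starts, width = spec$read_length))
        mcols(gr)$flag <- flag
        reads[[ct]] <- gr
      }
    }
    reads <- if (length(reads)) suppressWarnings(do.call(c, unname(reads))) else {
      g <- GRanges()
      mcols(g)$flag <- integer(0)
      g
    }

    list(tracks = tracks, cage_peaks = cage_peaks, reads = reads,
         truth = list(tss = tss, reads_per_100kb = lambda))
  })
}

#' Generate the two-host default-state fixture
#'
#' Builds the complete desk-scale experiment contrasting a host whose
#' default state is open and active ("host A": 12 TSSs planted across the
#' 50-kb locus, three times the host genome's CAGE density) with a host
#' whose default state is inactive ("host B": no locus TSSs, and a locus
#' read rate placing the locus count below the geneless-window median).
#' A whole-genome-sequencing-like depth track carries the locus at 2
#' copies for copy-number estimation.
#'
#' @param seed Integer seed; fully determines the fixture.
#' @param dir Optional directory. When given, all inputs are written as
#'   plain-text files (`trio.fa`, `genome.fa`, `genes.bed`,
#'   `excluded.bed`, `contigs.tsv`, `hostA_atac.bedGraph`,
#'   `hostA_cage_peaks.bed`, `hostA_reads.tsv`, `wgs.bedGraph`,
#'   `hostB_reads.tsv`, `truth.json`).
#' @return List with `spec`, `genome`, `trio`, `contig_lengths` (host
#'   contigs plus `synlocus`), `locus` (the locus interval), `hostA`,
#'   `hostB`, `wgs` (depth RleList) and `truth` (planted densities, copy
#'   number, read rates).
#' @export
make_default_state_fixture <- function(seed, dir = NULL) {
  spec <- simulation_spec(seed = seed)
  genome <- make_genome(spec, dir = dir)
  L <- spec$locus_length
  contig_lengths <- c(genome$contig_lengths,
                      setNames(L, spec$locus_contig))
  locus <- GRanges(spec$locus_contig, IRanges(1L, L))

  # planted locus TSSs: 12 across 50 kb (24 per 100 kb), jittered grid;
  # host genome TSSs: 8 per 100 kb, uniform -- planted density ratio 3.
  n_locus_tss <- 12L
  genome_tss_per_100kb <- 8
  planted <- with_seed(seed + 10L, {
    grid <- as.integer(seq(2500, L - 2500, length.out = n_locus_tss))
    lpos <- grid + sample.int(1001L, n_locus_tss, replace = TRUE) - 501L
    lstr <- sample(c("+", "-"), n_locus_tss, replace = TRUE)
    lstrength <- runif(n_locus_tss, 0.75, 1.5)
    gl <- genome$contig_lengths
    n_g <- round(genome_tss_per_100kb * sum(gl) / 1e5)
    gct <- sample(names(gl), n_g, replace = TRUE, prob = gl / sum(gl))
    gpos <- vapply(gct, function(ct) sample.int(gl[[ct]] - 2000L, 1L) + 1000L,
                   integer(1))
    gstr <- sample(c("+", "-"), n_g, replace = TRUE)
    gstrength <- runif(n_g, 0.75, 1.5)
    tss <- GRanges(
      c(rep(spec$locus_contig, n_locus_tss), gct),
      IRanges(c(lpos, gpos), width = 1L),
      strand = c(lstr, gstr)
    )
    mcols(tss)$score <- c(lstrength, gstrength)
    tss
  })

  trio <- make_locus_trio(spec,
                          tss_positions = start(planted)[
                            as.character(seqnames(planted)) == spec$locus_contig],
                          dir = dir)

  host_a <- simulate_signal(spec, contig_lengths, tss = planted,
                            seed = seed + 20L)

  spec_b <- spec
  spec_b$locus_read_rate <- 2e-5  # ~1 expected read on the 50-kb locus
  spec_b$background_rate <- 0.05
  host_b <- simulate_signal(spec_b, contig_lengths, tss = GRanges(),
                            seed = seed + 30L)

  spec_wgs <- spec
  spec_wgs$background_rate <- 60  # ~30x per strand-half, 60x combined
  spec_wgs$copy_number <- 2L
  wgs_sim <- simulate_signal(spec_wgs, contig_lengths, tss = GRanges(),
                             seed = seed + 40L)
  wgs <- RleList(lapply(names(contig_lengths), function(ct)
    wgs_sim$tracks$fwd[[ct]] + wgs_sim$tracks$rev[[ct]]), compress = FALSE)
  names(wgs) <- names(contig_lengths)

  truth <- list(
    locus_tss = sum(as.character(seqnames(planted)) == spec$locus_contig),
    locus_tss_per_100kb = n_locus_tss / L * 1e5,
    genome_tss_per_100kb = genome_tss_per_100kb,
    planted_density_ratio = (n_locus_tss / L * 1e5) / genome_tss_per_100kb,
    wgs_copy_number = 2L,
    hostB_locus_reads_expected = spec_b$locus_read_rate * L,
    hostB_genome_reads_per_100kb = spec_b$read_rate * 1e5
  )

  out <- list(spec = spec, genome = genome, trio = trio,
              contig_lengths = contig_lengths, locus = locus,
              hostA = host_a, hostB = host_b, wgs = wgs, truth = truth)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write.table(
      data.frame(contig = names(contig_lengths),
                 length = as.integer(contig_lengths)),
      file.path(dir, "contigs.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    atac <- RleList(lapply(names(contig_lengths), function(ct)
      host_a$tracks$fwd[[ct]] + host_a$tracks$rev[[ct]]), compress = FALSE)
    names(atac) <- names(contig_lengths)
    write_bedgraph(atac, file.path(dir, "hostA_atac.bedGraph"))
    write_bed(host_a$cage_peaks, file.path(dir, "hostA_cage_peaks.bed"))
    write_reads(host_a$reads, file.path(dir, "hostA_reads.tsv"))
    write_reads(host_b$reads, file.path(dir, "hostB_reads.tsv"))
    write_bedgraph(wgs, file.path(dir, "wgs.bedGraph"))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
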