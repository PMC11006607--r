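# End-to-end runner chaining the analysis stages over a fixture
# directory: composition -> CpG islands -> copy number -> relative
# coverage -> peak density -> geneless read counts -> TSSs -> promoters
# -> metaplot. Writes one TSV report and one JSON manifest.

input_error <- function(path) {
  stop(structure(
    class = c("locusforge_input_error", "error", "condition"),
    list(message = paste0("required input is missing: ", path),
         call = NULL)
  ))
}

require_file <- function(dir, name) {
  path <- file.path(dir, name)
  if (!file.exists(path)) input_error(path)
  path
}

#' Run the full analysis pipeline over a fixture directory
#'
#' Consumes the files written by [make_default_state_fixture()] (or any
#' directory with the same layout) and executes the analysis stages in
#' order, writing `report.tsv` (columns `stage`, `metric`, `value`) and a
#' machine-readable `manifest.json` (inputs, parameters, seed, package
#' version) into `out_dir`. All numbers in the report are computed from
#' the input files alone; rerunning on the same inputs reproduces the
#' report exactly.
#'
#' A missing input file raises a condition of class
#' `locusforge_input_error` naming the path.
#'
#' @param dir Fixture directory.
#' @param out_dir Output directory (created if needed).
#' @param window_size,window_step Sliding-window geometry for the
#'   genome-background statistics.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed is metadata for provenance).
#' @return The report as a data.frame, invisibly.
#' @export
run_pipeline <- function(dir, out_dir, window_size = 100000L,
                         window_step = 10000L, seed = 1L) {
  t_files <- list(
    trio = require_file(dir, "trio.fa"),
    genome = require_file(dir, "genome.fa"),
    genes = require_file(dir, "genes.bed"),
    excluded = require_file(dir, "excluded.bed"),
    contigs = require_file(dir, "contigs.tsv"),
    atac = require_file(dir, "hostA_atac.bedGraph"),
    cage = require_file(dir, "hostA_cage_peaks.bed"),
    wgs = require_file(dir, "wgs.bedGraph"),
    reads_b = require_file(dir, "hostB_reads.tsv")
  )
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  report <- list()
  add <- function(stage, metric, value) {
    report[[length(report) + 1L]] <<- data.frame(
      stage = stage, metric = metric, value = as.numeric(value))
  }

  contigs <- read.table(t_files$contigs, header = TRUE, sep = "\t")
  contig_lengths <- setNames(as.integer(contigs$length), contigs$contig)
  host_contigs <- setdiff(names(contig_lengths), "synlocus")
  locus <- GRanges("synlocus", IRanges(1L, contig_lengths[["synlocus"]]))

  # 1. sequence composition of the locus trio
  trio <- read_fasta(t_files$trio)
  for (i in seq_along(trio)) {
    p <- dinuc_profile(trio[i])
    cs <- cpg_stats(p)
    id <- names(trio)[i]
    add("seqstats", paste0(id, ".length"), p$length)
    add("seqstats", paste0(id, ".gc"), p$gc_fraction)
    add("seqstats", paste0(id, ".cpg_observed"), cs$observed)
    add("seqstats", paste0(id, ".cpg_expected"), cs$expected)
    add("seqstats", paste0(id, ".cpg_ratio"), cs$ratio)
    # 2. CpG islands
    isl <- find_cpg_islands(trio[i])
    add("cpg_islands", paste0(id, ".n_islands"), length(isl))
  }

  # 3. locus copy number from WGS-like depth
  wgs <- read_bedgraph(t_files$wgs, contig_lengths)
  cn <- estimate_copy_number(wgs, locus)
  add("copy_number", "estimate", cn$estimate)
  add("copy_number", "call", cn$call)

  # 4. copy-corrected relative coverage of the locus
  atac <- read_bedgraph(t_files$atac, contig_lengths)
  windows <- make_windows(contig_lengths[host_contigs],
                          size = window_size, step = window_step)
  rel <- relative_coverage(atac, locus, windows, copy_number = cn$call)
  add("relative_coverage", "locus_mean", rel$locus_mean)
  add("relative_coverage", "genome_mean", rel$genome_mean)
  add("relative_coverage", "relative", rel$relative)

  # 5. CAGE peak density, locus vs genome
  cage <- read_bed(t_files$cage)
  dens_locus <- peak_density(cage, region = locus)
  dens_genome <- peak_density(cage, windows = windows)
  add("peak_density", "locus_per_100kb", dens_locus)
  add("peak_density", "genome_per_100kb", dens_genome)
  add("peak_density", "ratio", dens_locus / dens_genome)

  # 6. geneless-window read counts (host B) vs the locus
  genes <- read_bed(t_files$genes)
  excluded <- read_bed(t_files$excluded)
  geneless <- geneless_windows(windows, c(granges_only(genes),
                                          granges_only(excluded)))
  reads_b <- read_reads(t_files$reads_b)
  counts <- count_reads_in_regions(reads_b, geneless)
  locus_count <- count_reads_in_regions(reads_b, locus)
  add("geneless", "n_windows", length(geneless))
  add("geneless", "median_reads", counts$median)
  add("geneless", "locus_reads", locus_count$counts)

  # 7-9. TSSs, promoters, metaplot at locus TSSs
  tss <- tss_from_cage(cage)
  locus_tss <- tss[as.character(seqnames(tss)) == "synlocus"]
  prom <- promoter_intervals(tss, contig_lengths = contig_lengths)
  atac_at_prom <- promoter_peak_overlap(cage, prom)
  add("tss", "n_total", length(tss))
  add("tss", "n_locus", length(locus_tss))
  add("promoters", "n", length(prom))
  add("promoters", "cage_in_promoters", length(atac_at_prom))
  mp <- metaplot(atac, locus_tss)
  add("metaplot", "n_tss", mp$n)
  add("metaplot", "argmax_offset", mp$profile$offset[which.max(mp$profile$mean)])
  add("metaplot", "max_mean", max(mp$profile$mean))

  report <- do.call(rbind, report)
  write.table(report, file.path(out_dir, "report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest <- list(
    package = "locusforge",
    version = as.character(packageVersion("locusforge")),
    seed = as.integer(seed),
    parameters = list(window_size = as.integer(window_size),
                      window_step = as.integer(window_step)),
    inputs = lapply(t_files, normalizePath)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}

# strip names/mcols so GRanges from different readers concatenate
granges_only <- function(gr) {
  out <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)))
  out
}
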