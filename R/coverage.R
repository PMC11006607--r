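# Sliding-window coverage statistics: windowing, mean depth, copy-number
# estimation, RPGC normalization, relative coverage, peak density,
# geneless windows, flag-filtered read counting, replicate correlation.

#' Sliding windows over a set of contigs
#'
#' Per contig, windows `[k * step + 1, k * step + size]` for all `k` whose
#' window fits entirely on the contig. Truncated terminal windows are
#' dropped by default so every window shares the same denominator; set
#' `keep_partial = TRUE` to retain them.
#'
#' @param contig_lengths Named integer vector of contig lengths.
#' @param size Window size in bp.
#' @param step Step between window starts in bp (`step <= size` gives
#'   sliding windows, `step == size` a non-overlapping tiling).
#' @return A [GenomicRanges::GRanges] of windows; `metadata()` records
#'   `size` and `step`.
#' @export
make_windows <- function(contig_lengths, size = 100000L, step = 10000L,
                         keep_partial = FALSE) {
  stopifnot(is.numeric(contig_lengths), !is.null(names(contig_lengths)),
            size >= step, step > 0)
  size <- as.integer(size)
  step <- as.integer(step)
  out <- list()
  for (ct in names(contig_lengths)) {
    len <- as.integer(contig_lengths[[ct]])
    if (keep_partial) {
      starts <- seq.int(1L, len, by = step)
      ends <- pmin(starts + size - 1L, len)
    } else {
      if (len < size) next
      starts <- seq.int(1L, len - size + 1L, by = step)
      ends <- starts + size - 1L
    }
    out[[ct]] <- GRanges(ct, IRanges(starts, ends))
  }
  gr <- if (length(out)) suppressWarnings(do.call(c, unname(out))) else GRanges()
  metadata(gr) <- list(size = size, step = step)
  gr
}

#' Mean per-base depth over regions
#'
#' Total read base count (the sum of per-base depths) over each region,
#' divided by the region length.
#'
#' @param track A per-base numeric [IRanges::RleList].
#' @param regions A [GenomicRanges::GRanges]; every region must lie within
#'   its contig.
#' @return Numeric vector of mean depths, one per region.
#' @export
mean_depth <- function(track, regions) {
  stopifnot(is(track, "RleList"), is(regions, "GRanges"))
  lens <- track_lengths(track)
  ct <- as.character(seqnames(regions))
  if (any(!ct %in% names(lens))) {
    stop("region on unknown contig '", ct[!ct %in% names(lens)][1L], "'",
         call. = FALSE)
  }
  if (any(start(regions) < 1L) || any(end(regions) > lens[ct])) {
    stop("region extends outside the coverage track", call. = FALSE)
  }
  out <- numeric(length(regions))
  for (contig in unique(ct)) {
    i <- which(ct == contig)
    v <- Views(track[[contig]], IRanges(start(regions)[i], end(regions)[i]))
    out[i] <- viewMeans(v)
  }
  out
}

#' Estimate the copy number of a locus from sequencing depth
#'
#' Mean depth over the locus divided by the mean depth over the rest of
#' the genome (all contigs except `exclude_contigs`, with the locus's own
#' contig excluded from the genome mean when it carries nothing else --
#' i.e. when the locus spans its whole contig). The mitochondrial contig
#' is excluded by default because its copy number does not reflect the
#' nuclear genome.
#'
#' @param wgs Whole-genome-sequencing depth track ([IRanges::RleList]).
#' @param locus A single [GenomicRanges::GRanges] interval.
#' @param exclude_contigs Contigs excluded from the genome average.
#' @return A `copy_number_estimate`: list with `locus_mean`,
#'   `genome_mean`, `estimate` (real) and `call` (nearest integer).
#' @export
estimate_copy_number <- function(wgs, locus, exclude_contigs = "chrM") {
  stopifnot(is(wgs, "RleList"), is(locus, "GRanges"), length(locus) == 1L)
  lens <- track_lengths(wgs)
  locus_contig <- as.character(seqnames(locus))
  locus_mean <- mean_depth(wgs, locus)
  # locus spanning its entire contig (e.g. an episome on its own reference
  # contig) must not contribute to the genome background
  drop <- exclude_contigs
  if (locus_contig %in% names(lens) &&
      start(locus) == 1L && end(locus) == lens[[locus_contig]]) {
    drop <- union(drop, locus_contig)
  }
  keep <- setdiff(names(lens), drop)
  if (length(keep) == 0L) stop("no contigs left for the genome average", call. = FALSE)
  tot <- sum(vapply(keep, function(ct) sum(as.numeric(sum(wgs[[ct]]))), numeric(1)))
  glen <- sum(lens[keep])
  if (tot <= 0) stop("genome coverage is zero; cannot estimate copy number",
                     call. = FALSE)
  genome_mean <- tot / glen
  est <- locus_mean / genome_mean
  structure(list(locus_mean = locus_mean, genome_mean = genome_mean,
                 estimate = est, call = as.integer(round(est))),
            class = "copy_number_estimate")
}

#' @export
print.copy_number_estimate <- function(x, ...) {
  cat(sprintf("Copy number %.3f (integer call %d); locus %.3f / genome %.3f\n",
              x$estimate, x$call, x$locus_mean, x$genome_mean))
  invisible(x)
}

#' RPGC (1x) normalization of a coverage track
#'
#' Scales every value by `effective_genome_size / total_depth` so that the
#' genome-wide mean coverage over the effective genome size is 1x. The
#' result is invariant to global rescaling of the input.
#'
#' @param track A per-base numeric [IRanges::RleList].
#' @param effective_genome_size Effective genome size in bp (e.g.
#'   12e6 for budding yeast).
#' @return The normalized [IRanges::RleList].
#' @export
rpgc_normalize <- function(track, effective_genome_size) {
  stopifnot(is(track, "RleList"), effective_genome_size > 0)
  tot <- sum(vapply(names(track), function(ct) sum(as.numeric(sum(track[[ct]]))),
                    numeric(1)))
  if (tot <= 0) stop("total depth is zero; cannot normalize", call. = FALSE)
  scale <- effective_genome_size / tot
  S4Vectors::endoapply(track, function(r) r * scale)
}

#' Copy-number-corrected coverage of a locus relative to the genome
#'
#' The locus mean depth, divided by its copy number, relative to the mean
#' of per-window mean depths over the genome windows:
#' `relative = (locus_mean / copy_number) / genome_mean`. Invariant to
#' global rescaling of the track.
#'
#' @param track Signal track ([IRanges::RleList]).
#' @param locus A single [GenomicRanges::GRanges] interval; its supplied
#'   length is the locus denominator.
#' @param windows Genome windows from [make_windows()] (non-empty).
#' @param copy_number Estimated locus copy number (> 0).
#' @return A `relative_coverage`: list with `locus_mean`, `genome_mean`,
#'   `copy_number` and `relative`.
#' @export
relative_coverage <- function(track, locus, windows, copy_number = 1) {
  stopifnot(is(track, "RleList"), is(locus, "GRanges"), length(locus) == 1L,
            copy_number > 0)
  if (length(windows) == 0L) stop("empty window set", call. = FALSE)
  locus_mean <- mean_depth(track, locus)
  genome_mean <- mean(mean_depth(track, windows))
  structure(list(locus_mean = locus_mean, genome_mean = genome_mean,
                 copy_number = copy_number,
                 relative = (locus_mean / copy_number) / genome_mean),
            class = "relative_coverage")
}

#' @export
print.relative_coverage <- function(x, ...) {
  cat(sprintf("Relative coverage %.3f (locus %.3f / copy %.3g / genome %.3f)\n",
              x$relative, x$locus_mean, x$copy_number, x$genome_mean))
  invisible(x)
}

#' Peak density per 100 kb
#'
#' Counts peaks assigned to a region and scales to peaks per `per` bases
#' (default 100 kb). Assignment is by peak midpoint by default, which
#' avoids double counting across overlapping sliding windows; use
#' `assign = "any"` for any-overlap assignment. With `windows` instead of
#' a single region, returns the mean of the per-window densities.
#'
#' @param peaks A [GenomicRanges::GRanges] of peaks.
#' @param region A single interval, or `NULL` when `windows` is given.
#' @param windows A window set from [make_windows()], or `NULL`.
#' @param per Scaling base count (default 1e5).
#' @param assign `"midpoint"` or `"any"`.
#' @return Peak density (peaks per `per` bp) as a single number.
#' @export
peak_density <- function(peaks, region = NULL, windows = NULL, per = 100000,
                         assign = c("midpoint", "any")) {
  assign <- match.arg(assign)
  stopifnot(is(peaks, "GRanges"))
  anchors <- if (assign == "midpoint") {
    mid <- floor((start(peaks) + end(peaks)) / 2)
    GRanges(seqnames(peaks), IRanges(mid, mid))
  } else {
    peaks
  }
  if (!is.null(region)) {
    stopifnot(is(region, "GRanges"), length(region) == 1L)
    n <- suppressWarnings(countOverlaps(region, anchors, ignore.strand = TRUE))
    return(as.numeric(n) / width(region) * per)
  }
  if (is.null(windows) || length(windows) == 0L) {
    stop("supply either a region or a non-empty window set", call. = FALSE)
  }
  counts <- suppressWarnings(countOverlaps(windows, anchors, ignore.strand = TRUE))
  mean(counts / width(windows) * per)
}

#' Windows free of annotated or excluded features
#'
#' Removes every window that overlaps any exclusion feature (annotated
#' transcripts, blacklist regions, centromeres, telomeres, ...) by at
#' least one base. Geneless windows serve as the background for
#' transcription-level comparisons.
#'
#' @param windows A window set ([GenomicRanges::GRanges]).
#' @param exclusions Features to exclude ([GenomicRanges::GRanges]).
#' @return The surviving windows, metadata preserved.
#' @export
geneless_windows <- function(windows, exclusions) {
  stopifnot(is(windows, "GRanges"), is(exclusions, "GRanges"))
  keep <- !suppressWarnings(overlapsAny(windows, exclusions, ignore.strand = TRUE))
  out <- windows[keep]
  metadata(out) <- metadata(windows)
  out
}

#' Count flag-filtered reads overlapping regions
#'
#' A read is counted in a region when its interval overlaps the region by
#' at least one base and its SAM flags contain none of the bits in
#' `exclude_flags` (default 2308 = unmapped 4 + secondary 256 +
#' supplementary 2048; note duplicates, bit 1024, are *not* excluded by
#' this mask and are counted).
#'
#' @param reads A [GenomicRanges::GRanges] with an integer `flag`
#'   metadata column (see [read_reads()]).
#' @param regions Regions to count over.
#' @param exclude_flags Bitmask of excluding flags.
#' @return A `region_counts`: list with `counts` (integer vector, one per
#'   region) and `median` (lower median across regions).
#' @export
count_reads_in_regions <- function(reads, regions, exclude_flags = 2308L) {
  stopifnot(is(reads, "GRanges"), is(regions, "GRanges"))
  flag <- mcols(reads)$flag
  if (is.null(flag)) stop("reads need a 'flag' metadata column", call. = FALSE)
  keep <- bitwAnd(as.integer(flag), as.integer(exclude_flags)) == 0L
  counts <- suppressWarnings(
    countOverlaps(regions, reads[keep], ignore.strand = TRUE))
  structure(list(counts = counts, median = lower_median(counts)),
            class = "region_counts")
}

#' @export
print.region_counts <- function(x, ...) {
  cat("Read counts over ", length(x$counts), " regions; median ",
      x$median, "\n", sep = "")
  invisible(x)
}

#' Pearson correlation of two tracks over genomic bins
#'
#' Averages each track over non-overlapping `bin`-bp bins, then (in
#' order): drops bins that are zero in both tracks (`skip_zeros`), drops
#' bins where either value deviates from its track median by more than
#' `mad_k` median absolute deviations (`remove_outliers`), applies
#' `log(1 + x)` (`log1p`), and returns the Pearson correlation.
#'
#' @param a,b Per-base numeric [IRanges::RleList] tracks over the same
#'   contigs.
#' @param bin Bin size in bp.
#' @param skip_zeros Drop bins zero in both tracks?
#' @param remove_outliers Drop MAD outliers?
#' @param log1p Apply `log(1 + x)` before correlating?
#' @param mad_k Outlier threshold in MADs.
#' @return Pearson r as a single number.
#' @export
binned_correlation <- function(a, b, bin = 10000L, skip_zeros = TRUE,
                               remove_outliers = TRUE, log1p = TRUE,
                               mad_k = 10) {
  stopifnot(is(a, "RleList"), is(b, "RleList"))
  la <- track_lengths(a)
  lb <- track_lengths(b)
  if (!identical(sort(names(la)), sort(names(lb))) || !all(la == lb[names(la)])) {
    stop("tracks must cover the same contigs at the same lengths", call. = FALSE)
  }
  bin <- as.integer(bin)
  va <- vb <- numeric(0)
  for (ct in names(la)) {
    nb <- la[[ct]] %/% bin
    if (nb == 0L) next
    ir <- IRanges(start = seq.int(1L, by = bin, length.out = nb), width = bin)
    va <- c(va, viewMeans(Views(a[[ct]], ir)))
    vb <- c(vb, viewMeans(Views(b[[ct]], ir)))
  }
  if (skip_zeros) {
    keep <- !(va == 0 & vb == 0)
    va <- va[keep]; vb <- vb[keep]
  }
  if (remove_outliers) {
    ok <- rep(TRUE, length(va))
    for (v in list(va, vb)) {
      m <- median(v)
      s <- mad(v)
      if (s > 0) ok <- ok & abs(v - m) <= mad_k * s
    }
    va <- va[ok]; vb <- vb[ok]
  }
  if (log1p) {
    va <- log1p(va); vb <- log1p(vb)
  }
  if (length(va) < 3L) {
    stop("fewer than 3 bins survive filtering; cannot correlate", call. = FALSE)
  }
  cor(va, vb, method = "pearson")
}
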