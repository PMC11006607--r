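# CAGE-derived TSSs, promoter intervals, and TSS-anchored metaplots.

#' Transcription start sites from CAGE peaks
#'
#' The TSS is the 5' coordinate of a CAGE peak: the start of a plus-strand
#' peak, the end of a minus-strand peak. CAGE peaks are stranded by
#' nature; unstranded peaks are an error.
#'
#' @param peaks Stranded CAGE peaks ([GenomicRanges::GRanges]).
#' @return Width-1 [GenomicRanges::GRanges] of TSS positions, strand kept.
#' @export
tss_from_cage <- function(peaks) {
  stopifnot(is(peaks, "GRanges"))
  st <- as.character(strand(peaks))
  if (any(st == "*")) {
    stop("CAGE peaks must be stranded (+ or -); found unstranded peaks",
         call. = FALSE)
  }
  pos <- ifelse(st == "+", start(peaks), end(peaks))
  GRanges(seqnames(peaks), IRanges(pos, pos), strand = st)
}

#' Promoter intervals around TSSs
#'
#' The promoter of a TSS spans `upstream` bases before it and
#' `downstream` bases from the TSS onwards (the TSS base is the first
#' downstream base), oriented by strand, for a total of
#' `upstream + downstream` bases on either strand. Defaults follow the
#' 200-bp-upstream / 100-bp-downstream putative-promoter definition.
#' Intervals running off a contig edge are clipped when contig lengths
#' are supplied.
#'
#' @param tss Width-1 stranded [GenomicRanges::GRanges] (see
#'   [tss_from_cage()]).
#' @param upstream,downstream Extents in bp.
#' @param contig_lengths Optional named contig lengths for clipping.
#' @return Promoter intervals as [GenomicRanges::GRanges].
#' @export
promoter_intervals <- function(tss, upstream = 200L, downstream = 100L,
                               contig_lengths = NULL) {
  stopifnot(is(tss, "GRanges"), all(width(tss) == 1L))
  prom <- suppressWarnings(promoters(tss, upstream = upstream,
                                     downstream = downstream))
  if (!is.null(contig_lengths)) {
    lens <- contig_lengths[as.character(seqnames(prom))]
    s <- pmax(start(prom), 1L)
    e <- pmin(end(prom), as.integer(lens))
    n_clip <- sum(s != start(prom) | e != end(prom))
    if (n_clip > 0) {
      message(n_clip, " promoter interval(s) clipped to contig bounds")
    }
    prom <- GRanges(seqnames(prom), IRanges(s, e), strand = strand(prom))
  }
  prom
}

#' ATAC peaks overlapping promoters
#'
#' Convenience wrapper around [intersect_peaks()]: peaks that overlap any
#' promoter interval by at least one base, strand-blind.
#'
#' @param peaks Peak set ([GenomicRanges::GRanges]).
#' @param promoters Promoter intervals ([GenomicRanges::GRanges]).
#' @return The overlapping subset of `peaks`.
#' @export
promoter_peak_overlap <- function(peaks, promoters) {
  intersect_peaks(peaks, promoters)
}

#' TSS-anchored signal metaplot
#'
#' For every TSS, extracts signal over the window from `flank` bases
#' upstream to `flank` bases downstream (the TSS base is offset 0;
#' offsets run `-flank .. flank - 1`), flips minus-strand windows so that
#' upstream is always left, averages within `bin`-bp bins, and aggregates
#' across TSSs into a per-bin mean and standard error (`sd / sqrt(n)`).
#' TSSs whose window runs off a contig edge are dropped (zero-padding
#' would bias the mean towards 0) and counted in `n_dropped`.
#'
#' An optional centered moving average of width `smooth` bp can be
#' applied to the track before extraction (off by default; mirrors the
#' smoothing used when coverage tracks are generated with a smooth
#' length).
#'
#' @param track Signal track ([IRanges::RleList]).
#' @param tss Width-1 stranded [GenomicRanges::GRanges].
#' @param flank Half-window in bp; must be divisible by `bin`.
#' @param bin Bin width in bp.
#' @param smooth Optional moving-average width in bp (`NULL` = none).
#' @return A `metaplot_profile`: list with `profile` (data.frame of
#'   `offset` -- the bin's first offset --, `mean`, `se`), `n` (TSSs
#'   aggregated), `n_dropped`, `flank`, `bin`.
#' @export
metaplot <- function(track, tss, flank = 500L, bin = 10L, smooth = NULL) {
  stopifnot(is(track, "RleList"), is(tss, "GRanges"), all(width(tss) == 1L))
  flank <- as.integer(flank)
  bin <- as.integer(bin)
  if (flank %% bin != 0L) stop("flank must be divisible by bin", call. = FALSE)
  lens <- track_lengths(track)
  ct <- as.character(seqnames(tss))
  if (any(!ct %in% names(lens))) {
    stop("TSS on a contig absent from the track", call. = FALSE)
  }
  st <- as.character(strand(tss))
  if (any(st == "*")) stop("TSSs must be stranded", call. = FALSE)
  pos <- start(tss)
  # window on the contig: plus strand [pos - flank, pos + flank - 1],
  # minus strand [pos - flank + 1, pos + flank] read right-to-left
  lo <- ifelse(st == "+", pos - flank, pos - flank + 1L)
  hi <- ifelse(st == "+", pos + flank - 1L, pos + flank)
  usable <- lo >= 1L & hi <= lens[ct]
  n_dropped <- sum(!usable)
  if (!any(usable)) stop("no TSS window fits inside the track", call. = FALSE)
  idx <- which(usable)
  w <- 2L * flank
  mat <- matrix(NA_real_, nrow = length(idx), ncol = w)
  cache <- new.env(parent = emptyenv())
  get_contig <- function(contig) {
    if (!exists(contig, envir = cache, inherits = FALSE)) {
      v <- as.numeric(track[[contig]])
      if (!is.null(smooth)) v <- moving_average(v, as.integer(smooth))
      assign(contig, v, envir = cache)
    }
    get(contig, envir = cache, inherits = FALSE)
  }
  for (r in seq_along(idx)) {
    i <- idx[r]
    v <- get_contig(ct[i])[lo[i]:hi[i]]
    if (st[i] == "-") v <- rev(v)
    mat[r, ] <- v
  }
  groups <- rep(seq_len(w %/% bin), each = bin)
  binned <- t(apply(mat, 1L, function(row) tapply(row, groups, mean)))
  if (nrow(mat) == 1L) binned <- matrix(binned, nrow = 1L)
  mu <- colMeans(binned)
  se <- if (nrow(binned) > 1L) {
    apply(binned, 2L, sd) / sqrt(nrow(binned))
  } else {
    rep(0, ncol(binned))
  }
  structure(
    list(profile = data.frame(offset = seq.int(-flank, flank - 1L, by = bin),
                              mean = as.numeric(mu), se = as.numeric(se)),
         n = nrow(binned), n_dropped = n_dropped, flank = flank, bin = bin),
    class = "metaplot_profile"
  )
}

#' @export
print.metaplot_profile <- function(x, ...) {
  cat("Metaplot over ", x$n, " TSS(s) (", x$n_dropped, " dropped), +/-",
      x$flank, " bp in ", x$bin, "-bp bins\n", sep = "")
  peak <- x$profile[which.max(x$profile$mean), ]
  cat(sprintf("  max mean %.4g at offset %d\n", peak$mean, peak$offset))
  invisible(x)
}

# Centered moving average; edges keep the original values.
moving_average <- function(v, width) {
  if (width <= 1L) return(v)
  sm <- as.numeric(stats::filter(v, rep(1 / width, width), sides = 2))
  sm[is.na(sm)] <- v[is.na(sm)]
  sm
}
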