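# Sequence-composition statistics: dinucleotide profiles, observed/expected
# CpG, windowed GC, CpG islands, IUPAC motif scanning, and the count-level
# prediction of what reversal does to a profile.

#' Dinucleotide composition profile of a sequence
#'
#' Counts every base (A, C, G, T, with N tallied separately) and every
#' overlapping dinucleotide; pairs containing an N are skipped. GC
#' fraction uses an N-free denominator.
#'
#' @param x A single sequence over A/C/G/T/N.
#' @return A `dinuc_profile`: list with `id`, `length`, `mono` (named
#'   counts A/C/G/T/N), `dinuc` (named counts of the 16 dinucleotides) and
#'   `gc_fraction`.
#' @examples
#' p <- dinuc_profile("ACGT")
#' p$dinuc[c("AC", "CG", "GT")]
#' @export
dinuc_profile <- function(x) {
  rec <- as_seq_record(x)
  check_alphabet(rec$seq, rec$id)
  s <- DNAString(rec$seq)
  af <- alphabetFrequency(s)
  mono <- af[c("A", "C", "G", "T", "N")]
  dinuc <- dinucleotideFrequency(s)
  len <- length(s)
  n_free <- len - mono[["N"]]
  gc <- if (n_free > 0) (mono[["C"]] + mono[["G"]]) / n_free else 0
  new_dinuc_profile(len, mono, dinuc, id = rec$id, gc_fraction = gc)
}

#' Construct a dinucleotide profile from counts
#'
#' Low-level constructor used when only the counts are available (for
#' example from a published composition table). Validates shapes and
#' non-negativity; [dinuc_profile()] computes fully consistent profiles
#' from sequence.
#'
#' @param length Sequence length in bp.
#' @param mono Named counts for A, C, G, T (N optional, default 0).
#' @param dinuc Named counts for the 16 dinucleotides (missing names
#'   default to 0).
#' @param id Record identifier.
#' @param gc_fraction GC fraction; computed from `mono` when `NULL`.
#' @return A `dinuc_profile`.
#' @export
new_dinuc_profile <- function(length, mono = NULL, dinuc = NULL, id = "profile",
                              gc_fraction = NULL) {
  all_dinucs <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                paste0))
  m <- setNames(rep(0, 5L), c("A", "C", "G", "T", "N"))
  if (!is.null(mono)) m[names(mono)] <- mono
  d <- setNames(rep(0, 16L), all_dinucs)
  if (!is.null(dinuc)) {
    if (!all(names(dinuc) %in% all_dinucs)) {
      stop("unknown dinucleotide name in 'dinuc'", call. = FALSE)
    }
    d[names(dinuc)] <- dinuc
  }
  if (any(m < 0) || any(d < 0) || length < 1) {
    stop("counts and length must be non-negative", call. = FALSE)
  }
  if (is.null(gc_fraction)) {
    n_free <- length - m[["N"]]
    gc_fraction <- if (n_free > 0) (m[["C"]] + m[["G"]]) / n_free else 0
  }
  structure(
    list(id = id, length = as.integer(length), mono = m,
         dinuc = d[all_dinucs], gc_fraction = as.numeric(gc_fraction)),
    class = "dinuc_profile"
  )
}

#' @export
print.dinuc_profile <- function(x, ...) {
  cat("Dinucleotide profile '", x$id, "': ", x$length, " bp, GC ",
      round(x$gc_fraction, 3), "\n", sep = "")
  print(x$dinuc)
  invisible(x)
}

#' Predict the dinucleotide profile of a reversed sequence
#'
#' Reversal (without complementation) maps every occurrence of the
#' dinucleotide XY onto YX, and leaves length and mononucleotide counts
#' unchanged. This computes the reversed-locus profile directly from the
#' forward profile, without touching the sequence. Applying it twice
#' returns the original profile.
#'
#' @param p A `dinuc_profile` with no N bases.
#' @return A `dinuc_profile` for the reversed sequence.
#' @export
predict_reversed_profile <- function(p) {
  stopifnot(inherits(p, "dinuc_profile"))
  if (p$mono[["N"]] > 0) {
    stop("profiles with N bases cannot be reversal-predicted", call. = FALSE)
  }
  rev_names <- vapply(strsplit(names(p$dinuc), ""), function(b)
    paste0(b[2L], b[1L]), character(1))
  d <- setNames(as.vector(p$dinuc), rev_names)
  new_dinuc_profile(p$length, p$mono, d, id = paste0(p$id, "_R"),
                    gc_fraction = p$gc_fraction)
}

#' Observed/expected CpG statistics
#'
#' The expected CpG count of a sequence is `nC * nG / length`, and the
#' observed/expected ratio is the observed CpG count divided by that
#' expectation (0 when the expectation is 0). Composition-random DNA has a
#' ratio near 1; CpG-depleted mammalian DNA is far below 1.
#'
#' @param p A `dinuc_profile`.
#' @return A `cpg_stats`: list with `observed`, `expected`, `ratio` (full
#'   precision; see [format.cpg_stats()] for the 2-decimal display form).
#' @export
cpg_stats <- function(p) {
  stopifnot(inherits(p, "dinuc_profile"), p$length > 0)
  expected <- p$mono[["C"]] * p$mono[["G"]] / p$length
  new_cpg_stats(p$dinuc[["CG"]], expected)
}

#' @rdname cpg_stats
#' @param observed Observed CpG count.
#' @param expected Expected CpG count (`nC * nG / length`).
#' @export
new_cpg_stats <- function(observed, expected) {
  stopifnot(observed >= 0, expected >= 0)
  ratio <- if (expected > 0) observed / expected else 0
  structure(list(observed = as.numeric(observed),
                 expected = as.numeric(expected),
                 ratio = ratio),
            class = "cpg_stats")
}

#' @export
format.cpg_stats <- function(x, ...) {
  # display convention: O/E ratio to two decimals, round-half-even
  sprintf("CpG observed %s, expected %s, O/E %s",
          format(x$observed), format(round(x$expected)),
          format(round(x$ratio, 2), nsmall = 2))
}

#' @export
print.cpg_stats <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Fold enrichment between two observed/expected CpG ratios
#'
#' Quotient of the O/E ratios of two sequences. By default each ratio is
#' first rounded to `ratio_digits` decimals (round-half-even), matching
#' the convention of reporting O/E ratios to two decimals; pass
#' `ratio_digits = NULL` for the full-precision quotient.
#'
#' @param a,b `cpg_stats` objects (enrichment of `a` over `b`).
#' @param ratio_digits Decimals to round each ratio to before dividing,
#'   or `NULL` for no rounding.
#' @return The fold enrichment (0 when `a`'s ratio is 0).
#' @export
oe_fold_enrichment <- function(a, b, ratio_digits = 2L) {
  stopifnot(inherits(a, "cpg_stats"), inherits(b, "cpg_stats"))
  ra <- a$ratio
  rb <- b$ratio
  if (!is.null(ratio_digits)) {
    ra <- round(ra, ratio_digits)
    rb <- round(rb, ratio_digits)
  }
  if (rb == 0) {
    if (ra == 0) {
      stop("fold enrichment is undefined when both ratios are 0", call. = FALSE)
    }
    stop("fold enrichment is undefined for a zero reference ratio", call. = FALSE)
  }
  ra / rb
}

#' Windowed GC content track
#'
#' GC fraction over sliding windows anchored at their start position, with
#' an N-free denominator. Only complete windows are reported.
#'
#' @param x A single sequence.
#' @param window Window width in bp.
#' @param step Step between window starts in bp.
#' @return A [GenomicRanges::GRanges] on the sequence id with a numeric
#'   `gc` metadata column.
#' @export
gc_track <- function(x, window = 5000L, step = window) {
  rec <- as_seq_record(x)
  check_alphabet(rec$seq, rec$id)
  L <- nchar(rec$seq)
  window <- as.integer(window)
  step <- as.integer(step)
  if (window > L) stop("window (", window, ") exceeds sequence length (", L, ")",
                       call. = FALSE)
  stopifnot(window >= 1L, step >= 1L)
  lf <- letterFrequencyInSlidingView(DNAString(rec$seq), window, c("CG", "N"))
  starts <- seq.int(1L, L - window + 1L, by = step)
  denom <- window - lf[starts, "N"]
  gc <- ifelse(denom > 0, lf[starts, "C|G"] / denom, 0)
  gr <- GRanges(rec$id, IRanges(starts, width = window))
  mcols(gr)$gc <- as.numeric(gc)
  gr
}

#' Call CpG islands by windowed thresholding
#'
#' Slides a `window`-bp view along the sequence in 1-bp steps and marks
#' windows whose GC fraction and observed/expected CpG ratio (computed
#' with the same `nC * nG / window` expectation used globally) meet the
#' thresholds. Maximal runs of qualifying windows are merged into islands
#' spanning from the first qualifying window start to the last qualifying
#' window end, and islands shorter than `min_len` are discarded. Defaults
#' follow the classic CpG-island plotting parameters (100-bp window,
#' 1-bp shift, 200-bp minimum length, GC >= 0.5, O/E >= 0.6).
#'
#' @param x A single sequence over A/C/G/T (N is allowed but counts
#'   against the thresholds).
#' @param window Scoring window in bp.
#' @param min_len Minimum island length in bp.
#' @param min_gc Minimum windowed GC fraction.
#' @param min_oe Minimum windowed observed/expected CpG ratio.
#' @return A [GenomicRanges::GRanges] with `mean_gc` and `mean_oe`
#'   metadata columns (means over the qualifying windows of each island);
#'   empty when no island qualifies.
#' @export
find_cpg_islands <- function(x, window = 100L, min_len = 200L,
                             min_gc = 0.5, min_oe = 0.6) {
  rec <- as_seq_record(x)
  check_alphabet(rec$seq, rec$id)
  L <- nchar(rec$seq)
  window <- as.integer(window)
  if (L < window) stop("sequence shorter than the scoring window", call. = FALSE)
  s <- DNAString(rec$seq)
  lf <- letterFrequencyInSlidingView(s, window, c("C", "G"))
  nC <- lf[, "C"]
  nG <- lf[, "G"]
  gc <- (nC + nG) / window
  # windowed CpG count via cumulative sum over CG start positions
  bases <- strsplit(rec$seq, "", fixed = TRUE)[[1L]]
  is_cg <- bases[-L] == "C" & bases[-1L] == "G"
  cs <- c(0, cumsum(is_cg))
  n_win <- L - window + 1L
  # window i covers CG starts i .. i + window - 2
  obs <- cs[pmin(seq_len(n_win) + window - 1L, L)] - cs[seq_len(n_win)]
  expct <- nC * nG / window
  oe <- ifelse(expct > 0, obs / expct, 0)
  ok <- gc >= min_gc & oe >= min_oe
  r <- rle(ok)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  qual <- which(r$values)
  if (length(qual) == 0L) return(GRanges())
  isl_start <- run_start[qual]
  isl_end <- run_end[qual] + window - 1L
  keep <- (isl_end - isl_start + 1L) >= min_len
  if (!any(keep)) return(GRanges())
  isl_start <- isl_start[keep]
  isl_end <- isl_end[keep]
  mean_gc <- mean_oe <- numeric(length(isl_start))
  for (i in seq_along(isl_start)) {
    w <- seq.int(run_start[qual[keep][i]], run_end[qual[keep][i]])
    mean_gc[i] <- mean(gc[w])
    mean_oe[i] <- mean(oe[w])
  }
  gr <- GRanges(rec$id, IRanges(isl_start, isl_end))
  mcols(gr)$mean_gc <- mean_gc
  mcols(gr)$mean_oe <- mean_oe
  gr
}

#' Scan a sequence for a degenerate IUPAC pattern
#'
#' Reports all exact matches of `pattern` under IUPAC degeneracy (N
#' matches any base, R matches A/G, ...). With `both_strands = TRUE` the
#' reverse complement of the pattern is also scanned and its matches are
#' reported on the minus strand, in the coordinates of the scanned
#' sequence.
#'
#' @param x A single sequence.
#' @param pattern IUPAC pattern string.
#' @param both_strands Also scan for the reverse-complement pattern?
#' @return A [GenomicRanges::GRanges] of match locations with strand.
#' @export
iupac_scan <- function(x, pattern, both_strands = FALSE) {
  rec <- as_seq_record(x)
  pattern <- toupper(pattern)
  bad <- setdiff(strsplit(pattern, "")[[1L]], names(IUPAC_CODE_MAP))
  if (length(bad)) {
    stop("illegal IUPAC code '", bad[1L], "' in pattern", call. = FALSE)
  }
  s <- DNAString(rec$seq)
  fwd <- matchPattern(DNAString(pattern), s, fixed = "subject")
  hits <- GRanges(rep(rec$id, length(fwd)), IRanges(start(fwd), end(fwd)),
                  strand = rep("+", length(fwd)))
  if (both_strands) {
    rc <- reverseComplement(DNAString(pattern))
    rev <- matchPattern(rc, s, fixed = "subject")
    hits <- c(hits,
              GRanges(rep(rec$id, length(rev)), IRanges(start(rev), end(rev)),
                      strand = rep("-", length(rev))))
  }
  hits[order(as.factor(seqnames(hits)), start(hits))]
}
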