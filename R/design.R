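# Locus design transforms: reversal without complementation, iterative
# stochastic CpG elimination, synthesis segmentation, and homology-arm
# insertion design. These are the algorithms that produce an
# evolutionarily naive locus from a natural template.

#' Reverse a DNA sequence without complementing it
#'
#' Writes the sequence right-to-left (`output[i] = input[L + 1 - i]`)
#' without exchanging A/T or C/G. Reversal preserves length, every
#' mononucleotide count (hence GC content, homopolymer runs, repeat
#' content), and maps every dinucleotide XY onto YX -- so the reversed
#' locus keeps the composition of the template while ablating its evolved
#' coding and regulatory information. The identifier gains a `_R` suffix.
#'
#' Ambiguity codes are rejected: a sequence destined for DNA synthesis
#' cannot contain N.
#'
#' @param x A single sequence: character scalar, [Biostrings::DNAString],
#'   or length-1 [Biostrings::DNAStringSet].
#' @return A length-1 named [Biostrings::DNAStringSet].
#' @seealso [predict_reversed_profile()] for the count-level consequence.
#' @export
reverse_sequence <- function(x) {
  rec <- as_seq_record(x)
  check_alphabet(rec$seq, rec$id, c("A", "C", "G", "T"))
  out <- DNAStringSet(Biostrings::reverse(DNAString(rec$seq)))
  names(out) <- paste0(rec$id, "_R")
  out
}

#' Eliminate all CpG dinucleotides by iterative stochastic deletion
#'
#' Scans the sequence for occurrences of `CG` and, for each occurrence,
#' deletes either the C or the G with equal probability. Because a
#' deletion can juxtapose a new C and G, the scan is reiterated until no
#' `CG` remains. Within one scan all occurrences (which are necessarily
#' at least two bases apart) are processed right-to-left, one independent
#' fair coin flip per occurrence, so indices stay stable.
#'
#' The realized output is one sample from the reachable set; the
#' guaranteed contract is that the result contains no `CG` substring and
#' that `nchar(input) - nchar(output)` equals the number of recorded
#' deletions. Runs are fully determined by `seed`.
#'
#' @param x A single sequence over A/C/G/T (see [reverse_sequence()] for
#'   accepted types).
#' @param seed Integer seed driving the coin flips; recorded in the result.
#' @param max_iter Safety cap on scan iterations (the process provably
#'   terminates; the cap guards against implementation error).
#' @return A `scrub_result`: list with elements
#'   \describe{
#'     \item{scrubbed}{named length-1 DNAStringSet, id suffixed `_noCpG`}
#'     \item{deletions}{data.frame with columns `iteration`, `position`
#'       (1-based position in the then-current sequence) and `base`
#'       (`"C"` or `"G"`), in deletion order}
#'     \item{n_iterations}{number of scans that deleted at least one base}
#'     \item{seed}{the seed used}
#'   }
#' @seealso [replay_scrub()] to reconstruct the output from the audit
#'   trail, [scrub_position_map()] for coordinate lift-over.
#' @export
scrub_cpg <- function(x, seed, max_iter = 100L) {
  rec <- as_seq_record(x)
  check_alphabet(rec$seq, rec$id, c("A", "C", "G", "T"))
  bases <- strsplit(rec$seq, "", fixed = TRUE)[[1L]]
  del_iter <- integer(0)
  del_pos <- integer(0)
  del_base <- character(0)
  it <- 0L
  with_seed(seed, {
    repeat {
      n <- length(bases)
      hits <- if (n >= 2L) which(bases[-n] == "C" & bases[-1L] == "G") else integer(0)
      if (length(hits) == 0L) break
      it <- it + 1L
      if (it > max_iter) {
        stop("scrub_cpg did not converge within ", max_iter,
             " iterations; this indicates an internal error", call. = FALSE)
      }
      # One coin per occurrence: 0 deletes the C (at hit), 1 deletes the G.
      # Occurrences are >= 2 apart so the right-to-left deletions never
      # disturb one another and can be applied as a batch.
      flips <- sample.int(2L, length(hits), replace = TRUE) - 1L
      drops <- hits + flips
      ord <- order(drops, decreasing = TRUE)
      del_iter <- c(del_iter, rep.int(it, length(drops)))
      del_pos <- c(del_pos, drops[ord])
      del_base <- c(del_base, bases[drops[ord]])
      bases <- bases[-drops]
    }
  })
  out_seq <- paste(bases, collapse = "")
  if (!nzchar(out_seq)) {
    warning("scrubbing reduced '", rec$id, "' to an empty sequence")
    scrubbed <- DNAStringSet("")
  } else {
    scrubbed <- DNAStringSet(out_seq)
  }
  names(scrubbed) <- paste0(rec$id, "_noCpG")
  structure(
    list(
      scrubbed = scrubbed,
      deletions = data.frame(iteration = del_iter, position = del_pos,
                             base = del_base, stringsAsFactors = FALSE),
      n_iterations = it,
      seed = as.integer(seed)
    ),
    class = "scrub_result"
  )
}

#' @export
print.scrub_result <- function(x, ...) {
  cat("CpG scrub result (seed ", x$seed, ")\n", sep = "")
  cat("  deletions: ", nrow(x$deletions), " over ", x$n_iterations,
      " iteration(s)\n", sep = "")
  cat("  scrubbed length: ", width(x$scrubbed), "\n", sep = "")
  invisible(x)
}

#' Replay a scrub audit trail
#'
#' Applies the recorded deletions, in order, to the input sequence and
#' returns the reconstructed output. Each deletion's position refers to
#' the sequence as it stood at the time of deletion, and the recorded base
#' is checked against the sequence during replay.
#'
#' @param x The original input sequence.
#' @param deletions The `deletions` data.frame of a [scrub_cpg()] result.
#' @return The reconstructed sequence as a character scalar.
#' @export
replay_scrub <- function(x, deletions) {
  rec <- as_seq_record(x)
  bases <- strsplit(rec$seq, "", fixed = TRUE)[[1L]]
  for (i in seq_len(nrow(deletions))) {
    p <- deletions$position[i]
    if (p < 1L || p > length(bases) || bases[p] != deletions$base[i]) {
      stop("audit trail does not replay against this input (deletion ", i, ")",
           call. = FALSE)
    }
    bases <- bases[-p]
  }
  paste(bases, collapse = "")
}

#' Map input coordinates through a scrub
#'
#' @param input_length Length of the scrubbed input sequence.
#' @param deletions The `deletions` data.frame of a [scrub_cpg()] result.
#' @return Integer vector of length `input_length`: for each input
#'   position, its 1-based position in the scrubbed output, or `NA` if the
#'   base was deleted.
#' @export
scrub_position_map <- function(input_length, deletions) {
  idx <- seq_len(input_length)
  for (i in seq_len(nrow(deletions))) {
    idx <- idx[-deletions$position[i]]
  }
  out <- rep(NA_integer_, input_length)
  out[idx] <- seq_along(idx)
  out
}

#' Minimal number of synthesis segments to tile a locus
#'
#' The smallest `n` such that `n` segments of at most `target_len` bases,
#' each overlapping its neighbour by at least `overlap` bases, cover a
#' locus of `L` bases: `n * target_len - (n - 1) * overlap >= L`. For
#' `L > target_len` this is `ceil((L - overlap) / (target_len - overlap))`;
#' otherwise one segment suffices.
#'
#' @param L Locus length in bp.
#' @param target_len Maximum segment length in bp.
#' @param overlap Required overlap between neighbouring segments in bp
#'   (must be smaller than `target_len`).
#' @return Integer segment count.
#' @examples
#' minimal_segment_count(100667, 4000, 300)  # 28
#' minimal_segment_count(95067, 3000, 300)   # 36
#' @export
minimal_segment_count <- function(L, target_len, overlap) {
  stopifnot(length(L) == 1L, length(target_len) == 1L, length(overlap) == 1L,
            L >= 1, target_len >= 1, overlap >= 0)
  if (overlap >= target_len) {
    stop("overlap (", overlap, ") must be smaller than target_len (",
         target_len, ")", call. = FALSE)
  }
  if (L <= target_len) return(1L)
  as.integer(ceiling((L - overlap) / (target_len - overlap)))
}

#' Plan overlapping synthesis segments for a locus
#'
#' Splits a locus into [minimal_segment_count()] segments of equal length
#' (the balanced length `ceil((L + (n-1) * overlap) / n)`, never exceeding
#' `target_len`), with consecutive segments overlapping by at least
#' `overlap` bases and the union covering the whole locus. Balanced
#' segments are synthesis-friendly and make the plan deterministic.
#'
#' @inheritParams minimal_segment_count
#' @param x The locus sequence (or a bare integer length).
#' @param target_len Maximum segment length in bp.
#' @param overlap Minimum overlap between neighbours in bp.
#' @return A `segment_plan`: list with `locus_id`, `locus_length`,
#'   `target_len`, `overlap`, and `segments`, a [GenomicRanges::GRanges]
#'   on the locus (seqname = locus id) named `seg1..segN`.
#' @seealso [segment_sequences()] to extract the segment sequences.
#' @export
plan_segments <- function(x, target_len, overlap) {
  if (is.numeric(x) && length(x) == 1L) {
    id <- "locus"
    L <- as.integer(x)
  } else {
    rec <- as_seq_record(x)
    id <- rec$id
    L <- nchar(rec$seq)
  }
  n <- minimal_segment_count(L, target_len, overlap)
  if (n == 1L) {
    seg_len <- L
    starts <- 1L
  } else {
    seg_len <- as.integer(ceiling((L + (n - 1) * overlap) / n))
    # Evenly spread the n segment starts over [1, L - seg_len + 1].
    starts <- as.integer(floor((seq_len(n) - 1L) * (L - seg_len) / (n - 1L))) + 1L
    starts[n] <- L - seg_len + 1L
  }
  segs <- GRanges(id, IRanges(starts, width = seg_len))
  names(segs) <- paste0("seg", seq_len(n))
  structure(
    list(locus_id = id, locus_length = L, target_len = as.integer(target_len),
         overlap = as.integer(overlap), segments = segs),
    class = "segment_plan"
  )
}

#' @export
print.segment_plan <- function(x, ...) {
  cat("Segment plan for '", x$locus_id, "' (", x$locus_length, " bp)\n",
      sep = "")
  cat("  ", length(x$segments), " segments, length <= ", x$target_len,
      " bp, overlap >= ", x$overlap, " bp\n", sep = "")
  invisible(x)
}

#' Extract the sequences of a segment plan
#'
#' @param plan A [plan_segments()] result.
#' @param x The locus sequence the plan was made for.
#' @return A named [Biostrings::DNAStringSet], one record per segment.
#' @export
segment_sequences <- function(plan, x) {
  stopifnot(inherits(plan, "segment_plan"))
  rec <- as_seq_record(x)
  if (nchar(rec$seq) != plan$locus_length) {
    stop("sequence length (", nchar(rec$seq), ") does not match the plan (",
         plan$locus_length, ")", call. = FALSE)
  }
  seqs <- substring(rec$seq, start(plan$segments), end(plan$segments))
  out <- DNAStringSet(seqs)
  names(out) <- names(plan$segments)
  out
}

#' Design a homology-arm insertion construct
#'
#' For transformation-mediated insertion of a payload at a chosen point in
#' a locus, the construct is the payload flanked by `arm_len` bases of
#' homology copied from either side of the insertion point (default 40 bp,
#' the arm length used for PCR-mediated yeast integrations).
#'
#' @param locus The target locus sequence.
#' @param point Insertion point: the number of locus bases preceding the
#'   insertion (i.e. the payload lands between positions `point` and
#'   `point + 1`). Must leave room for both arms.
#' @param payload The payload sequence.
#' @param arm_len Homology arm length in bp.
#' @return An `insertion_design`: list with `payload_id`, `point`,
#'   `left_arm`, `right_arm`, `construct` (character), and `arm_len`.
#' @export
design_insertion <- function(locus, point, payload, arm_len = 40L) {
  lrec <- as_seq_record(locus)
  prec <- as_seq_record(payload)
  L <- nchar(lrec$seq)
  point <- as.integer(point)
  arm_len <- as.integer(arm_len)
  if (point < arm_len || point > L - arm_len) {
    stop("insertion point ", point, " is too close to a locus end for ",
         arm_len, "-bp homology arms", call. = FALSE)
  }
  left_arm <- substring(lrec$seq, point - arm_len + 1L, point)
  right_arm <- substring(lrec$seq, point + 1L, point + arm_len)
  structure(
    list(payload_id = prec$id, point = point,
         left_arm = left_arm, right_arm = right_arm,
         construct = paste0(left_arm, prec$seq, right_arm),
         arm_len = arm_len),
    class = "insertion_design"
  )
}

#' @export
print.insertion_design <- function(x, ...) {
  cat("Insertion of '", x$payload_id, "' after locus position ", x$point,
      " (", x$arm_len, "-bp arms)\n", sep = "")
  invisible(x)
}
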