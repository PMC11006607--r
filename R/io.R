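# I/O for the standard text formats the pipeline touches, plus interval
# plumbing. Everything inside the package speaks GRanges (1-based, closed);
# BED and bedGraph keep their native 0-based half-open convention on disk,
# and the conversion happens here and only here.

#' Read a FASTA file of DNA sequences
#'
#' Reads a (multi-record) FASTA file, uppercases the sequences, and
#' validates that every record has a non-empty single-token identifier and
#' uses only the `A`, `C`, `G`, `T`, `N` alphabet. Identifiers are the first
#' whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readBStringSet(path)
  if (length(raw) == 0L) stop("FASTA file '", path, "' has no records", call. = FALSE)
  ids <- vapply(strsplit(names(raw), "[ \t]+"), `[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("FASTA file '", path, "' has a record with an empty identifier", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("FASTA file '", path, "' has duplicated identifiers", call. = FALSE)
  }
  seqs <- toupper(as.character(raw))
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[[i]])) {
      stop("FASTA record '", ids[[i]], "' has an empty sequence", call. = FALSE)
    }
    check_alphabet(seqs[[i]], ids[[i]])
  }
  out <- DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write sequences to a FASTA file
#'
#' @param x A named [Biostrings::DNAStringSet], or a named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) {
    nm <- names(x)
    x <- DNAStringSet(toupper(x))
    names(x) <- nm
  }
  stopifnot(is(x, "DNAStringSet"))
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("all records must be named before writing FASTA", call. = FALSE)
  }
  writeXStringSet(x, path)
  invisible(path)
}

#' Read a BED file of genomic intervals
#'
#' Accepts BED3..BED6. Coordinates on disk are 0-based half-open and are
#' converted to the package-wide GRanges convention (1-based closed).
#' Column 4 becomes interval names, column 5 a numeric `score`, column 6
#' the strand (missing strand becomes `*`). Malformed lines are reported
#' with their line number.
#'
#' @param path Path to a BED file.
#' @return A [GenomicRanges::GRanges], in file order.
#' @seealso [write_bed()]
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(GRanges())
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3L)) {
    stop("BED line ", idx[which(ncol < 3L)[1L]], " in '", path,
         "' has fewer than 3 columns", call. = FALSE)
  }
  contig <- vapply(fields, `[`, character(1), 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3L)))
  bad <- which(is.na(start0) | is.na(end0) | start0 < 0 | end0 <= start0)
  if (length(bad)) {
    stop("BED line ", idx[bad[1L]], " in '", path,
         "' has invalid coordinates (need 0 <= start < end)", call. = FALSE)
  }
  name <- ifelse(ncol >= 4L, vapply(fields, function(f) f[4L] %||% NA_character_, character(1)), NA_character_)
  score <- ifelse(ncol >= 5L, suppressWarnings(as.numeric(vapply(fields, function(f) f[5L] %||% NA_character_, character(1)))), NA_real_)
  strand <- ifelse(ncol >= 6L, vapply(fields, function(f) f[6L] %||% ".", character(1)), ".")
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GRanges(contig, IRanges(start0 + 1L, end0), strand = strand)
  if (any(!is.na(name))) {
    name[is.na(name)] <- ""
    names(gr) <- name
  }
  if (any(!is.na(score))) mcols(gr)$score <- score
  gr
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a

#' Write genomic intervals as BED
#'
#' Emits BED3 (plus name/score/strand columns when present) in 0-based
#' half-open coordinates.
#'
#' @param gr A [GenomicRanges::GRanges].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  stopifnot(is(gr, "GRanges"))
  df <- data.frame(
    contig = as.character(seqnames(gr)),
    start = start(gr) - 1L,
    end = end(gr),
    stringsAsFactors = FALSE
  )
  has_strand <- any(as.character(strand(gr)) != "*")
  has_score <- "score" %in% names(mcols(gr))
  if (has_strand || has_score || !is.null(names(gr))) {
    df$name <- if (!is.null(names(gr))) names(gr) else "."
    df$score <- if (has_score) mcols(gr)$score else 0
    df$strand <- sub("\\*", ".", as.character(strand(gr)))
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file into a per-base coverage track
#'
#' Materialises the 4-column bedGraph as per-base signal over the supplied
#' contigs: uncovered positions are 0. Overlapping bedGraph lines on the
#' same contig are a format error (a well-formed bedGraph partitions its
#' covered positions).
#'
#' @param path Path to a bedGraph file (0-based half-open intervals).
#' @param contig_lengths Named integer vector of contig lengths.
#' @return A per-base numeric [IRanges::RleList], one element per contig in
#'   `contig_lengths`.
#' @seealso [write_bedgraph()]
#' @export
read_bedgraph <- function(path, contig_lengths) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  stopifnot(is.numeric(contig_lengths), !is.null(names(contig_lengths)))
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(RleList(lapply(contig_lengths, function(n) Rle(0, n)), compress = FALSE))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  if (any(lengths(fields) < 4L)) {
    stop("bedGraph line ", idx[which(lengths(fields) < 4L)[1L]], " in '", path,
         "' has fewer than 4 columns", call. = FALSE)
  }
  contig <- vapply(fields, `[`, character(1), 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3L)))
  value <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 4L)))
  bad <- which(is.na(start0) | is.na(end0) | is.na(value) | start0 < 0 | end0 <= start0)
  if (length(bad)) {
    stop("bedGraph line ", idx[bad[1L]], " in '", path,
         "' is malformed", call. = FALSE)
  }
  if (any(!contig %in% names(contig_lengths))) {
    stop("bedGraph line ", idx[which(!contig %in% names(contig_lengths))[1L]],
         " in '", path, "' refers to an unknown contig", call. = FALSE)
  }
  if (any(value < 0) || any(!is.finite(value))) {
    stop("bedGraph line ", idx[which(value < 0 | !is.finite(value))[1L]],
         " in '", path, "' has a negative or non-finite value", call. = FALSE)
  }
  if (any(end0 > contig_lengths[contig])) {
    stop("bedGraph line ", idx[which(end0 > contig_lengths[contig])[1L]],
         " in '", path, "' extends past the end of its contig", call. = FALSE)
  }
  # overlap check, per contig in file order of coordinates
  for (ct in unique(contig)) {
    i <- contig == ct
    o <- order(start0[i])
    s <- start0[i][o]; e <- end0[i][o]
    if (length(s) > 1L && any(s[-1L] < e[-length(e)])) {
      j <- which(s[-1L] < e[-length(e)])[1L]
      stop("bedGraph '", path, "': overlapping intervals on contig ", ct,
           " near position ", s[j + 1L], call. = FALSE)
    }
  }
  gr <- GRanges(factor(contig, levels = names(contig_lengths)),
                IRanges(start0 + 1L, end0),
                seqlengths = setNames(as.integer(contig_lengths),
                                      names(contig_lengths)))
  cov <- coverage(gr, weight = value)
  cov[names(contig_lengths)]
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal value become one line each; zero runs are omitted.
#'
#' @param track A per-base numeric [IRanges::RleList].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(is(track, "RleList"))
  con <- file(path, "w")
  on.exit(close(con))
  for (ct in names(track)) {
    r <- track[[ct]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- c(1L, ends[-length(ends)] + 1L)
    vals <- S4Vectors::runValue(r)
    keep <- vals != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%s", ct, starts[keep] - 1L, ends[keep],
                         format(vals[keep], trim = TRUE, scientific = FALSE)),
                 con)
    }
  }
  invisible(path)
}

#' Read a tab-delimited read-interval file
#'
#' Columns: contig, start (0-based), end (exclusive), flags (SAM FLAG
#' bitfield). An optional header line starting with `contig` is skipped.
#'
#' @param path Path to the TSV file.
#' @return A [GenomicRanges::GRanges] with an integer `flag` metadata
#'   column.
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  has_header <- length(first) == 1L && startsWith(first, "contig")
  if (has_header && length(readLines(path, n = 2L)) == 1L) {
    return({
      g <- GRanges()
      mcols(g)$flag <- integer(0)
      g
    })
  }
  df <- read.table(path, sep = "\t", header = has_header, comment.char = "#",
                   col.names = c("contig", "start", "end", "flag"),
                   colClasses = c("character", "numeric", "numeric", "character"))
  if (nrow(df) == 0L) return(GRanges(flag = integer()))
  flag <- suppressWarnings(as.integer(df$flag))
  if (anyNA(flag) || any(flag < 0L)) {
    stop("read-interval file '", path, "' has a non-integer or negative flag",
         call. = FALSE)
  }
  if (any(df$start < 0 | df$end <= df$start)) {
    stop("read-interval file '", path, "' has invalid coordinates", call. = FALSE)
  }
  gr <- GRanges(df$contig, IRanges(df$start + 1L, df$end))
  mcols(gr)$flag <- flag
  gr
}

#' Write read intervals as a tab-delimited file
#'
#' @param reads A [GenomicRanges::GRanges] with a `flag` metadata column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path) {
  stopifnot(is(reads, "GRanges"), "flag" %in% names(mcols(reads)))
  df <- data.frame(contig = as.character(seqnames(reads)),
                   start = start(reads) - 1L, end = end(reads),
                   flag = mcols(reads)$flag)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Intervals of one set overlapping another
#'
#' Returns the members of `a` that overlap any member of `b` by at least
#' one base (`bedtools intersect -u` semantics). Strand is ignored.
#'
#' @param a,b [GenomicRanges::GRanges] objects.
#' @return The overlapping subset of `a`, in the order of `a`.
#' @export
intersect_peaks <- function(a, b) {
  stopifnot(is(a, "GRanges"), is(b, "GRanges"))
  suppressWarnings(subsetByOverlaps(a, b, ignore.strand = TRUE))
}

#' Parse a 1-based inclusive region string
#'
#' Converts browser-style coordinates such as `"chrX:134429208-134529874"`
#' (1-based, inclusive on both ends) into a GRanges interval. This is the
#' only place the 1-based inclusive convention enters the package.
#'
#' @param x Region string `contig:start-end`.
#' @return A width-`end - start + 1` [GenomicRanges::GRanges].
#' @examples
#' width(parse_region_1based("chrX:134429208-134529874"))  # 100667
#' @export
parse_region_1based <- function(x) {
  m <- regmatches(x, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", x))[[1L]]
  if (length(m) != 4L) stop("cannot parse region string '", x, "'", call. = FALSE)
  s <- as.numeric(gsub(",", "", m[3L]))
  e <- as.numeric(gsub(",", "", m[4L]))
  if (e < s) stop("region '", x, "' has end < start", call. = FALSE)
  GRanges(m[2L], IRanges(s, e))
}
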