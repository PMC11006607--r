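# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state (the global .Random.seed is saved and restored).
with_seed <- function(seed, expr) {
  seed <- as.integer(seed)
  stopifnot(length(seed) == 1L, !is.na(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Normalise the many ways a single sequence can arrive (character scalar,
# named character, DNAString, DNAStringSet of length 1) into a plain
# list(id=, seq=) with an uppercase sequence string.
as_seq_record <- function(x, id = NULL) {
  if (is(x, "DNAStringSet") || is(x, "BStringSet")) {
    if (length(x) != 1L) {
      stop("expected a single sequence, got ", length(x), call. = FALSE)
    }
    seq <- as.character(x[[1L]])
    if (is.null(id)) id <- names(x)
  } else if (is(x, "DNAString") || is(x, "BString")) {
    seq <- as.character(x)
  } else if (is.character(x) && length(x) == 1L) {
    seq <- x
    if (is.null(id) && !is.null(names(x))) id <- names(x)
  } else if (is.list(x) && !is.null(x$seq)) {
    seq <- x$seq
    if (is.null(id)) id <- x$id
  } else {
    stop("cannot interpret input as a DNA sequence record", call. = FALSE)
  }
  if (is.null(id) || !nzchar(id)) id <- "seq"
  seq <- unname(toupper(seq))
  if (!nzchar(seq)) stop("sequence '", id, "' is empty", call. = FALSE)
  list(id = as.character(id), seq = seq)
}

# Validate that a sequence string uses only the given alphabet; on failure
# name the first offending character.
check_alphabet <- function(seq, id, alphabet = c("A", "C", "G", "T", "N")) {
  bad <- regmatches(seq, regexpr(sprintf("[^%s]", paste(alphabet, collapse = "")), seq))
  if (length(bad) && nzchar(bad)) {
    stop(
      "sequence '", id, "' contains illegal character '", bad,
      "' (allowed: ", paste(alphabet, collapse = ""), ")",
      call. = FALSE
    )
  }
  invisible(TRUE)
}

seq_record_as_dnass <- function(rec) {
  out <- DNAStringSet(rec$seq)
  names(out) <- rec$id
  out
}

# Lower median: for even n the smaller of the two central order statistics.
# Deterministic, used for read-count summaries across windows.
lower_median <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sort(x)[floor((n + 1) / 2)]
}

# Named contig lengths from an RleList coverage track.
track_lengths <- function(track) {
  stopifnot(is(track, "RleList"))
  setNames(vapply(track, length, integer(1)), names(track))
}
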