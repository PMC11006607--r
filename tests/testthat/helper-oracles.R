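# Independent oracles and shared fixtures for the test suite. The oracles
# deliberately use naive implementations (loops, recursion, exhaustive
# enumeration) so they share no code with the functions they check.

library(GenomicRanges)
library(Biostrings)

# -- random sequences ---------------------------------------------------

rand_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# -- CpG scrubbing: exhaustive path enumeration -------------------------

# All strings reachable from `s` in one scan, enumerating every
# combination of per-occurrence coin flips under the same pass semantics
# as scrub_cpg (all occurrences of one scan handled right-to-left).
scrub_step_outcomes <- function(s) {
  bases <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(bases)
  hits <- if (n >= 2) which(bases[-n] == "C" & bases[-1] == "G") else integer(0)
  if (length(hits) == 0) return(character(0))
  k <- length(hits)
  outs <- character(0)
  for (mask in 0:(2^k - 1)) {
    flips <- bitwAnd(mask, 2^(seq_len(k) - 1)) > 0
    drops <- hits + as.integer(flips)
    outs <- c(outs, paste(bases[-drops], collapse = ""))
  }
  unique(outs)
}

# The full reachable set of CG-free end states.
enumerate_scrub <- function(s) {
  if (!grepl("CG", s, fixed = TRUE)) return(s)
  unique(unlist(lapply(scrub_step_outcomes(s), enumerate_scrub)))
}

# -- composition: brute-force counters ----------------------------------

brute_dinuc_count <- function(s) {
  all_dinucs <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                paste0))
  counts <- setNames(rep(0L, 16L), all_dinucs)
  b <- strsplit(s, "", fixed = TRUE)[[1]]
  for (i in seq_len(length(b) - 1L)) {
    d <- paste0(b[i], b[i + 1L])
    if (d %in% all_dinucs) counts[d] <- counts[d] + 1L
  }
  counts
}

# -- coverage: per-base loops -------------------------------------------

brute_mean_depth <- function(vec, start, end) {
  tot <- 0
  for (i in start:end) tot <- tot + vec[i]
  tot / (end - start + 1)
}

brute_count_reads <- function(reads_df, regions_df, mask = 2308L) {
  out <- integer(nrow(regions_df))
  for (j in seq_len(nrow(regions_df))) {
    n <- 0L
    for (i in seq_len(nrow(reads_df))) {
      if (bitwAnd(reads_df$flag[i], mask) != 0L) next
      if (reads_df$contig[i] != regions_df$contig[j]) next
      if (reads_df$start[i] <= regions_df$end[j] &&
          reads_df$end[i] >= regions_df$start[j]) {
        n <- n + 1L
      }
    }
    out[j] <- n
  }
  out
}

# -- shared end-to-end fixture (memoised across test files) -------------

fixture_env <- new.env(parent = emptyenv())

get_fixture <- function(seed = 101L) {
  key <- paste0("s", seed)
  if (!exists(key, envir = fixture_env, inherits = FALSE)) {
    dir <- file.path(tempdir(), paste0("lf_fixture_", seed))
    assign(key, list(fx = make_default_state_fixture(seed, dir = dir),
                     dir = dir),
           envir = fixture_env)
  }
  get(key, envir = fixture_env, inherits = FALSE)
}

# -- small GRanges builders ---------------------------------------------

gr <- function(contig, start, end, strand = "*", ...) {
  GRanges(contig, IRanges(start, end), strand = strand, ...)
}
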