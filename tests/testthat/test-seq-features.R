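# Composition statistics: dinucleotide profiles, CpG observed/expected,
# GC tracks, CpG islands, IUPAC scanning, and the reversal identity.

test_that("dinuc_profile counts overlapping pairs and handles N", {
  p <- dinuc_profile("AAA")
  expect_equal(p$dinuc[["AA"]], 3L - 1L)
  expect_equal(p$length, 3L)

  q <- dinuc_profile("ACGT")
  expect_equal(unname(q$dinuc[c("AC", "CG", "GT")]), c(1L, 1L, 1L))
  expect_equal(sum(q$dinuc), 3L)

  # pairs touching an N are skipped; N counted in mono, not in GC denominator
  r <- dinuc_profile("ACNGT")
  expect_equal(sum(r$dinuc), 2L)
  expect_equal(r$mono[["N"]], 1L)
  expect_equal(r$gc_fraction, 2 / 4)
})

test_that("dinucleotide counts agree with a brute-force pairwise counter", {
  set.seed(21)
  for (i in 1:5) {
    s <- rand_seq(2000, gc = runif(1, 0.3, 0.7))
    p <- dinuc_profile(s)
    expect_equal(unclass(p$dinuc)[names(brute_dinuc_count(s))],
                 brute_dinuc_count(s) + 0)
    expect_equal(sum(p$dinuc), nchar(s) - 1L)
    expect_equal(sum(p$mono), nchar(s))
  }
})

test_that("reversal identity: profile of reversed sequence equals prediction", {
  set.seed(31)
  for (i in 1:25) {
    s <- rand_seq(sample(200:2000, 1), gc = runif(1, 0.25, 0.65))
    direct <- dinuc_profile(reverse_sequence(s))
    predicted <- predict_reversed_profile(dinuc_profile(s))
    expect_equal(direct$dinuc, predicted$dinuc)
    expect_equal(direct$mono, predicted$mono)
    expect_equal(direct$gc_fraction, predicted$gc_fraction)
  }
  # involution at the profile level
  p <- dinuc_profile(rand_seq(500))
  expect_equal(predict_reversed_profile(predict_reversed_profile(p))$dinuc,
               p$dinuc)
})

test_that("cpg_stats implements the (nC x nG)/L expectation", {
  p <- dinuc_profile("ACGT")
  cs <- cpg_stats(p)
  expect_equal(cs$observed, 1)
  expect_equal(cs$expected, 1 * 1 / 4)
  expect_equal(cs$ratio, 4)

  a <- cpg_stats(dinuc_profile("AAAA"))
  expect_equal(a$observed, 0)
  expect_equal(a$expected, 0)
  expect_equal(a$ratio, 0)
})

test_that("expected CpG is invariant under reversal", {
  set.seed(41)
  for (i in 1:10) {
    p <- dinuc_profile(rand_seq(1500, gc = runif(1, 0.3, 0.6)))
    expect_equal(cpg_stats(predict_reversed_profile(p))$expected,
                 cpg_stats(p)$expected)
  }
})

test_that("scrubbed sequences have zero observed CpG and ratio 0", {
  set.seed(51)
  for (i in 1:5) {
    res <- scrub_cpg(rand_seq(800, gc = 0.5), seed = i)
    cs <- cpg_stats(dinuc_profile(res$scrubbed))
    expect_equal(cs$observed, 0)
    expect_equal(cs$ratio, 0)
  }
})

test_that("oe_fold_enrichment divides ratios with display rounding", {
  a <- new_cpg_stats(4499, 4291)
  b <- new_cpg_stats(1202, 4291)
  expect_equal(oe_fold_enrichment(a, b), 1.05 / 0.28)
  expect_equal(oe_fold_enrichment(a, b, ratio_digits = NULL),
               (4499 / 4291) / (1202 / 4291))
  expect_equal(oe_fold_enrichment(a, a), 1)
  zero <- new_cpg_stats(0, 100)
  expect_equal(oe_fold_enrichment(zero, b), 0)
  expect_error(oe_fold_enrichment(a, zero), "zero reference")
})

test_that("gc_track computes windowed GC fractions", {
  g <- gc_track(paste(rep("G", 50), collapse = ""), window = 10, step = 10)
  expect_true(all(mcols(g)$gc == 1))

  g2 <- gc_track("AATTGGCC", window = 4, step = 4)
  expect_equal(mcols(g2)$gc, c(0, 1))

  s <- rand_seq(10000, gc = 0.45)
  g3 <- gc_track(s, window = 500, step = 500)
  global <- dinuc_profile(s)$gc_fraction
  expect_lt(abs(mean(mcols(g3)$gc) - global), 0.02)
  expect_error(gc_track("ACGT", window = 10), "exceeds")
})

test_that("find_cpg_islands recovers an embedded CpG-rich repeat", {
  set.seed(61)
  at <- function(n) paste(sample(c("A", "T"), n, replace = TRUE), collapse = "")
  island <- paste(rep("CG", 150), collapse = "")  # 300 bp
  s <- paste0(at(900), island, at(800))
  isl <- find_cpg_islands(s)
  expect_equal(length(isl), 1L)
  # the called island must contain the repeat
  expect_lte(start(isl), 901L)
  expect_gte(end(isl), 1200L)
  expect_gte(mcols(isl)$mean_gc, 0.5)
  expect_gte(mcols(isl)$mean_oe, 0.6)

  # independent window-by-window scorer over the island span
  b <- strsplit(s, "")[[1]]
  for (w0 in c(901, 1000, 1101)) {
    win <- b[w0:(w0 + 99)]
    nC <- sum(win == "C"); nG <- sum(win == "G")
    obs <- sum(win[-100] == "C" & win[-1] == "G")
    expect_gte((nC + nG) / 100, 0.5)
    expect_gte(obs / (nC * nG / 100), 0.6)
  }

  expect_length(find_cpg_islands(paste(rep("A", 2000), collapse = "")), 0L)

  # CG-rich run shorter than min_len is discarded
  short <- paste0(at(900), paste(rep("CG", 20), collapse = ""), at(900))
  expect_length(find_cpg_islands(short), 0L)
})

test_that("scrubbed sequences yield no CpG islands at the default O/E floor", {
  res <- scrub_cpg(rand_seq(3000, gc = 0.55), seed = 5)
  expect_length(find_cpg_islands(res$scrubbed), 0L)
})

test_that("iupac_scan matches degenerate patterns on both strands", {
  hits <- iupac_scan("AACTCAGACTCAA", "CTCNGNCTC")
  expect_equal(start(hits), 3L)
  expect_equal(end(hits), 11L)

  n_all <- iupac_scan("ACGTACGT", "N")
  expect_equal(length(n_all), 8L)

  # reverse-complement matches reported on the minus strand
  both <- iupac_scan("AAGGGCCAAA", "GGCC", both_strands = TRUE)
  expect_equal(length(both), 2L)
  expect_setequal(as.character(strand(both)), c("+", "-"))

  expect_error(iupac_scan("ACGT", "CXG"), "IUPAC")
})

test_that("iupac_scan agrees with a naive regex enumeration", {
  set.seed(71)
  iupac_regex <- c(A = "A", C = "C", G = "G", T = "T", N = "[ACGT]",
                   R = "[AG]", Y = "[CT]", W = "[AT]", S = "[CG]")
  for (i in 1:5) {
    s <- rand_seq(500)
    pat <- paste(sample(names(iupac_regex), 6, replace = TRUE), collapse = "")
    rx <- paste(iupac_regex[strsplit(pat, "")[[1]]], collapse = "")
    naive <- integer(0)
    for (p in 1:(nchar(s) - 5)) {
      if (grepl(paste0("^", rx), substring(s, p, p + 5))) naive <- c(naive, p)
    }
    got <- iupac_scan(s, pat)
    expect_equal(start(got), naive)
  }
})
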