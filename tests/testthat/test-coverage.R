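# Window/coverage statistics: windowing, depth, copy number, RPGC,
# relative coverage, peak density, geneless windows, read counting,
# binned correlation.

track1 <- function(v, name = "c1") {
  tr <- RleList(list(Rle(v)), compress = FALSE)
  names(tr) <- name
  tr
}

test_that("make_windows produces the sliding-window grid", {
  w <- make_windows(c(cA = 300000L), size = 100000L, step = 10000L)
  expect_equal(length(w), 21L)  # floor((300-100)/10)+1
  expect_true(all(width(w) == 100000L))

  expect_length(make_windows(c(cA = 50000L), size = 100000L), 0L)
  expect_equal(length(make_windows(c(cA = 50000L), size = 100000L,
                                   keep_partial = TRUE)), 5L)

  tiles <- make_windows(c(cA = 1000L), size = 100L, step = 100L)
  expect_equal(length(tiles), 10L)
  expect_equal(sum(width(tiles)), 1000L)  # non-overlapping tiling
})

test_that("mean_depth equals the naive per-base loop", {
  expect_equal(mean_depth(track1(rep(3, 10)), gr("c1", 2, 6)), 3)
  expect_equal(mean_depth(track1(c(0, 0, 6, 6)), gr("c1", 1, 4)), 3)
  set.seed(9)
  v <- rpois(500, 4) * 0.5
  tr <- track1(v)
  for (i in 1:10) {
    s <- sample(400, 1); e <- s + sample(90, 1)
    expect_equal(mean_depth(tr, gr("c1", s, e)), brute_mean_depth(v, s, e))
  }
  expect_error(mean_depth(tr, gr("c1", 490, 600)), "outside")
})

test_that("estimate_copy_number divides locus depth by the genome mean", {
  tr <- RleList(list(Rle(rep(30, 1000)), Rle(rep(60, 200))), compress = FALSE)
  names(tr) <- c("g1", "locus")
  cn <- estimate_copy_number(tr, gr("locus", 1, 200))
  expect_equal(cn$estimate, 2)
  expect_equal(cn$call, 2L)

  # locus = whole (single-contig) genome -> 1.0 against itself is
  # impossible; against an identical second contig it is 1.0
  tr2 <- RleList(list(Rle(rep(30, 1000)), Rle(rep(30, 1000))), compress = FALSE)
  names(tr2) <- c("g1", "g2")
  expect_equal(estimate_copy_number(tr2, gr("g2", 1, 1000))$estimate, 1)

  # excluded contigs do not pollute the genome mean
  tr3 <- RleList(list(Rle(rep(30, 1000)), Rle(rep(3000, 100)),
                      Rle(rep(60, 200))), compress = FALSE)
  names(tr3) <- c("g1", "chrM", "locus")
  expect_equal(estimate_copy_number(tr3, gr("locus", 1, 200))$estimate, 2)
})

test_that("rpgc_normalize rescales to 1x over the effective genome size", {
  tr <- track1(rep(5, 1000))
  out <- rpgc_normalize(tr, effective_genome_size = 1000)
  expect_true(all(as.numeric(out[["c1"]]) == 1))

  # scale invariance
  set.seed(13)
  v <- rpois(2000, 7)
  a <- rpgc_normalize(track1(v), 5000)
  b <- rpgc_normalize(track1(2 * v), 5000)
  expect_equal(as.numeric(a[["c1"]]), as.numeric(b[["c1"]]))
  # post-normalization total equals the effective size
  expect_equal(sum(as.numeric(a[["c1"]])), 5000)
})

test_that("relative_coverage corrects for copy number and is scale invariant", {
  tr <- RleList(list(Rle(rep(5, 2000)), Rle(rep(10, 500))), compress = FALSE)
  names(tr) <- c("g1", "locus")
  w <- make_windows(c(g1 = 2000L), size = 500L, step = 500L)
  locus <- gr("locus", 1, 500)
  expect_equal(relative_coverage(tr, locus, w, 1)$relative, 2)
  expect_equal(relative_coverage(tr, locus, w, 2)$relative, 1)

  set.seed(17)
  tr2 <- RleList(list(Rle(rpois(2000, 5) + 1), Rle(rpois(500, 10) + 1)),
                 compress = FALSE)
  names(tr2) <- c("g1", "locus")
  r1 <- relative_coverage(tr2, locus, w, 2)$relative
  tr2s <- S4Vectors::endoapply(tr2, function(r) r * 7.5)
  expect_equal(relative_coverage(tr2s, locus, w, 2)$relative, r1)
  expect_error(relative_coverage(tr2, locus, w[0], 1), "empty")
})

test_that("relative coverage recovers a planted per-copy enrichment", {
  # episome at 4 copies with 2x per-copy signal: relative ~ 2
  set.seed(23)
  tr <- RleList(list(Rle(rpois(200000, 10)), Rle(rpois(50000, 10 * 4 * 2))),
                compress = FALSE)
  names(tr) <- c("g1", "epi")
  w <- make_windows(c(g1 = 200000L), size = 20000L, step = 20000L)
  rel <- relative_coverage(tr, gr("epi", 1, 50000), w, copy_number = 4)
  expect_lt(abs(rel$relative - 2), 0.1)
})

test_that("peak_density scales midpoint counts per 100 kb", {
  pk_starts <- c(1000, 20000, 40000, 60000, 90000)
  pk <- gr("c1", pk_starts, pk_starts + 50)
  region <- gr("c1", 1, 100000)
  expect_equal(peak_density(pk, region = region), 5)
  expect_equal(peak_density(gr("c1", pk_starts[1:3], pk_starts[1:3] + 50),
                            region = gr("c1", 1, 50000)), 6)

  # a peak whose midpoint is outside the region is not counted
  edge <- gr("c1", 99990, 100200)  # midpoint 100095
  expect_equal(peak_density(edge, region = region), 0)
  expect_equal(peak_density(edge, region = region, assign = "any"), 1)

  # window form: mean of per-window densities (midpoints 3 vs 2)
  w <- make_windows(c(c1 = 100000L), size = 50000L, step = 50000L)
  expect_equal(peak_density(pk, windows = w), mean(c(3, 2) / 50000 * 1e5))
})

test_that("geneless_windows drops any window touching an exclusion", {
  w <- make_windows(c(c1 = 100000L), size = 10000L, step = 10000L)
  expect_equal(length(geneless_windows(w, GRanges())), 10L)
  expect_length(geneless_windows(w, gr("c1", 1, 100000)), 0L)

  genes <- gr("c1", c(5000, 35000), c(6000, 36000))
  left <- geneless_windows(w, genes)
  expect_equal(length(left), 8L)
  expect_false(any(overlapsAny(left, genes)))
  # order of exclusions is irrelevant
  expect_equal(start(geneless_windows(w, rev(genes))), start(left))
})

test_that("count_reads_in_regions applies the 2308 flag mask", {
  rd <- gr("c1", c(100, 200, 300, 400), c(175, 275, 375, 475))
  mcols(rd)$flag <- c(0L, 256L, 1024L, 2048L)
  rc <- count_reads_in_regions(rd, gr("c1", 1, 1000))
  expect_equal(rc$counts, 2L)  # flag 0 and duplicate counted; 256/2048 not

  unmapped <- rd
  mcols(unmapped)$flag <- c(4L, 4L, 4L, 4L)
  expect_equal(count_reads_in_regions(unmapped, gr("c1", 1, 1000))$counts, 0L)
})

test_that("count_reads_in_regions equals the brute-force double loop", {
  set.seed(29)
  reads_df <- data.frame(
    contig = sample(c("c1", "c2"), 800, replace = TRUE),
    start = sample(10000, 800, replace = TRUE)
  )
  reads_df$end <- reads_df$start + 74L
  reads_df$flag <- sample(c(0L, 0L, 0L, 256L, 1024L, 2048L, 4L), 800,
                          replace = TRUE)
  rd <- GRanges(reads_df$contig, IRanges(reads_df$start, reads_df$end))
  mcols(rd)$flag <- reads_df$flag
  regions_df <- data.frame(
    contig = rep(c("c1", "c2"), each = 20),
    start = rep(seq(1, 9501, by = 500), 2)
  )
  regions_df$end <- regions_df$start + 499L
  regions <- GRanges(regions_df$contig, IRanges(regions_df$start, regions_df$end))
  got <- count_reads_in_regions(rd, regions)
  expect_equal(got$counts, brute_count_reads(reads_df, regions_df))
  expect_equal(got$median, sort(got$counts)[floor((length(got$counts) + 1) / 2)])
})

test_that("geneless-window read counts land in the planted Poisson regime", {
  set.seed(31)
  n_win <- 1001L
  starts <- seq(1, by = 100000, length.out = n_win)
  regions <- GRanges("c1", IRanges(starts, width = 100000L))
  n_reads <- rpois(1, 20 * n_win)
  rd <- GRanges("c1", IRanges(sample(starts[n_win] + 99999L - 75L, n_reads,
                                     replace = TRUE), width = 75L))
  mcols(rd)$flag <- 0L
  rc <- count_reads_in_regions(rd, regions)
  expect_gte(rc$median, 15)
  expect_lte(rc$median, 25)
})

test_that("binned_correlation matches expectations on known inputs", {
  set.seed(37)
  v <- rpois(50000, 8)
  a <- track1(v)
  expect_equal(binned_correlation(a, a, bin = 100), 1)

  b <- track1(2 * v)
  expect_gte(binned_correlation(a, b, bin = 100), 0.99)

  # independent tracks decorrelate
  x <- track1(rpois(1000000, 5))
  y <- track1(rpois(1000000, 5))
  expect_lt(abs(binned_correlation(x, y, bin = 100)), 0.05)

  expect_error(binned_correlation(track1(c(1, 2)), track1(c(1, 2)), bin = 1),
               "fewer than 3")
  expect_error(binned_correlation(a, track1(v, name = "other"), bin = 100),
               "same contigs")
})
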