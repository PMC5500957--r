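test_that("segment boundaries become breakpoints with correct coordinates", {
  x <- toy_profiles(matrix(c(0, 0, 0.7, 0.7, 0), ncol = 1))
  bpm <- detect_breakpoints(x)
  bp <- bpm$breakpoints
  expect_equal(bp$feature_index, c(3L, 5L))
  expect_equal(bp$delta_log2, c(0.7, -0.7))
  # uncertainty interval spans from just after the upstream feature to the
  # downstream feature's start
  expect_equal(bp$interval_start, c(2060L, 4060L))
  expect_equal(bp$interval_end, c(3000L, 5000L))
  expect_equal(unname(bpm$per_sample_counts), 2)
  expect_equal(unname(which(bpm$indicator[, 1] == 1L)), c(3L, 5L))
})

test_that("constant profiles yield no breakpoints", {
  bpm <- detect_breakpoints(toy_profiles(matrix(c(0.3, 0.3, 0.3), ncol = 1)))
  expect_equal(nrow(bpm$breakpoints), 0L)
  expect_equal(sum(bpm$indicator), 0L)
})

test_that("per-chromosome breakpoint count equals runs minus one (RLE oracle)", {
  set.seed(42)
  chrom <- rep(c("1", "2", "3"), times = c(40, 35, 25))
  for (rep_i in 1:20) {
    seg <- vapply(1:4, function(s) {
      vals <- unlist(lapply(split(seq_along(chrom), chrom), function(idx) {
        lens <- diff(c(0, sort(sample(length(idx) - 1,
                                      sample(0:5, 1))), length(idx)))
        rep(round(stats::rnorm(length(lens), 0, 0.5), 3), lens)
      }), use.names = FALSE)
      vals
    }, numeric(length(chrom)))
    bpm <- detect_breakpoints(toy_profiles(seg, chrom = chrom))
    for (s in 1:4) {
      expected <- sum(vapply(split(seg[, s], chrom),
                             function(v) length(rle(v)$lengths) - 1L,
                             integer(1)))
      expect_equal(unname(bpm$per_sample_counts[s]), expected)
    }
  }
})

test_that("breakpoints never sit on a chromosome's first feature", {
  set.seed(7)
  chrom <- rep(c("1", "2"), each = 30)
  seg <- matrix(sample(c(0, 0.4), 60 * 3, replace = TRUE), ncol = 3)
  bpm <- detect_breakpoints(toy_profiles(seg, chrom = chrom))
  first_idx <- which(c(TRUE, chrom[-1] != chrom[-60]))
  expect_false(any(bpm$breakpoints$feature_index %in% first_idx))
})

## one sample, four chromosomes, each carrying exactly one breakpoint with
## flanking call pairs (0,0), (0,1), (1,1), (-1,0)
flank_fixture <- function() {
  chrom <- rep(c("1", "2", "3", "4"), each = 2)
  seg <- matrix(c(0, 0.05,  0, 0.4,  0.3, 0.6,  -0.4, 0), ncol = 1)
  calls <- matrix(c(0L, 0L,  0L, 1L,  1L, 1L,  -1L, 0L), ncol = 1)
  detect_breakpoints(toy_profiles(seg, chrom = chrom, calls = calls))
}

test_that("deviation filter keeps only shifts exceeding the threshold", {
  x <- toy_profiles(matrix(c(0, 0.7, 0.4), ncol = 1))  # deltas +0.7, -0.3
  bpm <- detect_breakpoints(x)
  kept <- filter_breakpoints(bpm, "deviation", threshold = 0.5)
  expect_equal(kept$breakpoints$delta_log2, 0.7)
  # strict inequality: a shift exactly at the threshold is dropped
  at <- filter_breakpoints(bpm, "deviation", threshold = 0.7)
  expect_equal(nrow(at$breakpoints), 0L)
})

test_that("cna_associated drops only neutral-neutral flanked breakpoints", {
  bpm <- flank_fixture()
  expect_equal(nrow(bpm$breakpoints), 4L)
  kept <- filter_breakpoints(bpm, "cna_associated")
  flank <- paste(kept$breakpoints$call_up, kept$breakpoints$call_down)
  expect_setequal(flank, c("0 1", "1 1", "-1 0"))
})

test_that("cna_call_change keeps only dissimilar flanking call states", {
  kept <- filter_breakpoints(flank_fixture(), "cna_call_change")
  flank <- paste(kept$breakpoints$call_up, kept$breakpoints$call_down)
  expect_setequal(flank, c("0 1", "-1 0"))
})

test_that("call-based filters demand calls and modes are validated", {
  bpm <- detect_breakpoints(toy_profiles(matrix(c(0, 0.5), ncol = 1)))
  expect_error(filter_breakpoints(bpm, "cna_associated"), "calls")
  expect_error(filter_breakpoints(bpm, "cna_call_change"), "calls")
  expect_error(filter_breakpoints(bpm, "nonsense"))
  expect_error(filter_breakpoints(flank_fixture(), "deviation",
                                  threshold = -1), "positive")
})

test_that("filtering only removes breakpoints and call-change is nested in cna-associated", {
  set.seed(11)
  for (rep_i in 1:10) {
    n <- 40
    calls <- matrix(sample(-1:1, n * 2, replace = TRUE), ncol = 2)
    seg <- calls * 0.4 + matrix(round(stats::runif(n * 2, 0, 0.05), 4),
                                ncol = 2)
    bpm <- detect_breakpoints(toy_profiles(seg, calls = calls))
    a <- filter_breakpoints(bpm, "cna_associated")
    cc <- filter_breakpoints(bpm, "cna_call_change")
    dv <- filter_breakpoints(bpm, "deviation", threshold = 0.3)
    expect_true(all(a$indicator <= bpm$indicator))
    expect_true(all(dv$indicator <= bpm$indicator))
    expect_true(all(cc$indicator <= a$indicator))
    expect_equal(unname(a$per_sample_counts), unname(colSums(a$indicator)))
  }
})
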