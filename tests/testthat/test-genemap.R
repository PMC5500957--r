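test_that("feature association counts overlapping features only", {
  grid <- feature_grid(c("a", "b", "c"), c("1", "1", "1"),
                       c(100L, 200L, 300L), c(120L, 220L, 320L))
  genes <- gene_annotation("G1", "1", 150L, 250L)
  expect_equal(unname(associate_features_to_genes(grid, genes)), 1L)
  off <- gene_annotation("G2", "7", 150L, 250L)
  expect_equal(unname(associate_features_to_genes(grid, off)), 0L)
})

test_that("feature association equals a brute-force all-pairs scan", {
  set.seed(3)
  for (rep_i in 1:10) {
    n <- 60
    chrom <- sample(c("1", "2", "X"), n, replace = TRUE)
    start <- integer(n)
    for (cc in unique(chrom)) {     # disjoint features within chromosome
      k <- sum(chrom == cc)
      start[chrom == cc] <- cumsum(sample(200:2000, k))
    }
    grid <- feature_grid(sprintf("f%02d", 1:n), chrom, start, start + 99L)
    gs <- sample(1:50000, 30)
    genes <- gene_annotation(sprintf("g%02d", 1:30),
                             sample(c("1", "2", "X", "9"), 30, replace = TRUE),
                             gs, gs + sample(100:20000, 30))
    got <- associate_features_to_genes(grid, genes)
    want <- brute_overlap_count(genes$chromosome, genes$start, genes$end,
                                grid$chromosome, grid$start, grid$end)
    expect_equal(unname(got), want)
  }
})

test_that("a breakpoint interval hits exactly the genes it overlaps", {
  # interval [1:121-200]: the gap after a feature ending at 120 up to the
  # downstream feature starting at 200
  grid <- feature_grid(c("f1", "f2"), c("1", "1"), c(100L, 200L),
                       c(120L, 260L))
  seg <- matrix(c(0, 0.5), ncol = 1)
  bpm <- detect_breakpoints(cnp_set(grid, seg, sample_ids = "s1"))
  expect_equal(bpm$breakpoints$interval_start, 121L)
  expect_equal(bpm$breakpoints$interval_end, 200L)
  genes <- gene_annotation(c("A", "B", "C"), rep("1", 3),
                           c(50L, 150L, 500L), c(110L, 400L, 600L))
  gbm <- map_breakpoints_to_genes(bpm, genes)
  expect_equal(unname(gbm$indicator[, 1]), c(0L, 1L, 0L))
})

test_that("multiple breakpoints of one sample in one gene count once", {
  # two boundaries at features 2 and 4; one long gene spans everything
  x <- profiles_from_boundaries(5, list(c(2L, 4L)))
  bpm <- detect_breakpoints(x)
  expect_equal(unname(bpm$per_sample_counts), 2)
  gene <- gene_annotation("BIG", "1", 1L, 10000L)
  gbm <- map_breakpoints_to_genes(bpm, gene)
  expect_identical(unname(gbm$indicator[1, 1]), 1L)
})

test_that("gene mapping equals a brute-force gene-by-breakpoint scan", {
  set.seed(19)
  for (rep_i in 1:8) {
    chrom <- rep(c("1", "2"), each = 50)
    seg <- matrix(sample(c(0, 0.5, -0.5), 100 * 5, replace = TRUE,
                         prob = c(0.7, 0.15, 0.15)), ncol = 5)
    bpm <- detect_breakpoints(toy_profiles(seg, chrom = chrom))
    gs <- sample(1:60000, 25)
    genes <- gene_annotation(sprintf("g%02d", 1:25),
                             sample(c("1", "2"), 25, replace = TRUE),
                             gs, gs + sample(500:30000, 25))
    gbm <- map_breakpoints_to_genes(bpm, genes)
    bp <- bpm$breakpoints
    want <- matrix(0L, 25, 5, dimnames = dimnames(gbm$indicator))
    for (g in 1:25) for (b in seq_len(nrow(bp))) {
      if (genes$chromosome[g] == bp$chromosome[b] &&
          max(genes$start[g], bp$interval_start[b]) <=
            min(genes$end[g], bp$interval_end[b]))
        want[g, match(bp$sample_id[b], bpm$sample_ids)] <- 1L
    }
    expect_identical(gbm$indicator, want)
  }
})

test_that("feature-position mapping is at least as strict as interval mapping", {
  set.seed(23)
  seg <- matrix(sample(c(0, 0.5), 80, replace = TRUE), ncol = 2)
  bpm <- detect_breakpoints(toy_profiles(seg))
  gs <- sample(1:40000, 20)
  genes <- gene_annotation(sprintf("g%02d", 1:20), rep("1", 20),
                           gs, gs + sample(200:5000, 20))
  by_interval <- map_breakpoints_to_genes(bpm, genes, mode = "interval")
  by_feature <- map_breakpoints_to_genes(bpm, genes, mode = "feature")
  expect_true(all(by_feature$indicator <= by_interval$indicator))
})

test_that("mapping is monotone under breakpoint filtering", {
  set.seed(31)
  calls <- matrix(sample(-1:1, 60 * 3, replace = TRUE), ncol = 3)
  seg <- calls * 0.45
  bpm <- detect_breakpoints(toy_profiles(seg, calls = calls))
  gs <- sample(1:40000, 15)
  genes <- gene_annotation(sprintf("g%02d", 1:15), rep("1", 15),
                           gs, gs + sample(500:8000, 15))
  full <- map_breakpoints_to_genes(bpm, genes)
  sub <- map_breakpoints_to_genes(filter_breakpoints(bpm, "cna_call_change"),
                                  genes)
  expect_true(all(sub$indicator <= full$indicator))
})

test_that("an empty gene list is rejected", {
  bpm <- detect_breakpoints(toy_profiles(matrix(c(0, 0.5), ncol = 1)))
  expect_error(map_breakpoints_to_genes(bpm, data.frame()), "non-empty")
})

test_that("per-gene summary reports covariates and hit counts", {
  x <- profiles_from_boundaries(6, list(3L, c(3L, 5L)))
  bpm <- detect_breakpoints(x)
  genes <- gene_annotation(c("G1", "G2"), c("1", "1"),
                           c(2500L, 4500L), c(3500L, 4800L))
  s <- summary(map_breakpoints_to_genes(bpm, genes))
  expect_equal(s$samples_hit, c(2L, 1L))
  expect_equal(s$gene_length, c(1001L, 301L))
})
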