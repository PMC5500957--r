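test_that("the feature-level null uses p_s = N_s / N", {
  set.seed(1)
  boundaries <- list(sort(sample(2:100, 5)), sort(sample(2:100, 10)))
  x <- profiles_from_boundaries(100, boundaries)
  res <- feature_level_test(detect_breakpoints(x))
  expect_equal(unname(attr(res, "null")$probs), c(0.05, 0.10))
  # features without any breakpoint get p-value exactly 1
  expect_true(all(res$p_value[res$observed == 0L] == 1))
  # the 'eligible' convention removes the one chromosome-first feature
  res_e <- feature_level_test(detect_breakpoints(x), n_mode = "eligible")
  expect_equal(unname(attr(res_e, "null")$probs), c(5, 10) / 99)
})

test_that("feature-level p-values agree with a Monte-Carlo null", {
  set.seed(77)
  x <- profiles_from_boundaries(10, list(2L, c(3L, 7L), c(3L, 9L), 5L))
  res <- feature_level_test(detect_breakpoints(x))
  probs <- attr(res, "null")$probs
  draws <- 1e6
  t_sim <- rowSums(vapply(probs, function(p) stats::rbinom(draws, 1L, p),
                          numeric(draws)))
  for (t_obs in sort(unique(res$observed[res$observed > 0L]))) {
    p_mc <- mean(t_sim >= t_obs)
    se <- sqrt(p_mc * (1 - p_mc) / draws)
    p_exact <- res$p_value[match(t_obs, res$observed)]
    expect_lt(abs(p_exact - p_mc), 3 * se + 1e-9)
  }
})

test_that("p-values strictly decrease with the observed count", {
  set.seed(13)
  pb <- poisson_binomial(stats::runif(20, 0.05, 0.9))
  expect_true(all(diff(pb$tail) < 0))
})

test_that("constant gene covariates leave only the sample-burden effect", {
  set.seed(21)
  ind <- matrix(stats::rbinom(30 * 8, 1L, 0.1), 30, 8)
  gbm <- toy_gbm(ind, gene_length = rep(5000L, 30),
                 feature_count = rep(3L, 30),
                 sample_counts = c(5, 10, 15, 20, 25, 30, 35, 40))
  nm <- fit_gene_null_model(gbm)
  # every gene row identical: p varies only with the sample covariate
  expect_lt(max(apply(nm$probs, 2, function(col) diff(range(col)))), 1e-12)
})

test_that("the null model recovers generating probabilities as G*S grows", {
  mae <- function(g, s, seed) {
    set.seed(seed)
    fc <- sample(1:6, g, replace = TRUE)
    ns <- sample(10:60, s, replace = TRUE)
    p_true <- outer(fc, ns) / 3000        # linear in feature_count x N_s
    ind <- matrix(stats::rbinom(g * s, 1L, as.vector(p_true)), g, s)
    if (all(ind == 0)) ind[1, 1] <- 1L
    gbm <- toy_gbm(ind, gene_length = sample(10000:80000, g),
                   feature_count = fc, sample_counts = ns)
    mean(abs(fit_gene_null_model(gbm)$probs - p_true))
  }
  expect_lt(mae(150, 80, seed = 31), mae(25, 12, seed = 31))
})

test_that("a positive burden coefficient makes predicted probabilities grow with burden", {
  set.seed(41)
  ns <- sample(5:40, 20, replace = TRUE)
  fc <- sample(1:5, 50, replace = TRUE)
  ind <- matrix(stats::rbinom(50 * 20, 1L,
                              as.vector(outer(fc, ns) / 1500)), 50, 20)
  gbm <- toy_gbm(ind, gene_length = sample(10000:80000, 50),
                 feature_count = fc, sample_counts = ns)
  nm <- fit_gene_null_model(gbm)
  expect_gt(nm$coefficients[["sample_breakpoints"]], 0)
  # predicting the same cohort at doubled burdens raises every probability
  newdata <- data.frame(gene_length = rep(as.numeric(gbm$gene_length), 20),
                        feature_count = rep(as.numeric(fc), 20),
                        sample_breakpoints = rep(ns * 2, each = 50))
  doubled <- stats::predict(nm$model, newdata = newdata)
  expect_gt(mean(doubled), mean(nm$probs))
})

test_that("an all-zero outcome matrix cannot be modeled", {
  gbm <- toy_gbm(matrix(0L, 5, 4), gene_length = rep(1000L, 5),
                 feature_count = rep(2L, 5), sample_counts = rep(3, 4))
  expect_error(fit_gene_null_model(gbm), "no breakpoints")
})

test_that("equal gene null probabilities reduce to a binomial tail", {
  ind <- matrix(0L, 1, 200)
  ind[1, 1:5] <- 1L
  gbm <- toy_gbm(ind, gene_length = 1000L, feature_count = 2L,
                 sample_counts = rep(10, 200))
  res <- gene_level_test(gbm, matrix(0.01, 1, 200), adjusted = FALSE)
  expect_equal(res$p_value,
               stats::pbinom(4, 200, 0.01, lower.tail = FALSE))
  # and an unhit gene has p-value 1
  res0 <- gene_level_test(toy_gbm(rbind(ind, 0L),
                                  gene_length = c(1000L, 1000L),
                                  feature_count = c(2L, 2L),
                                  sample_counts = rep(10, 200)),
                          matrix(0.01, 2, 200), adjusted = FALSE)
  expect_equal(res0$p_value[2], 1)
})

test_that("gene-level p-values equal full enumeration for small cohorts", {
  set.seed(53)
  for (rep_i in 1:5) {
    g <- 6; s <- 10
    probs <- matrix(stats::runif(g * s, 0.02, 0.4), g, s)
    ind <- matrix(stats::rbinom(g * s, 1L, 0.25), g, s)
    if (all(ind == 0)) ind[1, 1] <- 1L
    gbm <- toy_gbm(ind, gene_length = rep(1000L, g),
                   feature_count = rep(2L, g), sample_counts = rep(3, s))
    res <- gene_level_test(gbm, probs, adjusted = FALSE)
    for (i in seq_len(g)) {
      t_obs <- sum(ind[i, ])
      oracle <- if (t_obs == 0L) 1 else enum_poisbinom_tail(probs[i, ])[t_obs + 1L]
      expect_equal(res$p_value[i], oracle, tolerance = 1e-12)
    }
  }
})

test_that("mismatched null-probability dimensions are rejected", {
  gbm <- toy_gbm(matrix(1L, 2, 3), gene_length = c(100L, 100L),
                 feature_count = c(1L, 1L), sample_counts = rep(2, 3))
  expect_error(gene_level_test(gbm, matrix(0.1, 3, 3)), "do not match")
})

test_that("with vanishing attainable minima Gilbert reduces to plain BH", {
  set.seed(61)
  p <- c(stats::runif(15, 1e-4, 0.04), stats::runif(25, 0.2, 1))
  min_att <- rep(1e-12, 40)
  gf <- gilbert_fdr(p, min_att, alpha = 0.1)
  expect_identical(gf$rejected, bh_reject(p, 0.1))
  expect_true(all(gf$in_multiplicity_set))
  # adjusted values match BH-adjusted p-values up to bisection resolution
  expect_equal(gf$adjusted, stats::p.adjust(p, "BH"), tolerance = 1e-6)
})

test_that("the K-search excludes tests that cannot reach small p-values", {
  gf <- gilbert_fdr(p_values = c(0.5, 0.001, 0.9),
                    min_attainable = c(0.5, 1e-9, 1e-9), alpha = 0.1)
  expect_equal(gf$K, 2L)
  expect_identical(gf$in_multiplicity_set, c(FALSE, TRUE, TRUE))
  # BH applied to tests 2 and 3 only: 0.001 <= 0.1 * 1/2 rejected, 0.9 not
  expect_identical(gf$rejected, c(FALSE, TRUE, FALSE))
  expect_equal(gf$adjusted[1], 1)
})

test_that("Gilbert rejects at least the plain BH set on cohort-style discrete tests", {
  # nulls shaped like the gene-level tests of this package: Poisson-binomial
  # counts over a cohort of samples with small per-sample probabilities
  set.seed(71)
  for (rep_i in 1:20) {
    m <- 50
    s <- sample(c(6L, 30L), 1)
    p <- min_att <- numeric(m)
    for (i in seq_len(m)) {
      q <- stats::runif(s, 0.001, 0.2)
      hits <- sum(stats::runif(s) < pmin(1, q * sample(c(1, 6), 1)))
      p[i] <- if (hits == 0L) 1 else poisson_binomial(q)$tail[hits + 1L]
      min_att[i] <- prod(q)
    }
    gf <- gilbert_fdr(p, min_att, alpha = 0.1, adjusted = FALSE)
    bh <- bh_reject(p, 0.1)
    expect_true(all(gf$rejected >= bh))
  }
})

test_that("rejection at level alpha matches the adjusted values", {
  set.seed(83)
  m <- 30
  n_i <- sample(2:10, m, replace = TRUE)
  q_i <- stats::runif(m, 0.05, 0.4)
  t_i <- stats::rbinom(m, n_i, pmin(1, q_i * sample(c(1, 3), m,
                                                    replace = TRUE)))
  p <- stats::pbinom(t_i - 1, n_i, q_i, lower.tail = FALSE)
  gf <- gilbert_fdr(p, q_i^n_i, alpha = 0.15)
  expect_identical(gf$rejected, gf$adjusted <= 0.15 + 1e-9)
})

test_that("gilbert_fdr validates its inputs", {
  expect_error(gilbert_fdr(0.5, 0.1, alpha = 0), "alpha")
  expect_error(gilbert_fdr(0.5, 0.1, alpha = 1), "alpha")
  expect_error(gilbert_fdr(c(0.5, 0.2), 0.1), "equal length")
  expect_error(gilbert_fdr(0.5, 1.4), "\\[0, 1\\]")
})
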