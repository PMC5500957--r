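#' Feature-level recurrence test
#'
#' Because copy number features (probes or bins) are nearly uniformly spaced,
#' every feature shares the same null probability of hosting a breakpoint
#' within a sample; it differs only between samples and equals
#' \eqn{p_s = N_s / N}, the sample's breakpoint burden over the total feature
#' count.  The observed statistic for feature i is the number of samples with
#' a breakpoint there; its null distribution is a single Poisson-binomial
#' over \eqn{(p_1, ..., p_S)} shared by all features.  P-values are exact
#' upper tails \eqn{P(T \ge t_{obs})} and are adjusted by Benjamini-Hochberg.
#'
#' @param bpm a \code{"breakpoint_matrix"} (filtered or not).
#' @param n_mode denominator convention for N: \code{"all"} uses every grid
#'   feature; \code{"eligible"} subtracts the per-chromosome first features,
#'   which can never host a breakpoint.
#' @return a \code{data.frame} with one row per feature: \code{feature_id},
#'   \code{chromosome}, \code{start}, \code{end}, \code{observed} (samples
#'   with a breakpoint), \code{p_value}, \code{fdr} (BH-adjusted), plus the
#'   shared null as attribute \code{"null"}.
#' @export
feature_level_test <- function(bpm, n_mode = c("all", "eligible")) {
  stopifnot(inherits(bpm, "breakpoint_matrix"))
  n_mode <- match.arg(n_mode)
  grid <- bpm$grid
  if (nrow(grid) == 0L)
    stop("no features to test")
  n <- nrow(grid)
  if (n_mode == "eligible")
    n <- n - length(unique(grid$chromosome))
  probs <- bpm$per_sample_counts / n
  if (any(probs > 1))
    stop("per-sample breakpoint count exceeds the feature count")
  null <- poisson_binomial(probs)
  observed <- as.integer(rowSums(bpm$indicator))
  p <- pb_upper_tail(null, observed)
  res <- data.frame(feature_id = grid$feature_id,
                    chromosome = grid$chromosome,
                    start = grid$start, end = grid$end,
                    observed = observed,
                    p_value = p,
                    fdr = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  attr(res, "null") <- null
  attr(res, "n_features") <- n
  res
}

#' Fit the gene-level breakpoint null model
#'
#' At gene level a uniform null probability is untenable: the chance that a
#' random breakpoint lands in a gene grows with 1) the length of the gene,
#' 2) the number of features associated with the gene and 3) the sample's
#' total breakpoint burden.  A pooled linear probability model corrects for
#' these covariates: the binary gene-hit outcomes over all (gene, sample)
#' pairs are regressed by ordinary least squares on the two gene covariates
#' and the sample burden (main effects only), and the fitted values -- clipped
#' into \code{[1e-10, 1 - 1e-10]} -- become the gene- and sample-specific
#' null probabilities \eqn{p_{g,s}}.
#'
#' @param gbm a \code{"gene_break_matrix"}.
#' @param log_covariates if \code{TRUE}, covariates enter as
#'   \code{log1p(x)} instead of untransformed.
#' @return an object of class \code{"gene_null_model"}: a list with
#'   \code{probs} (G x S matrix of \eqn{p_{g,s}}), \code{coefficients},
#'   \code{model} (the underlying \code{lm} fit) and \code{log_covariates}.
#' @export
fit_gene_null_model <- function(gbm, log_covariates = FALSE) {
  stopifnot(inherits(gbm, "gene_break_matrix"))
  g <- nrow(gbm$indicator)
  s <- ncol(gbm$indicator)
  y <- as.numeric(gbm$indicator)          # column-major: gene index fastest
  if (all(y == 0))
    stop("no breakpoints to model: all gene-hit indicators are zero")
  df <- data.frame(
    hit = y,
    gene_length = rep(as.numeric(gbm$gene_length), times = s),
    feature_count = rep(as.numeric(gbm$gene_feature_count), times = s),
    sample_breakpoints = rep(as.numeric(gbm$per_sample_counts), each = g))
  if (log_covariates) {
    df$gene_length <- log1p(df$gene_length)
    df$feature_count <- log1p(df$feature_count)
    df$sample_breakpoints <- log1p(df$sample_breakpoints)
  }
  fit <- stats::lm(hit ~ gene_length + feature_count + sample_breakpoints,
                   data = df, model = FALSE)
  probs <- matrix(pmin(pmax(stats::fitted(fit), 1e-10), 1 - 1e-10), g, s,
                  dimnames = dimnames(gbm$indicator))
  structure(list(probs = probs,
                 coefficients = stats::coef(fit),
                 model = fit,
                 log_covariates = log_covariates),
            class = "gene_null_model")
}

#' @export
print.gene_null_model <- function(x, ...) {
  cat("Gene-level breakpoint null model (linear probability, OLS)\n")
  cat("  ", nrow(x$probs), " genes x ", ncol(x$probs), " samples",
      if (x$log_covariates) ", log1p covariates", "\n", sep = "")
  cat("  coefficients:\n")
  print(x$coefficients)
  invisible(x)
}

#' @method coef gene_null_model
#' @export
coef.gene_null_model <- function(object, ...) object$coefficients

#' @export
fitted.gene_null_model <- function(object, ...) object$probs

#' Gene-level recurrence test with exact per-gene nulls
#'
#' The statistic per gene is the number of samples with a breakpoint in the
#' gene; its null is the Poisson-binomial over that gene's row of
#' \eqn{p_{g,s}} (which differs per gene, so the distribution is recomputed
#' for each).  P-values are exact upper tails; multiple testing is corrected
#' either by the discreteness-aware Tarone-Gilbert procedure (default, see
#' \code{\link{gilbert_fdr}}) or plain Benjamini-Hochberg.
#'
#' @param gbm a \code{"gene_break_matrix"}.
#' @param null_probs a \code{"gene_null_model"} or a numeric G x S matrix of
#'   null probabilities matching \code{gbm}.
#' @param alpha FDR level used for the Gilbert rejection set (default 0.1).
#' @param fdr_method \code{"gilbert"} or \code{"bh"}.
#' @param adjusted for \code{"gilbert"}: also compute adjusted values (the
#'   smallest level at which each gene is rejected, by bisection); slightly
#'   more work for large gene sets.
#' @return a \code{data.frame} with one row per gene: identifiers, extent,
#'   covariates, \code{observed}, \code{null_prob_mean} (the gene's mean
#'   \eqn{p_{g,s}}), \code{min_attainable} (smallest p-value the gene's
#'   discrete null can produce, \eqn{\prod_s p_{g,s}}), \code{p_value},
#'   \code{fdr} and \code{significant} (in the rejection set at
#'   \code{alpha}).
#' @export
gene_level_test <- function(gbm, null_probs, alpha = 0.1,
                            fdr_method = c("gilbert", "bh"),
                            adjusted = TRUE) {
  stopifnot(inherits(gbm, "gene_break_matrix"))
  fdr_method <- match.arg(fdr_method)
  if (inherits(null_probs, "gene_null_model"))
    null_probs <- null_probs$probs
  null_probs <- as.matrix(null_probs)
  if (!all(dim(null_probs) == dim(gbm$indicator)))
    stop("null probability matrix dimensions (",
         paste(dim(null_probs), collapse = " x "),
         ") do not match the gene breakpoint matrix (",
         paste(dim(gbm$indicator), collapse = " x "), ")")
  if (any(null_probs < 0) || any(null_probs > 1))
    stop("null probabilities must lie in [0, 1]")
  g <- nrow(null_probs)
  observed <- as.integer(rowSums(gbm$indicator))
  p <- numeric(g)
  for (i in seq_len(g)) {
    pb <- poisson_binomial(null_probs[i, ])
    p[i] <- pb_upper_tail(pb, observed[i])
  }
  # support minimum of the discrete null: P(T = S) = prod(p_{g,s});
  # log-scale sum avoids premature underflow for moderate S
  min_attainable <- exp(rowSums(log(null_probs)))
  if (fdr_method == "gilbert") {
    gf <- gilbert_fdr(p, min_attainable, alpha = alpha, adjusted = adjusted)
    fdr <- if (adjusted) gf$adjusted else ifelse(gf$rejected, alpha, 1)
    significant <- gf$rejected
  } else {
    fdr <- stats::p.adjust(p, method = "BH")
    significant <- fdr < alpha
  }
  data.frame(gene_id = gbm$genes$gene_id,
             gene_name = gbm$genes$gene_name,
             chromosome = gbm$genes$chromosome,
             start = gbm$genes$start,
             end = gbm$genes$end,
             gene_length = as.integer(gbm$gene_length),
             feature_count = as.integer(gbm$gene_feature_count),
             observed = observed,
             null_prob_mean = rowMeans(null_probs),
             min_attainable = min_attainable,
             p_value = p,
             fdr = fdr,
             significant = significant,
             stringsAsFactors = FALSE)
}

## Core of the Tarone-Gilbert procedure at one level: the multiplicity set
## and the BH rejections within it.  sorted_min is sort(min_attainable).
.gilbert_reject <- function(p_values, min_attainable, sorted_min, alpha) {
  m <- length(p_values)
  k <- seq_len(m)
  counts <- findInterval(alpha / k, sorted_min)
  K <- k[counts <= k][1L]
  in_set <- min_attainable <= alpha / K
  rejected <- logical(m)
  idx <- which(in_set)
  if (length(idx)) {
    mr <- length(idx)
    o <- order(p_values[idx])
    ranked <- p_values[idx][o]
    below <- which(ranked <= alpha * seq_len(mr) / mr)
    if (length(below))
      rejected[idx[o[seq_len(max(below))]]] <- TRUE
  }
  list(rejected = rejected, K = K, in_set = in_set)
}

#' Discreteness-aware FDR control (Tarone-Gilbert procedure)
#'
#' Exact tests on discrete statistics cannot produce arbitrarily small
#' p-values: each test has a minimum attainable p-value (here
#' \eqn{\prod_s p_{g,s}}, the upper tail at the full cohort).  Tests whose
#' minimum attainable value is too large to ever be rejected only dilute the
#' Benjamini-Hochberg multiplicity burden.  Following Tarone's idea as
#' adapted by Gilbert to FDR control, the procedure finds the smallest
#' \eqn{K \ge 1} with
#' \eqn{\#\{g : \alpha^*_g \le \alpha / K\} \le K}
#' (where \eqn{\alpha^*_g} is the minimum attainable p-value), restricts to
#' the multiplicity set \eqn{R = \{g : \alpha^*_g \le \alpha / K\}}, and
#' applies Benjamini-Hochberg within R at level \eqn{\alpha}.  Genes outside
#' R are never rejected and receive adjusted value 1.  When all minimum
#' attainable values tend to zero (the continuous limit) the procedure
#' reduces exactly to plain BH.
#'
#' Adjusted values are defined as the smallest level \eqn{\alpha} at which a
#' test is rejected by the procedure, computed by bisection over
#' \eqn{\alpha}; they may legitimately fall below the BH-adjusted values
#' because the multiplicity set shrinks.
#'
#' @param p_values exact p-values.
#' @param min_attainable per-test minimum attainable p-values (same length).
#' @param alpha target FDR level in (0, 1).
#' @param adjusted compute adjusted values by bisection (default TRUE).
#' @param bisect_iter bisection iterations (41 gives ~5e-13 resolution).
#' @return a list with \code{rejected} (logical), \code{adjusted} (numeric,
#'   or NULL), \code{K}, \code{in_multiplicity_set} (logical) and
#'   \code{alpha}.
#' @export
gilbert_fdr <- function(p_values, min_attainable, alpha = 0.1,
                        adjusted = TRUE, bisect_iter = 41L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1")
  if (length(p_values) != length(min_attainable))
    stop("p_values and min_attainable must have equal length")
  if (anyNA(p_values) || anyNA(min_attainable))
    stop("p_values and min_attainable must not contain NA")
  if (any(min_attainable < 0) || any(min_attainable > 1))
    stop("min_attainable values must lie in [0, 1]")
  sorted_min <- sort(min_attainable)
  base <- .gilbert_reject(p_values, min_attainable, sorted_min, alpha)
  adj <- NULL
  if (adjusted) {
    m <- length(p_values)
    adj <- rep(1, m)
    # tests never rejected even just below level 1 keep adjusted value 1
    near_one <- .gilbert_reject(p_values, min_attainable, sorted_min,
                                1 - 1e-12)$rejected
    for (g in which(near_one)) {
      lo <- 0; hi <- 1 - 1e-12
      for (it in seq_len(bisect_iter)) {
        mid <- (lo + hi) / 2
        if (.gilbert_reject(p_values, min_attainable, sorted_min,
                            mid)$rejected[g]) hi <- mid else lo <- mid
      }
      adj[g] <- hi
    }
  }
  list(rejected = base$rejected, adjusted = adj, K = base$K,
       in_multiplicity_set = base$in_set, alpha = alpha)
}
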