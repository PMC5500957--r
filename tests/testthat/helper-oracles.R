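## Independent oracles and in-code fixtures shared across the suite.

## Exact Poisson-binomial pmf by full enumeration over all 2^S outcomes.
## Deliberately independent of the package's PGF expansion.
enum_poisbinom_pmf <- function(probs) {
  s <- length(probs)
  outcomes <- as.matrix(expand.grid(rep(list(0:1), s)))
  pr <- exp(outcomes %*% log(probs) + (1 - outcomes) %*% log1p(-probs))
  counts <- rowSums(outcomes)
  pmf <- numeric(s + 1)
  agg <- tapply(pr, counts, sum)
  pmf[as.integer(names(agg)) + 1L] <- agg
  pmf
}

enum_poisbinom_tail <- function(probs) {
  rev(cumsum(rev(enum_poisbinom_pmf(probs))))
}

## Quadratic all-pairs interval overlap scan (1-based inclusive).
brute_overlap_count <- function(q_chrom, q_start, q_end,
                                s_chrom, s_start, s_end) {
  vapply(seq_along(q_chrom), function(i) {
    sum(s_chrom == q_chrom[i] &
          pmax(s_start, q_start[i]) <= pmin(s_end, q_end[i]))
  }, integer(1))
}

## Build a single-chromosome-per-block profile set from explicit per-sample
## segmented value vectors.  seg: features x samples matrix; chrom: per-row
## chromosome labels.  Feature i occupies [i*1000, i*1000 + 59].
toy_profiles <- function(seg, chrom = rep("1", nrow(as.matrix(seg))),
                         calls = NULL) {
  seg <- as.matrix(seg)
  n <- nrow(seg)
  grid <- feature_grid(sprintf("P%03d", seq_len(n)), chrom,
                       start = seq_len(n) * 1000L,
                       end = seq_len(n) * 1000L + 59L)
  cnp_set(grid, seg, calls = calls,
          sample_ids = sprintf("S%02d", seq_len(ncol(seg))))
}

## Profiles with breakpoints planted at given feature indices (per sample):
## the segmented value flips between 0 and 0.5 at every planted boundary.
profiles_from_boundaries <- function(n_features, boundaries_list,
                                     chrom = rep("1", n_features)) {
  seg <- vapply(boundaries_list, function(b) {
    flip <- integer(n_features)
    flip[b] <- 1L
    0.5 * (cumsum(flip) %% 2)
  }, numeric(n_features))
  toy_profiles(seg, chrom = chrom)
}

## Minimal gene_break_matrix built directly from an indicator and covariates
## (bypasses mapping; for null-model unit tests).
toy_gbm <- function(indicator, gene_length, feature_count, sample_counts) {
  g <- nrow(indicator)
  genes <- gene_annotation(sprintf("G%03d", seq_len(g)),
                           chromosome = rep("1", g),
                           start = seq_len(g) * 10000L,
                           end = seq_len(g) * 10000L + gene_length - 1L)
  structure(list(genes = genes,
                 sample_ids = colnames(indicator) %||%
                   sprintf("S%02d", seq_len(ncol(indicator))),
                 indicator = indicator,
                 gene_length = stats::setNames(as.integer(gene_length),
                                               genes$gene_id),
                 gene_feature_count = stats::setNames(as.integer(feature_count),
                                                      genes$gene_id),
                 per_sample_counts = as.numeric(sample_counts),
                 n_features = 1000L,
                 map_mode = "interval"),
            class = "gene_break_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Plain BH step-up rejection set (independent of the package's Gilbert path).
bh_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  below <- which(p[o] <= alpha * seq_len(m) / m)
  rej <- logical(m)
  if (length(below)) rej[o[seq_len(max(below))]] <- TRUE
  rej
}
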