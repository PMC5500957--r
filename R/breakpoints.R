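#' Detect per-sample breakpoints from segmented profiles
#'
#' A copy number segment is a maximal run of features sharing one segmented
#' value within a chromosome.  Each segment boundary -- every segment start
#' except the first segment of a chromosome -- is recorded as a breakpoint,
#' located at the genomic start position of the downstream segment's first
#' feature.  Because copy number platforms are granular, the true break lies
#' somewhere in the interval between the last upstream feature and the first
#' downstream feature; that uncertainty interval
#' \code{[upstream end + 1, downstream start]} is carried with every
#' breakpoint and used for gene mapping.
#'
#' @param profiles a \code{\link{cnp_set}}.
#' @param tol non-negative tolerance for comparing adjacent segmented values;
#'   the default 0 treats segmentation output as exactly piecewise-constant.
#'   A small tolerance (e.g. 1e-8) accommodates values that round-tripped
#'   through text at differing precision.
#' @return an object of class \code{"breakpoint_matrix"}: a list with
#'   \describe{
#'     \item{grid}{the feature grid (all N features).}
#'     \item{sample_ids}{sample names.}
#'     \item{indicator}{N x S binary matrix; \code{indicator[i, s] = 1} iff
#'       sample s has a breakpoint whose downstream segment starts at
#'       feature i.}
#'     \item{breakpoints}{one row per breakpoint: \code{sample_id},
#'       \code{feature_index}, \code{feature_id}, \code{chromosome},
#'       \code{interval_start}, \code{interval_end}, \code{delta_log2},
#'       \code{call_up}, \code{call_down}.}
#'     \item{per_sample_counts}{breakpoints per sample (the burden N_s).}
#'   }
#' @export
detect_breakpoints <- function(profiles, tol = 0) {
  stopifnot(inherits(profiles, "cnp_set"), tol >= 0)
  grid <- profiles$grid
  seg <- profiles$segmented
  n <- nrow(grid)
  s <- ncol(seg)
  same_chrom <- grid$chromosome[-1L] == grid$chromosome[-n]
  changed <- abs(seg[-1L, , drop = FALSE] - seg[-n, , drop = FALSE]) > tol
  indicator <- matrix(0L, n, s, dimnames = dimnames(seg))
  indicator[-1L, ] <- 1L * (changed & same_chrom)
  hits <- which(indicator == 1L, arr.ind = TRUE)
  hits <- hits[order(hits[, 2L], hits[, 1L]), , drop = FALSE]
  i <- hits[, 1L]
  j <- hits[, 2L]
  has_calls <- !is.null(profiles$calls)
  bp <- data.frame(
    sample_id = profiles$sample_ids[j],
    feature_index = as.integer(i),
    feature_id = grid$feature_id[i],
    chromosome = grid$chromosome[i],
    interval_start = grid$end[i - 1L] + 1L,
    interval_end = grid$start[i],
    delta_log2 = seg[cbind(i, j)] - seg[cbind(i - 1L, j)],
    call_up = if (has_calls) profiles$calls[cbind(i - 1L, j)]
              else rep(NA_integer_, length(i)),
    call_down = if (has_calls) profiles$calls[cbind(i, j)]
                else rep(NA_integer_, length(i)),
    stringsAsFactors = FALSE)
  new_breakpoint_matrix(grid, profiles$sample_ids, indicator, bp,
                        has_calls = has_calls, filter = "none")
}

new_breakpoint_matrix <- function(grid, sample_ids, indicator, breakpoints,
                                  has_calls, filter, threshold = NA_real_) {
  structure(list(grid = grid, sample_ids = sample_ids, indicator = indicator,
                 breakpoints = breakpoints,
                 per_sample_counts = stats::setNames(colSums(indicator),
                                                     sample_ids),
                 has_calls = has_calls, filter = filter,
                 threshold = threshold),
            class = "breakpoint_matrix")
}

#' @export
print.breakpoint_matrix <- function(x, ...) {
  cat("Breakpoint matrix: ", nrow(x$breakpoints), " breakpoints, ",
      length(x$sample_ids), " samples, ", nrow(x$grid), " features\n", sep = "")
  cat("  filter: ", x$filter,
      if (!is.na(x$threshold)) paste0(" (threshold ", x$threshold, ")"),
      "\n", sep = "")
  cat("  breakpoints per sample: median ",
      stats::median(x$per_sample_counts), ", range ",
      min(x$per_sample_counts), "-", max(x$per_sample_counts), "\n", sep = "")
  invisible(x)
}

#' Select breakpoints by flanking-segment characteristics
#'
#' Three selection modes restrict the raw breakpoint set using the two copy
#' number segments flanking each breakpoint:
#' \describe{
#'   \item{\code{deviation}}{keep breakpoints whose absolute shift in
#'     segmented log2-ratio between the consecutive segments exceeds
#'     \code{threshold} (strict inequality).}
#'   \item{\code{cna_associated}}{keep all breakpoints except those flanked
#'     by two copy-number-neutral segments (discrete calls 0 and 0).  A
#'     breakpoint between two aberrant segments of the same state, e.g. gain
#'     to stronger gain, is retained.}
#'   \item{\code{cna_call_change}}{keep only breakpoints whose flanking
#'     segments carry dissimilar discrete copy number states.}
#' }
#' Modes \code{cna_associated} and \code{cna_call_change} require discrete
#' calls to be present in the profile set the breakpoints came from.
#'
#' @param bpm a \code{\link{detect_breakpoints}} result.
#' @param mode one of \code{"deviation"}, \code{"cna_associated"},
#'   \code{"cna_call_change"}.
#' @param threshold log2-ratio shift threshold for \code{mode = "deviation"};
#'   must be positive.  The default 0.2 is an arbitrary but common choice for
#'   tumor data with normal-cell admixture.
#' @return a new \code{"breakpoint_matrix"} containing the selected
#'   breakpoints, with the indicator matrix and per-sample counts recomputed.
#' @export
filter_breakpoints <- function(bpm,
                               mode = c("deviation", "cna_associated",
                                        "cna_call_change"),
                               threshold = 0.2) {
  stopifnot(inherits(bpm, "breakpoint_matrix"))
  mode <- match.arg(mode)
  bp <- bpm$breakpoints
  if (mode == "deviation") {
    if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
      stop("mode 'deviation' requires a single positive threshold")
    keep <- abs(bp$delta_log2) > threshold
  } else {
    if (!isTRUE(bpm$has_calls))
      stop("mode '", mode, "' requires discrete copy number calls")
    keep <- switch(mode,
      cna_associated = !(bp$call_up == 0L & bp$call_down == 0L),
      cna_call_change = bp$call_up != bp$call_down)
    keep[is.na(keep)] <- FALSE
  }
  bp <- bp[keep, , drop = FALSE]
  rownames(bp) <- NULL
  indicator <- matrix(0L, nrow(bpm$grid), length(bpm$sample_ids),
                      dimnames = dimnames(bpm$indicator))
  if (nrow(bp))
    indicator[cbind(bp$feature_index,
                    match(bp$sample_id, bpm$sample_ids))] <- 1L
  new_breakpoint_matrix(bpm$grid, bpm$sample_ids, indicator, bp,
                        has_calls = bpm$has_calls, filter = mode,
                        threshold = if (mode == "deviation") threshold
                                    else NA_real_)
}

#' Export breakpoints as a BED-style table
#'
#' Breakpoint uncertainty intervals are converted to 0-based half-open
#' coordinates (\code{interval_start - 1}, \code{interval_end}); the name
#' field is \code{sample_id:feature_id} and the score is the log2-ratio
#' shift.
#'
#' @param bpm a \code{"breakpoint_matrix"}.
#' @param path optional file; if given the table is written as
#'   tab-separated BED without header.
#' @return the BED \code{data.frame}, invisibly if \code{path} is given.
#' @export
breakpoints_to_bed <- function(bpm, path = NULL) {
  bp <- bpm$breakpoints
  bed <- data.frame(chrom = bp$chromosome,
                    start = bp$interval_start - 1L,
                    end = bp$interval_end,
                    name = paste(bp$sample_id, bp$feature_id, sep = ":"),
                    score = bp$delta_log2,
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    return(invisible(bed))
  }
  bed
}
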