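## Gene mapping: breakpoint uncertainty intervals vs gene extents.  All
## overlap arithmetic is 1-based inclusive on both sides and delegated to
## GenomicRanges.

.as_granges <- function(chromosome, start, end, levels = unique(chromosome)) {
  GenomicRanges::GRanges(seqnames = factor(chromosome, levels = levels),
                         ranges = IRanges::IRanges(start = start, end = end))
}

#' Count grid features associated with each gene
#'
#' A feature is associated with a gene when they share a chromosome and their
#' extents overlap by at least one base
#' (\code{max(starts) <= min(ends)}).  The count is one of the covariates of
#' the gene-level null model: genes spanning more features present more
#' candidate breakpoint positions.
#'
#' @param grid a \code{\link{feature_grid}}.
#' @param genes a \code{\link{gene_annotation}}.
#' @return integer vector, one count per gene, named by \code{gene_id}.
#' @export
associate_features_to_genes <- function(grid, genes) {
  stopifnot(inherits(grid, "feature_grid"), inherits(genes, "gene_annotation"))
  lev <- unique(c(grid$chromosome, genes$chromosome))
  gr_feat <- .as_granges(grid$chromosome, grid$start, grid$end, levels = lev)
  gr_gene <- .as_granges(genes$chromosome, genes$start, genes$end, levels = lev)
  counts <- GenomicRanges::countOverlaps(gr_gene, gr_feat)
  stats::setNames(as.integer(counts), genes$gene_id)
}

#' Map breakpoints onto genes
#'
#' A gene is hit by a breakpoint when they share a chromosome and the gene
#' extent overlaps the breakpoint's location.  With
#' \code{mode = "interval"} (default) the location is the full uncertainty
#' interval between the flanking features, so genes lying inside large
#' inter-probe gaps are not missed; with \code{mode = "feature"} only the
#' genomic start position of the downstream segment's first feature is used.
#'
#' The per-gene, per-sample indicator is binary: a gene overlapped by several
#' breakpoint intervals of one sample counts once, as required by the
#' Bernoulli null model of the cohort statistics.
#'
#' @param bpm a \code{"breakpoint_matrix"}, already filtered with the
#'   caller's selection mode of choice.
#' @param genes a \code{\link{gene_annotation}}; must be non-empty.
#' @param mode \code{"interval"} or \code{"feature"}.
#' @return an object of class \code{"gene_break_matrix"}: a list with
#'   \code{genes}, \code{sample_ids}, binary \code{indicator} (genes x
#'   samples), covariates \code{gene_length} (bp) and
#'   \code{gene_feature_count}, and \code{per_sample_counts} (the breakpoint
#'   burden N_s of the input, sample covariate of the null model).
#' @export
map_breakpoints_to_genes <- function(bpm, genes, mode = c("interval", "feature")) {
  stopifnot(inherits(bpm, "breakpoint_matrix"))
  mode <- match.arg(mode)
  if (!inherits(genes, "gene_annotation") || nrow(genes) == 0L)
    stop("a non-empty gene annotation is required")
  bp <- bpm$breakpoints
  indicator <- matrix(0L, nrow(genes), length(bpm$sample_ids),
                      dimnames = list(genes$gene_id, bpm$sample_ids))
  if (nrow(bp)) {
    lev <- unique(c(bp$chromosome, genes$chromosome))
    gr_bp <- if (mode == "interval")
      .as_granges(bp$chromosome, bp$interval_start, bp$interval_end,
                  levels = lev)
    else
      .as_granges(bp$chromosome, bpm$grid$start[bp$feature_index],
                  bpm$grid$start[bp$feature_index], levels = lev)
    gr_gene <- .as_granges(genes$chromosome, genes$start, genes$end,
                           levels = lev)
    hits <- GenomicRanges::findOverlaps(gr_gene, gr_bp)
    if (length(hits))
      indicator[cbind(S4Vectors::queryHits(hits),
                      match(bp$sample_id[S4Vectors::subjectHits(hits)],
                            bpm$sample_ids))] <- 1L
  }
  structure(list(genes = genes,
                 sample_ids = bpm$sample_ids,
                 indicator = indicator,
                 gene_length = stats::setNames(genes$end - genes$start + 1L,
                                               genes$gene_id),
                 gene_feature_count = associate_features_to_genes(bpm$grid,
                                                                  genes),
                 per_sample_counts = bpm$per_sample_counts,
                 n_features = nrow(bpm$grid),
                 map_mode = mode),
            class = "gene_break_matrix")
}

#' @export
print.gene_break_matrix <- function(x, ...) {
  cat("Gene breakpoint matrix: ", nrow(x$genes), " genes x ",
      length(x$sample_ids), " samples (mapping: ", x$map_mode, ")\n", sep = "")
  cat("  genes hit in >=1 sample: ", sum(rowSums(x$indicator) > 0), "\n",
      sep = "")
  invisible(x)
}

#' Per-gene summary of a gene breakpoint matrix
#'
#' @param object a \code{"gene_break_matrix"}.
#' @param ... unused.
#' @return a \code{data.frame} with one row per gene: extent, length,
#'   associated feature count and the number of samples with a breakpoint in
#'   the gene.
#' @method summary gene_break_matrix
#' @export
summary.gene_break_matrix <- function(object, ...) {
  data.frame(gene_id = object$genes$gene_id,
             gene_name = object$genes$gene_name,
             chromosome = object$genes$chromosome,
             start = object$genes$start,
             end = object$genes$end,
             gene_length = as.integer(object$gene_length),
             feature_count = as.integer(object$gene_feature_count),
             samples_hit = as.integer(rowSums(object$indicator)),
             stringsAsFactors = FALSE)
}
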