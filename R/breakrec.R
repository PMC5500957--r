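#' Cohort-level recurrent breakpoint analysis
#'
#' The main fitting function of the package.  Starting from segmented copy
#' number profiles it (1) detects per-sample breakpoints at segment
#' boundaries, (2) optionally restricts them by flanking-segment
#' characteristics, (3) maps breakpoint uncertainty intervals onto genes and
#' (4) tests every feature and every gene for recurrence across the cohort
#' against exact Poisson-binomial nulls -- uniform per-feature probabilities
#' \eqn{p_s = N_s / N} at feature level, covariate-corrected probabilities
#' \eqn{p_{g,s}} from a linear probability model at gene level -- with
#' Benjamini-Hochberg control at feature level and discreteness-aware
#' Tarone-Gilbert control at gene level (mirroring their respective default
#' conventions).
#'
#' @param profiles a \code{\link{cnp_set}} of segmented log2-ratios (and
#'   optionally discrete calls).
#' @param genes an optional \code{\link{gene_annotation}}; without it only
#'   the feature-level analysis is run.
#' @param filter breakpoint selection: \code{"none"} (keep all),
#'   \code{"deviation"}, \code{"cna_associated"} or \code{"cna_call_change"}
#'   (see \code{\link{filter_breakpoints}}).
#' @param threshold log2-ratio shift threshold for \code{filter = "deviation"}.
#' @param map_mode gene mapping by breakpoint \code{"interval"} (default) or
#'   downstream \code{"feature"} position (see
#'   \code{\link{map_breakpoints_to_genes}}).
#' @param alpha FDR level for significance calls (default 0.1).
#' @param gene_fdr \code{"gilbert"} (default) or \code{"bh"}.
#' @param n_mode feature-count denominator convention, see
#'   \code{\link{feature_level_test}}.
#' @param log_covariates pass covariates through \code{log1p} in the gene
#'   null model.
#' @param tol segmented-value comparison tolerance, see
#'   \code{\link{detect_breakpoints}}.
#' @return an object of class \code{"breakrec"}: a list with components
#'   \code{breakpoints} (the filtered \code{breakpoint_matrix}),
#'   \code{gene_matrix} (\code{gene_break_matrix} or NULL),
#'   \code{null_model} (\code{gene_null_model} or NULL), result tables
#'   \code{feature} and \code{gene}, the significance level \code{alpha},
#'   the matched \code{params} and the \code{call}.
#' @seealso \code{\link{summary.breakrec}}, \code{\link{plot.breakrec}},
#'   \code{\link{simulate_cohort}}
#' @examples
#' sim <- simulate_cohort(sim_config(n_samples = 12, n_features = 200,
#'                                   n_chromosomes = 4, n_genes = 30,
#'                                   breakpoint_range = c(2L, 8L), seed = 7))
#' fit <- breakrec(sim$profiles, sim$genes, filter = "cna_associated")
#' fit
#' head(fit$gene[order(fit$gene$p_value), ])
#' @export
breakrec <- function(profiles, genes = NULL,
                     filter = c("none", "deviation", "cna_associated",
                                "cna_call_change"),
                     threshold = 0.2,
                     map_mode = c("interval", "feature"),
                     alpha = 0.1,
                     gene_fdr = c("gilbert", "bh"),
                     n_mode = c("all", "eligible"),
                     log_covariates = FALSE,
                     tol = 0) {
  stopifnot(inherits(profiles, "cnp_set"))
  filter <- match.arg(filter)
  map_mode <- match.arg(map_mode)
  gene_fdr <- match.arg(gene_fdr)
  n_mode <- match.arg(n_mode)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1")

  bpm <- detect_breakpoints(profiles, tol = tol)
  if (filter != "none")
    bpm <- filter_breakpoints(bpm, mode = filter, threshold = threshold)
  feature <- feature_level_test(bpm, n_mode = n_mode)

  gbm <- null_model <- gene <- NULL
  if (!is.null(genes)) {
    gbm <- map_breakpoints_to_genes(bpm, genes, mode = map_mode)
    null_model <- fit_gene_null_model(gbm, log_covariates = log_covariates)
    gene <- gene_level_test(gbm, null_model, alpha = alpha,
                            fdr_method = gene_fdr)
  }
  structure(list(breakpoints = bpm, gene_matrix = gbm,
                 null_model = null_model,
                 feature = feature, gene = gene,
                 alpha = alpha,
                 params = list(filter = filter, threshold = threshold,
                               map_mode = map_mode, gene_fdr = gene_fdr,
                               n_mode = n_mode,
                               log_covariates = log_covariates, tol = tol),
                 call = match.call()),
            class = "breakrec")
}

#' @export
print.breakrec <- function(x, ...) {
  bpm <- x$breakpoints
  cat("Recurrent breakpoint analysis\n")
  cat("  samples: ", length(bpm$sample_ids),
      "   features: ", nrow(bpm$grid),
      "   breakpoints: ", nrow(bpm$breakpoints),
      " (filter: ", x$params$filter, ")\n", sep = "")
  cat("  features with FDR < ", x$alpha, ": ",
      sum(x$feature$fdr < x$alpha), "\n", sep = "")
  if (!is.null(x$gene))
    cat("  genes tested: ", nrow(x$gene),
        "   recurrent breakpoint genes (", x$params$gene_fdr, " FDR < ",
        x$alpha, "): ", sum(x$gene$significant), "\n", sep = "")
  invisible(x)
}

#' Summarize a recurrent breakpoint analysis
#'
#' @param object a \code{"breakrec"} fit.
#' @param n_top number of top-ranked units to display.
#' @param ... unused.
#' @return an object of class \code{"summary.breakrec"} (printed with
#'   per-sample breakpoint burden, null-model coefficients and the
#'   top-ranked recurrent features and genes).
#' @method summary breakrec
#' @export
summary.breakrec <- function(object, n_top = 10L, ...) {
  bpm <- object$breakpoints
  top_feat <- object$feature[order(object$feature$p_value,
                                   -object$feature$observed), ]
  top_feat <- utils::head(top_feat[top_feat$observed > 0L, ], n_top)
  top_gene <- NULL
  if (!is.null(object$gene)) {
    top_gene <- object$gene[order(object$gene$p_value,
                                  -object$gene$observed), ]
    top_gene <- utils::head(top_gene, n_top)
  }
  structure(list(n_samples = length(bpm$sample_ids),
                 n_features = nrow(bpm$grid),
                 filter = object$params$filter,
                 burden = summary(as.numeric(bpm$per_sample_counts)),
                 coefficients = if (!is.null(object$null_model))
                   object$null_model$coefficients else NULL,
                 alpha = object$alpha,
                 n_sig_features = sum(object$feature$fdr < object$alpha),
                 n_sig_genes = if (!is.null(object$gene))
                   sum(object$gene$significant) else NA_integer_,
                 top_features = top_feat,
                 top_genes = top_gene),
            class = "summary.breakrec")
}

#' @export
print.summary.breakrec <- function(x, ...) {
  cat("Recurrent breakpoint analysis: ", x$n_samples, " samples, ",
      x$n_features, " features (filter: ", x$filter, ")\n\n", sep = "")
  cat("Per-sample breakpoint burden (N_s):\n")
  print(x$burden)
  if (!is.null(x$coefficients)) {
    cat("\nGene null model coefficients:\n")
    print(x$coefficients)
  }
  cat("\nSignificant at FDR < ", x$alpha, ": ", x$n_sig_features,
      " features", sep = "")
  if (!is.na(x$n_sig_genes)) cat(", ", x$n_sig_genes, " genes", sep = "")
  cat("\n\nTop recurrent features:\n")
  print(x$top_features, row.names = FALSE)
  if (!is.null(x$top_genes)) {
    cat("\nTop recurrent genes:\n")
    print(x$top_genes[, c("gene_id", "chromosome", "observed",
                          "p_value", "fdr", "significant")],
          row.names = FALSE)
  }
  invisible(x)
}

#' @method coef breakrec
#' @export
coef.breakrec <- function(object, ...) {
  if (is.null(object$null_model))
    stop("no gene null model was fitted (no gene annotation supplied)")
  object$null_model$coefficients
}

#' @export
fitted.breakrec <- function(object, ...) {
  if (is.null(object$null_model))
    stop("no gene null model was fitted (no gene annotation supplied)")
  object$null_model$probs
}

#' Breakpoint frequency plot
#'
#' Draws, for one chromosome, the per-feature breakpoint sample-frequency as
#' vertical bars at the feature positions, genes as horizontal red bars at
#' their genomic extents (at a height equal to the fraction of samples with a
#' breakpoint in the gene), and labels genes significant at the fit's FDR
#' level with their names.
#'
#' @param x a \code{"breakrec"} fit.
#' @param chromosome chromosome to draw; defaults to the chromosome carrying
#'   the most breakpoints.
#' @param xlim optional base-pair window within the chromosome.
#' @param alpha significance level for labeling; defaults to the fit's.
#' @param ... passed to \code{plot.default}.
#' @return invisibly, a list with the per-feature frequencies and the gene
#'   rows drawn.
#' @method plot breakrec
#' @export
plot.breakrec <- function(x, chromosome = NULL, xlim = NULL,
                          alpha = x$alpha, ...) {
  bpm <- x$breakpoints
  grid <- bpm$grid
  s <- length(bpm$sample_ids)
  if (is.null(chromosome)) {
    per_chrom <- tapply(rowSums(bpm$indicator), grid$chromosome, sum)
    chromosome <- names(per_chrom)[which.max(per_chrom)]
  }
  chromosome <- normalize_chromosome(chromosome)
  sel <- grid$chromosome == chromosome
  if (!any(sel)) {
    warning("no features on chromosome ", chromosome, "; empty plot")
    graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                   xlab = paste0("chromosome ", chromosome, " position (Mb)"),
                   ylab = "breakpoint frequency", ...)
    return(invisible(NULL))
  }
  pos <- grid$start[sel] / 1e6
  freq <- rowSums(bpm$indicator[sel, , drop = FALSE]) / s
  if (is.null(xlim)) xlim <- range(pos) else xlim <- xlim / 1e6
  gene_rows <- NULL
  ymax <- max(freq, 0.05)
  if (!is.null(x$gene)) {
    gene_rows <- x$gene[x$gene$chromosome == chromosome, , drop = FALSE]
    if (nrow(gene_rows))
      ymax <- max(ymax, gene_rows$observed / s)
  }
  graphics::plot(NA, xlim = xlim, ylim = c(0, ymax * 1.15),
                 xlab = paste0("chromosome ", chromosome, " position (Mb)"),
                 ylab = "breakpoint frequency", ...)
  graphics::segments(pos, 0, pos, freq, col = "black", lwd = 1)
  if (!is.null(gene_rows) && nrow(gene_rows)) {
    gy <- gene_rows$observed / s
    graphics::segments(gene_rows$start / 1e6, gy, gene_rows$end / 1e6, gy,
                       col = "red", lwd = 3)
    sig <- gene_rows$fdr < alpha
    if (any(sig))
      graphics::text((gene_rows$start[sig] + gene_rows$end[sig]) / 2e6,
                     gy[sig], labels = gene_rows$gene_name[sig],
                     pos = 3, cex = 0.8, col = "red")
  }
  invisible(list(position_mb = pos, frequency = freq, genes = gene_rows))
}
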