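#' Run the full analysis from files to result tables
#'
#' Orchestrates the complete workflow -- read inputs, detect and filter
#' breakpoints, map to genes, run the cohort statistics -- and writes the
#' result tables plus a JSON run manifest to \code{out_dir}.  Any stage
#' failure is re-raised with the stage name prepended and partial outputs
#' are removed, so an output directory is either complete or absent.
#'
#' Files written: \code{feature_results.tsv}, \code{gene_results.tsv} (if a
#' gene annotation was given), \code{breakpoints.tsv},
#' \code{breakpoints.bed}, and \code{manifest.json} recording package
#' version, parameters, input MD5 checksums and per-sample breakpoint
#' counts.
#'
#' @param segments path to the wide segmented TSV.
#' @param out_dir output directory (created if needed).
#' @param calls optional path to the parallel calls TSV.
#' @param genes optional gene annotation path.
#' @param genes_format \code{"bed"} or \code{"tsv"}.
#' @param dialect segmented file dialect, \code{"wide"} or \code{"long"}.
#' @param drop_sex drop X/Y features at load.
#' @param filter,threshold,map_mode,alpha,gene_fdr,n_mode,log_covariates,tol
#'   passed to \code{\link{breakrec}}.
#' @param plot_chromosome if non-NULL, also write
#'   \code{breakpoint_frequency.png} for this chromosome.
#' @return the \code{"breakrec"} fit, invisibly.
#' @export
run_pipeline <- function(segments, out_dir, calls = NULL, genes = NULL,
                         genes_format = c("bed", "tsv"),
                         dialect = c("wide", "long"), drop_sex = FALSE,
                         filter = "none", threshold = 0.2,
                         map_mode = "interval", alpha = 0.1,
                         gene_fdr = "gilbert", n_mode = "all",
                         log_covariates = FALSE, tol = 0,
                         plot_chromosome = NULL) {
  genes_format <- match.arg(genes_format)
  dialect <- match.arg(dialect)
  written <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  profiles <- stage("io", read_segmented_profiles(segments, dialect = dialect,
                                                  calls_path = calls,
                                                  drop_sex = drop_sex))
  annotation <- if (!is.null(genes))
    stage("io", read_gene_annotation(genes, format = genes_format)) else NULL
  fit <- stage("statistics",
               breakrec(profiles, annotation, filter = filter,
                        threshold = threshold, map_mode = map_mode,
                        alpha = alpha, gene_fdr = gene_fdr, n_mode = n_mode,
                        log_covariates = log_covariates, tol = tol))
  stage("export", {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    f <- file.path(out_dir, "feature_results.tsv")
    utils::write.table(fit$feature, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, f)
    if (!is.null(fit$gene)) {
      f <- file.path(out_dir, "gene_results.tsv")
      utils::write.table(fit$gene, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      written <- c(written, f)
    }
    f <- file.path(out_dir, "breakpoints.tsv")
    utils::write.table(fit$breakpoints$breakpoints, f, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written <- c(written, f)
    f <- file.path(out_dir, "breakpoints.bed")
    breakpoints_to_bed(fit$breakpoints, f)
    written <- c(written, f)
    if (!is.null(plot_chromosome)) {
      f <- file.path(out_dir, "breakpoint_frequency.png")
      grDevices::png(f, width = 1200, height = 500)
      plot(fit, chromosome = plot_chromosome)
      grDevices::dev.off()
      written <- c(written, f)
    }
    inputs <- c(segments = segments, calls = calls, genes = genes)
    manifest <- list(
      package = "breakrec",
      version = as.character(utils::packageVersion("breakrec")),
      parameters = c(fit$params, list(alpha = alpha, dialect = dialect,
                                      genes_format = genes_format,
                                      drop_sex = drop_sex)),
      inputs = as.list(unname(tools::md5sum(inputs))) |>
        stats::setNames(names(inputs)),
      n_features = nrow(fit$breakpoints$grid),
      per_sample_breakpoints = as.list(fit$breakpoints$per_sample_counts))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })
  invisible(fit)
}
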