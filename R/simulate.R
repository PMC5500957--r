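#' Configuration for synthetic copy number cohorts
#'
#' The generator emulates the input of the package -- already segmented
#' (piecewise-constant) log2-ratio profiles on a shared feature grid -- not
#' raw probe-level data: there is no probe noise, waviness or GC bias, which
#' all belong upstream of segmentation.  Features are placed with (nearly)
#' uniform spacing per chromosome, each sample draws a breakpoint burden N_s
#' and scatters segment boundaries uniformly over the eligible (non
#' chromosome-first) features, and optional planted genes force a boundary
#' inside their extent for a chosen fraction of samples (penetrance).
#' Adjacent segments alternate between copy-number-neutral and aberrant
#' (gain or loss) levels, so every planted boundary is a genuine level shift
#' and carries a discrete call change.
#'
#' @param n_samples number of tumor profiles.
#' @param n_features total features (probes/bins); must be at least
#'   \code{2 * n_chromosomes}.
#' @param n_chromosomes chromosomes 1..n (values above 22 become X, Y).
#' @param spacing_mean mean inter-feature spacing in bp (default 30 kb, a
#'   typical 105k array density).
#' @param spacing_jitter relative uniform jitter on spacing, in [0, 1).
#' @param feature_width feature extent in bp (default 60, an oligo probe).
#' @param breakpoint_range integer range; each sample's breakpoint burden
#'   N_s is drawn uniformly from \code{breakpoint_range[1]:breakpoint_range[2]}.
#' @param call_levels named numeric vector of segmented log2-ratio levels for
#'   \code{loss}, \code{neutral}, \code{gain}.  Defaults
#'   (-0.45, 0, 0.45) approximate single-copy changes with stromal admixture.
#' @param level_jitter_sd Gaussian jitter (sd, log2 units) added per segment
#'   level; 0 by default because segmented data are piecewise-constant.
#' @param n_genes number of background genes placed uniformly at random.
#' @param gene_length_range gene extent range in bp.
#' @param planted_genes optional \code{data.frame} with columns
#'   \code{chromosome}, \code{start}, \code{end}, \code{penetrance}; each row
#'   plants a recurrent breakpoint gene hit in
#'   \code{round(penetrance * n_samples)} samples.
#' @param seed integer RNG seed; the whole cohort is reproducible from it.
#' @return a validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_samples = 50L, n_features = 1000L,
                       n_chromosomes = 22L, spacing_mean = 30000,
                       spacing_jitter = 0.2, feature_width = 60L,
                       breakpoint_range = c(5L, 50L),
                       call_levels = c(loss = -0.45, neutral = 0, gain = 0.45),
                       level_jitter_sd = 0, n_genes = 200L,
                       gene_length_range = c(15000, 90000),
                       planted_genes = NULL, seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_features = as.integer(n_features),
              n_chromosomes = as.integer(n_chromosomes),
              spacing_mean = spacing_mean,
              spacing_jitter = spacing_jitter,
              feature_width = as.integer(feature_width),
              breakpoint_range = as.integer(breakpoint_range),
              call_levels = call_levels,
              level_jitter_sd = level_jitter_sd,
              n_genes = as.integer(n_genes),
              gene_length_range = gene_length_range,
              planted_genes = planted_genes,
              seed = as.integer(seed))
  stopifnot(cfg$n_samples >= 1L,
            cfg$n_features >= 2L * cfg$n_chromosomes,
            cfg$spacing_jitter >= 0, cfg$spacing_jitter < 1,
            length(cfg$breakpoint_range) == 2L,
            cfg$breakpoint_range[1L] >= 0L,
            cfg$breakpoint_range[2L] >= cfg$breakpoint_range[1L],
            all(c("loss", "neutral", "gain") %in% names(cfg$call_levels)))
  if (!is.null(planted_genes)) {
    stopifnot(is.data.frame(planted_genes),
              all(c("chromosome", "start", "end", "penetrance") %in%
                    names(planted_genes)),
              all(planted_genes$penetrance >= 0),
              all(planted_genes$penetrance <= 1))
  }
  class(cfg) <- "sim_config"
  cfg
}

.chromosome_label <- function(i) {
  ifelse(i <= 22L, as.character(i), c("X", "Y")[i - 22L])
}

#' Simulate a segmented copy number cohort with known breakpoints
#'
#' Generates a \code{\link{cnp_set}} (segmented values plus matching discrete
#' calls), a gene annotation (background genes plus any planted genes, the
#' latter with ids \code{PLANTED1..}), and the ground-truth breakpoint
#' placements per sample.  Ground truth uses the same convention as
#' \code{\link{detect_breakpoints}}: the grid index of the first feature of
#' each downstream segment.  On noise-free levels (the default) detection
#' recovers the truth exactly.
#'
#' The caller's RNG state is left untouched; all randomness derives from
#' \code{config$seed}.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a list of class \code{"sim_cohort"} with elements
#'   \code{profiles} (a \code{cnp_set}), \code{genes}
#'   (a \code{gene_annotation}), \code{truth} (per-sample integer vectors of
#'   breakpoint feature indices), \code{planted_carriers} (per planted gene,
#'   the sample ids forced to carry a hit) and \code{config}.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  ## feature grid: features split as evenly as possible over chromosomes
  per_chrom <- rep(config$n_features %/% config$n_chromosomes,
                   config$n_chromosomes)
  extra <- config$n_features %% config$n_chromosomes
  if (extra > 0L) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
  chrom <- rep(.chromosome_label(seq_len(config$n_chromosomes)), per_chrom)
  gaps <- round(config$spacing_mean *
                  stats::runif(config$n_features,
                               1 - config$spacing_jitter,
                               1 + config$spacing_jitter))
  gaps <- pmax(gaps, config$feature_width + 1L)
  start <- unlist(lapply(split(gaps, rep(seq_len(config$n_chromosomes),
                                         per_chrom)),
                         cumsum), use.names = FALSE)
  grid <- feature_grid(sprintf("F%05d", seq_len(config$n_features)),
                       chrom, start, start + config$feature_width - 1L)
  n <- nrow(grid)
  first <- chromosome_first(grid)
  eligible <- which(!first)

  ## genes: background placed uniformly; planted appended with known extents
  chrom_span <- tapply(grid$end, grid$chromosome, max)
  genes <- NULL
  if (config$n_genes > 0L) {
    gchrom <- sample(names(chrom_span), config$n_genes, replace = TRUE,
                     prob = as.numeric(chrom_span))
    glen <- round(stats::runif(config$n_genes, config$gene_length_range[1L],
                               config$gene_length_range[2L]))
    gstart <- round(stats::runif(config$n_genes, 1,
                                 pmax(1, as.numeric(chrom_span[gchrom]) - glen)))
    genes <- data.frame(gene_id = sprintf("GENE%04d", seq_len(config$n_genes)),
                        chromosome = gchrom, start = gstart,
                        end = gstart + glen - 1L, stringsAsFactors = FALSE)
  }
  planted <- config$planted_genes
  if (!is.null(planted) && nrow(planted)) {
    planted_df <- data.frame(gene_id = sprintf("PLANTED%d", seq_len(nrow(planted))),
                             chromosome = normalize_chromosome(planted$chromosome),
                             start = as.integer(planted$start),
                             end = as.integer(planted$end),
                             stringsAsFactors = FALSE)
    genes <- rbind(genes, planted_df)
  }
  annotation <- if (is.null(genes)) NULL else
    gene_annotation(genes$gene_id, genes$chromosome, genes$start, genes$end)

  ## per-sample boundaries: uniform background + forced planted hits
  sample_ids <- sprintf("S%03d", seq_len(config$n_samples))
  truth <- vector("list", config$n_samples)
  names(truth) <- sample_ids
  burden <- sample(seq(config$breakpoint_range[1L], config$breakpoint_range[2L]),
                   config$n_samples, replace = TRUE)
  for (s in seq_len(config$n_samples)) {
    truth[[s]] <- sort(sample(eligible, burden[s]))
  }
  planted_carriers <- list()
  if (!is.null(planted) && nrow(planted)) {
    for (k in seq_len(nrow(planted))) {
      ## a feature's breakpoint interval [prev end + 1, start] overlaps the
      ## gene iff gene.start <= feature.start and gene.end >= prev end + 1
      pc <- normalize_chromosome(planted$chromosome[k])
      cand <- eligible[grid$chromosome[eligible] == pc &
                         grid$start[eligible] >= planted$start[k] &
                         grid$end[eligible - 1L] + 1L <= planted$end[k]]
      if (!length(cand))
        stop("planted gene ", k, " overlaps no eligible breakpoint interval")
      n_carriers <- round(planted$penetrance[k] * config$n_samples)
      carriers <- sample(seq_len(config$n_samples), n_carriers)
      for (s in carriers) {
        truth[[s]] <- sort(union(truth[[s]],
                                 if (length(cand) == 1L) cand
                                 else sample(cand, 1L)))
      }
      planted_carriers[[sprintf("PLANTED%d", k)]] <- sample_ids[carriers]
    }
  }

  ## segment levels: alternate neutral / aberrant so adjacent segments always
  ## differ in both value and call
  seg <- matrix(0, n, config$n_samples)
  calls <- matrix(0L, n, config$n_samples)
  chrom_index <- match(grid$chromosome, unique(grid$chromosome))
  for (s in seq_len(config$n_samples)) {
    boundary <- logical(n)
    boundary[truth[[s]]] <- TRUE
    ## segment id: increments at chromosome starts and at boundaries
    seg_id <- cumsum(first | boundary)
    n_seg <- seg_id[n]
    state <- integer(n_seg)           # -1 loss, 0 neutral, +1 gain
    seg_first <- which(first | boundary)
    prev_state <- 0L
    prev_chrom <- 0L
    for (j in seq_len(n_seg)) {
      if (chrom_index[seg_first[j]] != prev_chrom) {
        state[j] <- 0L                 # each chromosome starts neutral
      } else if (prev_state == 0L) {
        state[j] <- sample(c(-1L, 1L), 1L)
      } else {
        state[j] <- 0L
      }
      prev_state <- state[j]
      prev_chrom <- chrom_index[seg_first[j]]
    }
    level <- unname(config$call_levels[c("loss", "neutral", "gain")][state + 2L])
    if (config$level_jitter_sd > 0)
      level <- level + stats::rnorm(n_seg, 0, config$level_jitter_sd)
    seg[, s] <- level[seg_id]
    calls[, s] <- state[seg_id]
  }
  profiles <- cnp_set(grid, seg, calls = calls, sample_ids = sample_ids)
  structure(list(profiles = profiles, genes = annotation, truth = truth,
                 planted_carriers = planted_carriers, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Simulated cohort (seed ", x$config$seed, "): ",
      length(x$profiles$sample_ids), " samples, ",
      nrow(x$profiles$grid), " features, ",
      if (is.null(x$genes)) 0L else nrow(x$genes), " genes\n", sep = "")
  cat("  planted genes: ", length(x$planted_carriers), "\n", sep = "")
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes the standard wide segmented TSV, the parallel calls TSV, the gene
#' annotation as BED and the ground-truth breakpoint placements as TSV
#' (columns \code{sample}, \code{feature_index}, \code{feature}).
#'
#' @param sim a \code{\link{simulate_cohort}} result.
#' @param dir output directory (created if absent).
#' @return the directory path, invisibly.
#' @export
write_simulated_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_segmented_profiles(sim$profiles,
                           file.path(dir, "segments.tsv"),
                           calls_path = file.path(dir, "calls.tsv"))
  if (!is.null(sim$genes))
    write_gene_annotation(sim$genes, file.path(dir, "genes.bed"),
                          format = "bed")
  truth <- data.frame(
    sample = rep(names(sim$truth), lengths(sim$truth)),
    feature_index = unlist(sim$truth, use.names = FALSE))
  truth$feature <- sim$profiles$grid$feature_id[truth$feature_index]
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
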