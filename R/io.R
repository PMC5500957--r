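#' @keywords internal
"_PACKAGE"

## Chromosome names are handled without a "chr" prefix throughout; ordering is
## the natural genomic order 1..22, X, Y, MT, then anything else alphabetically.

normalize_chromosome <- function(x) {
  sub("^chr", "", as.character(x), ignore.case = TRUE)
}

chromosome_rank <- function(x) {
  x <- normalize_chromosome(x)
  r <- suppressWarnings(as.numeric(x))
  r[x %in% c("X", "x")] <- 23
  r[x %in% c("Y", "y")] <- 24
  r[x %in% c("MT", "M", "mt")] <- 25
  other <- is.na(r)
  if (any(other)) {
    r[other] <- 25 + match(x[other], sort(unique(x[other])))
  }
  r
}

#' Construct an ordered genomic feature grid
#'
#' A feature grid holds the genomic positions of the measurement units of a
#' copy number platform -- microarray probes or fixed-width sequencing bins.
#' Candidate breakpoint positions are defined relative to this grid: a
#' breakpoint can sit between any two adjacent features of one chromosome.
#'
#' Features are sorted by (chromosome, start) with chromosomes in natural
#' order (1..22, X, Y).  Coordinates are 1-based and inclusive.  Duplicate
#' (chromosome, start) pairs and overlapping features are rejected because
#' they make the breakpoint interval between adjacent features ill-defined.
#'
#' @param feature_id character vector of unique feature identifiers.
#' @param chromosome chromosome per feature; a leading "chr" is stripped.
#' @param start,end integer base-pair positions, 1-based inclusive,
#'   \code{end >= start}.
#' @param drop_sex if \code{TRUE}, features on X and Y are removed.
#' @return a \code{data.frame} of class \code{"feature_grid"} with columns
#'   \code{feature_id}, \code{chromosome}, \code{start}, \code{end}, sorted
#'   into genomic order.
#' @export
feature_grid <- function(feature_id, chromosome, start, end, drop_sex = FALSE) {
  fid <- as.character(feature_id)
  chrom <- normalize_chromosome(chromosome)
  start <- as.integer(start)
  end <- as.integer(end)
  n <- length(fid)
  if (length(chrom) != n || length(start) != n || length(end) != n)
    stop("feature_id, chromosome, start and end must have equal length")
  if (anyNA(start) || anyNA(end) || anyNA(chrom))
    stop("feature coordinates must not contain missing values")
  if (any(end < start))
    stop("feature end must be >= start")
  if (anyDuplicated(fid))
    stop("duplicate feature_id: ", fid[duplicated(fid)][1L])
  if (drop_sex) {
    keep <- !(chrom %in% c("X", "Y"))
    fid <- fid[keep]; chrom <- chrom[keep]; start <- start[keep]; end <- end[keep]
  }
  o <- order(chromosome_rank(chrom), start)
  g <- data.frame(feature_id = fid[o], chromosome = chrom[o],
                  start = start[o], end = end[o], stringsAsFactors = FALSE)
  dup <- duplicated(g[, c("chromosome", "start")])
  if (any(dup))
    stop("duplicate (chromosome, start) position at feature ",
         g$feature_id[dup][1L])
  same <- g$chromosome[-1L] == g$chromosome[-nrow(g)]
  if (any(same & g$end[-nrow(g)] >= g$start[-1L]))
    stop("overlapping features within a chromosome; grid features must be disjoint")
  class(g) <- c("feature_grid", "data.frame")
  g
}

## TRUE for the first feature of each chromosome (can never host a breakpoint).
chromosome_first <- function(grid) {
  c(TRUE, grid$chromosome[-1L] != grid$chromosome[-nrow(grid)])
}

#' Bundle a feature grid with per-sample segmented copy number values
#'
#' The segmented matrix holds piecewise-constant log2-ratios as produced by a
#' segmentation algorithm (e.g. Circular Binary Segmentation) upstream of this
#' package; the optional calls matrix holds discrete copy number states
#' (-2 double loss, -1 loss, 0 neutral, +1 gain, +2 amplification).
#'
#' Features carrying a missing segmented value in any sample are dropped
#' cohort-wide (with a warning reporting the count), so that the total feature
#' count N -- the denominator of the per-sample null breakpoint probability --
#' is shared by all samples.
#'
#' @param grid a \code{\link{feature_grid}}.
#' @param segmented numeric matrix, features x samples, in grid row order.
#' @param calls optional integer matrix of the same shape with values in
#'   -2..2.
#' @param sample_ids sample names; defaults to \code{colnames(segmented)}.
#' @return an object of class \code{"cnp_set"}: a list with elements
#'   \code{grid}, \code{sample_ids}, \code{segmented}, \code{calls}.
#' @export
cnp_set <- function(grid, segmented, calls = NULL, sample_ids = colnames(segmented)) {
  stopifnot(inherits(grid, "feature_grid"))
  segmented <- as.matrix(segmented)
  if (!is.numeric(segmented))
    stop("segmented values must be numeric")
  if (nrow(segmented) != nrow(grid))
    stop("segmented has ", nrow(segmented), " rows but grid has ",
         nrow(grid), " features")
  if (is.null(sample_ids))
    sample_ids <- sprintf("sample%02d", seq_len(ncol(segmented)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != ncol(segmented) || anyDuplicated(sample_ids))
    stop("sample_ids must be unique and match the number of sample columns")
  if (!is.null(calls)) {
    calls <- as.matrix(calls)
    if (!all(dim(calls) == dim(segmented)))
      stop("calls matrix dimensions (", nrow(calls), " x ", ncol(calls),
           ") do not match segmented (", nrow(segmented), " x ",
           ncol(segmented), ")")
    storage.mode(calls) <- "integer"
    if (!all(calls[!is.na(calls)] %in% -2:2))
      stop("discrete calls must be integers in -2..2")
  }
  incomplete <- rowSums(is.na(segmented)) > 0L
  if (any(incomplete)) {
    warning("dropped ", sum(incomplete),
            " feature(s) with missing segmented values (cohort-wide)")
    grid <- grid[!incomplete, , drop = FALSE]
    class(grid) <- c("feature_grid", "data.frame")
    segmented <- segmented[!incomplete, , drop = FALSE]
    if (!is.null(calls)) calls <- calls[!incomplete, , drop = FALSE]
  }
  if (nrow(grid) == 0L)
    stop("no features left after dropping incomplete rows")
  dimnames(segmented) <- list(grid$feature_id, sample_ids)
  if (!is.null(calls)) dimnames(calls) <- dimnames(segmented)
  structure(list(grid = grid, sample_ids = sample_ids,
                 segmented = segmented, calls = calls),
            class = "cnp_set")
}

#' @export
print.cnp_set <- function(x, ...) {
  cat("Segmented copy number profiles\n")
  cat("  features: ", nrow(x$grid), " on ",
      length(unique(x$grid$chromosome)), " chromosome(s)\n", sep = "")
  cat("  samples:  ", length(x$sample_ids), "\n", sep = "")
  cat("  calls:    ", if (is.null(x$calls)) "absent" else "present", "\n", sep = "")
  invisible(x)
}

## Locate required columns by (case-insensitive) name; error with the file
## path so loader failures are actionable.
.require_cols <- function(df, cols, path) {
  idx <- match(cols, tolower(names(df)))
  if (anyNA(idx))
    stop("file ", path, " is missing required column(s): ",
         paste(cols[is.na(idx)], collapse = ", "))
  idx
}

#' Read segmented copy number profiles from TSV
#'
#' Two dialects are supported.  \code{wide}: one row per feature with columns
#' \code{feature}, \code{chromosome}, \code{start}, \code{end} followed by one
#' column of segmented log2-ratios per sample; discrete calls may be supplied
#' as a parallel wide file via \code{calls_path}.  \code{long}: one row per
#' (feature, sample) with columns \code{feature}, \code{chromosome},
#' \code{start}, \code{end}, \code{sample}, \code{segmented} and optionally
#' \code{call}.
#'
#' Rows are sorted into genomic order on load, so file order does not matter.
#' Non-numeric segmented values and dimension mismatches between the
#' segmented and calls files are hard errors.
#'
#' @param path TSV file with header.
#' @param dialect \code{"wide"} or \code{"long"}.
#' @param calls_path optional wide TSV of discrete calls (wide dialect only).
#' @param drop_sex drop features on chromosomes X and Y.
#' @return a \code{\link{cnp_set}}.
#' @export
read_segmented_profiles <- function(path, dialect = c("wide", "long"),
                                    calls_path = NULL, drop_sex = FALSE) {
  dialect <- match.arg(dialect)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (dialect == "wide") {
    meta <- .require_cols(df, c("feature", "chromosome", "start", "end"), path)
    sample_cols <- setdiff(seq_along(df), meta)
    if (length(sample_cols) == 0L)
      stop("file ", path, " contains no sample columns")
    for (j in sample_cols) {
      v <- df[[j]]
      if (is.character(v)) {
        bad <- which(!is.na(v) & is.na(suppressWarnings(as.numeric(v))))
        if (length(bad))
          stop("non-numeric segmented value '", v[bad[1L]], "' in column '",
               names(df)[j], "', row ", bad[1L], " of ", path)
        df[[j]] <- as.numeric(v)
      }
    }
    grid <- feature_grid(df[[meta[1L]]], df[[meta[2L]]], df[[meta[3L]]],
                         df[[meta[4L]]], drop_sex = drop_sex)
    o <- match(grid$feature_id, df[[meta[1L]]])
    seg <- as.matrix(df[o, sample_cols, drop = FALSE])
    colnames(seg) <- names(df)[sample_cols]
    calls <- NULL
    if (!is.null(calls_path)) {
      cf <- utils::read.delim(calls_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE, check.names = FALSE)
      cmeta <- .require_cols(cf, c("feature", "chromosome", "start", "end"),
                             calls_path)
      ccols <- setdiff(seq_along(cf), cmeta)
      if (!identical(sort(names(cf)[ccols]), sort(names(df)[sample_cols])) ||
          nrow(cf) != nrow(df))
        stop("calls file ", calls_path,
             " does not match the segmented file dimensions/samples")
      co <- match(grid$feature_id, cf[[cmeta[1L]]])
      if (anyNA(co))
        stop("calls file ", calls_path, " is missing features present in ", path)
      calls <- as.matrix(cf[co, names(df)[sample_cols], drop = FALSE])
    }
    cnp_set(grid, seg, calls = calls, sample_ids = names(df)[sample_cols])
  } else {
    idx <- .require_cols(df, c("feature", "chromosome", "start", "end",
                               "sample", "segmented"), path)
    has_call <- "call" %in% tolower(names(df))
    v <- df[[idx[6L]]]
    if (is.character(v)) {
      bad <- which(!is.na(v) & is.na(suppressWarnings(as.numeric(v))))
      if (length(bad))
        stop("non-numeric segmented value '", v[bad[1L]], "' in row ",
             bad[1L], " of ", path)
      df[[idx[6L]]] <- as.numeric(v)
    }
    feat <- df[[idx[1L]]]
    samp <- as.character(df[[idx[5L]]])
    ufeat <- !duplicated(feat)
    grid <- feature_grid(feat[ufeat], df[[idx[2L]]][ufeat],
                         df[[idx[3L]]][ufeat], df[[idx[4L]]][ufeat],
                         drop_sex = drop_sex)
    samples <- unique(samp)
    seg <- matrix(NA_real_, nrow(grid), length(samples),
                  dimnames = list(grid$feature_id, samples))
    seg[cbind(match(feat, grid$feature_id), match(samp, samples))] <- df[[idx[6L]]]
    calls <- NULL
    if (has_call) {
      ci <- match("call", tolower(names(df)))
      calls <- matrix(NA_integer_, nrow(grid), length(samples),
                      dimnames = dimnames(seg))
      calls[cbind(match(feat, grid$feature_id), match(samp, samples))] <-
        as.integer(df[[ci]])
    }
    cnp_set(grid, seg, calls = calls, sample_ids = samples)
  }
}

#' Write segmented profiles (and calls) as wide TSV
#'
#' Inverse of \code{\link{read_segmented_profiles}} (wide dialect):
#' reading the written file returns an identical object.
#'
#' @param x a \code{\link{cnp_set}}.
#' @param path output TSV for segmented values.
#' @param calls_path optional output TSV for discrete calls.
#' @return \code{path}, invisibly.
#' @export
write_segmented_profiles <- function(x, path, calls_path = NULL) {
  stopifnot(inherits(x, "cnp_set"))
  out <- data.frame(feature = x$grid$feature_id,
                    chromosome = x$grid$chromosome,
                    start = x$grid$start, end = x$grid$end,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- cbind(out, as.data.frame(x$segmented, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(calls_path)) {
    if (is.null(x$calls)) stop("profile set has no calls to write")
    outc <- cbind(out[, 1:4], as.data.frame(x$calls, check.names = FALSE))
    utils::write.table(outc, calls_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a gene annotation from BED or TSV
#'
#' BED input (\code{format = "bed"}) is 0-based half-open and is converted to
#' the package's internal 1-based inclusive coordinates on read; columns are
#' chrom, start, end, name (BED4, no header).  TSV input is 1-based inclusive
#' with a header declaring columns \code{gene_id}, \code{chromosome},
#' \code{start}, \code{end} and optionally \code{gene_name}.
#'
#' @param path annotation file.
#' @param format \code{"bed"} or \code{"tsv"}.
#' @return a \code{data.frame} of class \code{"gene_annotation"} with columns
#'   \code{gene_id}, \code{gene_name}, \code{chromosome}, \code{start},
#'   \code{end}.
#' @export
read_gene_annotation <- function(path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  if (format == "bed") {
    df <- utils::read.delim(path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)
    if (ncol(df) < 4L)
      stop("BED gene annotation requires at least 4 columns (chrom, start, end, name)")
    g <- gene_annotation(gene_id = df[[4L]], chromosome = df[[1L]],
                         start = as.integer(df[[2L]]) + 1L,
                         end = as.integer(df[[3L]]))
  } else {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    idx <- .require_cols(df, c("gene_id", "chromosome", "start", "end"), path)
    name_i <- match("gene_name", tolower(names(df)))
    g <- gene_annotation(gene_id = df[[idx[1L]]],
                         gene_name = if (!is.na(name_i)) df[[name_i]] else NULL,
                         chromosome = df[[idx[2L]]],
                         start = as.integer(df[[idx[3L]]]),
                         end = as.integer(df[[idx[4L]]]))
  }
  g
}

#' Construct a gene annotation table
#'
#' @param gene_id unique gene identifiers.
#' @param chromosome,start,end gene extents, 1-based inclusive.
#' @param gene_name display names; defaults to \code{gene_id}.
#' @return a \code{data.frame} of class \code{"gene_annotation"}.
#' @export
gene_annotation <- function(gene_id, chromosome, start, end, gene_name = NULL) {
  gene_id <- as.character(gene_id)
  if (is.null(gene_name)) gene_name <- gene_id
  start <- as.integer(start); end <- as.integer(end)
  if (anyDuplicated(gene_id))
    stop("duplicate gene_id: ", gene_id[duplicated(gene_id)][1L])
  if (any(end < start))
    stop("gene end < start for ", gene_id[which(end < start)[1L]])
  g <- data.frame(gene_id = gene_id, gene_name = as.character(gene_name),
                  chromosome = normalize_chromosome(chromosome),
                  start = start, end = end, stringsAsFactors = FALSE)
  class(g) <- c("gene_annotation", "data.frame")
  g
}

#' Write a gene annotation as BED4 or TSV
#'
#' @param genes a \code{\link{gene_annotation}}.
#' @param path output file.
#' @param format \code{"bed"} (coordinates converted to 0-based half-open) or
#'   \code{"tsv"} (1-based inclusive with header).
#' @return \code{path}, invisibly.
#' @export
write_gene_annotation <- function(genes, path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  if (format == "bed") {
    out <- data.frame(genes$chromosome, genes$start - 1L, genes$end,
                      genes$gene_id)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    out <- genes[, c("gene_id", "gene_name", "chromosome", "start", "end")]
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
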