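#' Per-sample depth mask
#'
#' The set of genomic coordinates at which a sample's aligned read depth
#' reaches a threshold (default 10x, the depth at which a variant is
#' considered detectable). Internally stored as a reduced
#' [GenomicRanges::GRanges] in the 1-based closed convention that
#' GenomicRanges defines; BED I/O converts to/from 0-based half-open
#' coordinates in [read_depth_mask()] / [write_depth_mask()] only.
#'
#' @param sample_id sample the mask belongs to.
#' @param chrom,start,end parallel vectors of intervals, 1-based closed.
#'   Overlapping or adjacent intervals are merged.
#' @param threshold integer depth threshold the mask was built at.
#' @return An object of class `depth_mask`.
#' @export
depth_mask <- function(sample_id, chrom, start, end, threshold = 10L) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (length(start) && any(start < 1L))
    stop("mask interval with non-positive start coordinate")
  if (length(start) && any(end < start))
    stop("mask interval with end < start")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  gr <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  structure(list(sample_id = sample_id, threshold = as.integer(threshold),
                 ranges = gr),
            class = "depth_mask")
}

#' @export
print.depth_mask <- function(x, ...) {
  cat("depth_mask:", x$sample_id, "(depth >=", x$threshold, "x),",
      length(x$ranges), "intervals,", mask_length(x), "bp\n")
  invisible(x)
}

#' Total number of coordinates covered by a mask
#' @param mask a [depth_mask()] (or a bare `GRanges`).
#' @return integer-valued numeric, exact.
#' @export
mask_length <- function(mask) {
  gr <- if (inherits(mask, "depth_mask")) mask$ranges else mask
  sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(gr))))
}

# the single place where BED (0-based half-open) meets the internal
# (1-based closed) convention: pos_bed = pos - 1
.bed_to_closed <- function(start0, end0) list(start = start0 + 1L, end = end0)
.closed_to_bed <- function(start1, end1) list(start = start1 - 1L, end = end1)

#' Read / write a depth mask in BED format
#'
#' BED3 (`chrom`, `start`, `end`; 0-based half-open). An optional
#' `#threshold=<int>` header line records the depth threshold; the sample id
#' defaults to the file's base name. Unsorted input is sorted with a warning;
#' overlapping intervals are merged; negative coordinates are fatal.
#'
#' @param path BED file path.
#' @param sample_id sample id to attach (default: file base name).
#' @param threshold depth threshold if not recorded in the file header.
#' @return [read_depth_mask()] returns a [depth_mask()];
#'   [write_depth_mask()] returns `path` invisibly. The write/read round
#'   trip reproduces the interval set exactly.
#' @export
read_depth_mask <- function(path, sample_id = NULL, threshold = 10L) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  th <- sub("^#threshold=", "", grep("^#threshold=", hdr, value = TRUE))
  if (length(th)) threshold <- as.integer(th[1])
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (is.null(sample_id))
    sample_id <- sub("\\.bed$", "", basename(path))
  if (!length(body))
    return(depth_mask(sample_id, character(), integer(), integer(), threshold))
  parts <- strsplit(body, "\t", fixed = TRUE)
  chrom <- vapply(parts, `[`, "", 1L)
  start0 <- as.integer(vapply(parts, `[`, "", 2L))
  end0 <- as.integer(vapply(parts, `[`, "", 3L))
  if (anyNA(start0) || anyNA(end0)) stop("malformed BED coordinates in ", path)
  if (any(start0 < 0L)) stop("negative BED coordinate in ", path)
  o <- order(chrom, start0)
  if (!identical(o, seq_along(o))) {
    warning("unsorted BED input in ", path, "; sorting")
    chrom <- chrom[o]; start0 <- start0[o]; end0 <- end0[o]
  }
  cc <- .bed_to_closed(start0, end0)
  depth_mask(sample_id, chrom, cc$start, cc$end, threshold)
}

#' @rdname read_depth_mask
#' @param mask a [depth_mask()].
#' @export
write_depth_mask <- function(mask, path) {
  gr <- mask$ranges
  cc <- .closed_to_bed(GenomicRanges::start(gr), GenomicRanges::end(gr))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#threshold=", mask$threshold), con)
  if (length(gr))
    writeLines(paste(as.character(GenomicRanges::seqnames(gr)),
                     cc$start, cc$end, sep = "\t"), con)
  invisible(path)
}

#' Restrict a mask to a set of chromosomes
#' @param mask a [depth_mask()].
#' @param chroms chromosome names to keep.
#' @return a [depth_mask()].
#' @export
mask_keep_chroms <- function(mask, chroms) {
  gr <- mask$ranges
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) %in% chroms]
  structure(list(sample_id = mask$sample_id, threshold = mask$threshold,
                 ranges = gr), class = "depth_mask")
}
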