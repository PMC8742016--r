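#' Callable coordinates of a parent-offspring trio
#'
#' A coordinate is callable for a trio when the mother, the father and the
#' focal offspring all reach the depth threshold there, i.e. the exact
#' three-way intersection of the per-sample depth masks.
#'
#' @param mother_mask,father_mask,focal_mask [depth_mask()] objects built at
#'   the same threshold over the same chromosome universe.
#' @param ranges if `TRUE`, return the intersection `GRanges` instead of
#'   its size.
#' @return coordinate count (numeric, exact) or a `GRanges`.
#' @examples
#' m <- depth_mask("m", "1", 1, 100)
#' f <- depth_mask("f", "1", 51, 150)
#' o <- depth_mask("o", "1", 81, 120)
#' trio_callable(m, f, o)  # [81,100] -> 20
#' @export
trio_callable <- function(mother_mask, father_mask, focal_mask,
                          ranges = FALSE) {
  ms <- list(mother_mask, father_mask, focal_mask)
  th <- vapply(ms, function(m) m$threshold, 1L)
  if (length(unique(th)) != 1L)
    stop("masks built at different thresholds: ",
         paste(unique(th), collapse = ", "))
  universe <- lapply(ms, function(m)
    GenomeInfoDb::seqlevels(m$ranges))
  if (length(unique(vapply(universe, function(u)
    paste(sort(u), collapse = ","), ""))) != 1L)
    stop("masks cover different chromosome universes")
  gr <- GenomicRanges::intersect(
    GenomicRanges::intersect(ms[[1]]$ranges, ms[[2]]$ranges),
    ms[[3]]$ranges)
  if (ranges) gr else mask_length(gr)
}

#' Remove failed variant coordinates from a trio's callable set
#'
#' Coordinates reported by the joint variant caller that did not survive the
#' filtering regime have proven un-callable and are removed from the trio's
#' callable set; surviving candidate coordinates remain callable.
#'
#' @param callable a `GRanges` of the trio's callable coordinates (from
#'   `trio_callable(..., ranges = TRUE)`).
#' @param variant_coords data.frame with `chrom`, `pos` (1-based) of all
#'   variant-caller-reported sites.
#' @param candidate_coords data.frame with `chrom`, `pos` of the surviving
#'   candidate mutations (must be a subset of `variant_coords`).
#' @return the adjusted `GRanges`.
#' @export
subtract_failed_variant_sites <- function(callable, variant_coords,
                                          candidate_coords = NULL) {
  if (nrow(variant_coords) == 0L) return(callable)
  key <- paste(variant_coords$chrom, variant_coords$pos)
  if (!is.null(candidate_coords) && nrow(candidate_coords)) {
    ckey <- paste(candidate_coords$chrom, candidate_coords$pos)
    if (!all(ckey %in% key))
      stop("candidate coordinates must be a subset of variant coordinates")
    keep <- !(key %in% ckey)
    variant_coords <- variant_coords[keep, , drop = FALSE]
  }
  if (nrow(variant_coords) == 0L) return(callable)
  drop_gr <- GenomicRanges::GRanges(
    variant_coords$chrom,
    IRanges::IRanges(variant_coords$pos, variant_coords$pos))
  suppressWarnings(GenomicRanges::setdiff(callable, drop_gr))
}

#' Total callable sites across trios, doubled for diploidy
#'
#' Per-trio adjusted callable counts are summed over focal offspring and the
#' total is doubled exactly once to account for the two chromosome copies
#' screened per individual.
#'
#' @param per_trio numeric vector of per-trio callable counts.
#' @return `C = 2 * sum(per_trio)`.
#' @export
total_callable <- function(per_trio) {
  stopifnot(length(per_trio) >= 1L)
  2 * sum(as.numeric(per_trio))
}

#' Callable-site summary for the whole pedigree
#'
#' Runs [trio_callable()] for every focal offspring against the parents,
#' removes failed variant coordinates per trio with
#' [subtract_failed_variant_sites()], and totals with [total_callable()].
#' With `sex_aware_x = TRUE` the callable X coordinates of male focal
#' offspring are counted once instead of twice (they carry a single X);
#' the default keeps the uniform doubling.
#'
#' @param masks named list of [depth_mask()] (all samples).
#' @param manifest a [sample_manifest()] with a confirmed father.
#' @param records the joint-call [site_records()] (for the failed-variant
#'   removal); `NULL` to skip removal.
#' @param candidates the surviving candidates data.frame (or `NULL`).
#' @param ploidy a [ploidy_map()]; required for `sex_aware_x`.
#' @param sex_aware_x count male-focal X coordinates once (default `FALSE`:
#'   uniform doubling of every callable coordinate).
#' @return list of class `callable_summary`: `per_trio` (data.frame with
#'   `focal`, `callable_raw`, `removed`, `callable`), `total` (the doubled
#'   total C), `doubling_factor` (recorded explicitly).
#' @export
callable_summary <- function(masks, manifest, records = NULL,
                             candidates = NULL, ploidy = NULL,
                             sex_aware_x = FALSE) {
  mom <- mother_id(manifest); dad <- confirmed_father(manifest)
  foc <- focal_ids(manifest)
  sexes <- stats::setNames(manifest$sex, manifest$sample_id)
  if (sex_aware_x && is.null(ploidy))
    stop("sex_aware_x requires a ploidy map")
  variant_coords <- if (!is.null(records))
    data.frame(chrom = records$chrom, pos = records$pos,
               stringsAsFactors = FALSE)
  else data.frame(chrom = character(), pos = integer())
  per <- data.frame(focal = foc, callable_raw = NA_real_,
                    removed = NA_real_, callable = NA_real_,
                    contribution = NA_real_, stringsAsFactors = FALSE)
  # mother x father intersection and the variant-coordinate set are shared
  # across trios and computed once; the removal step is done by overlap
  # counting (equivalent to a positionwise setdiff for width-1 removals,
  # covered by the test against subtract_failed_variant_sites)
  parents_gr <- GenomicRanges::intersect(masks[[mom]]$ranges,
                                         masks[[dad]]$ranges)
  var_gr <- if (nrow(variant_coords)) {
    vu <- unique(variant_coords[, c("chrom", "pos")])
    # width-1 ranges kept unmerged so each coordinate is counted once
    GenomicRanges::GRanges(vu$chrom, IRanges::IRanges(vu$pos, vu$pos))
  } else NULL
  x_chroms <- if (!is.null(ploidy)) ploidy$chrom[ploidy$class == "X"]
  else character()
  for (k in seq_along(foc)) {
    gr <- GenomicRanges::intersect(parents_gr, masks[[foc[k]]]$ranges)
    raw <- mask_length(gr)
    cand_k <- if (!is.null(candidates) && nrow(candidates))
      candidates[candidates$carrier == foc[k], c("chrom", "pos"), drop = FALSE]
    else NULL
    removed <- 0; removed_x <- 0
    if (!is.null(var_gr)) {
      inside <- suppressWarnings(IRanges::overlapsAny(var_gr, gr))
      keep_key <- if (!is.null(cand_k) && nrow(cand_k))
        paste(cand_k$chrom, cand_k$pos) else character()
      vk <- paste(as.character(GenomicRanges::seqnames(var_gr)),
                  GenomicRanges::start(var_gr))
      drop <- inside & !(vk %in% keep_key)
      removed <- sum(drop)
      removed_x <- sum(drop & as.character(
        GenomicRanges::seqnames(var_gr)) %in% x_chroms)
    }
    n_adj <- raw - removed
    per$callable_raw[k] <- raw
    per$removed[k] <- removed
    per$callable[k] <- n_adj
    contribution <- 2 * n_adj
    if (sex_aware_x && sexes[foc[k]] == "male") {
      x_len <- mask_length(gr[as.character(
        GenomicRanges::seqnames(gr)) %in% x_chroms]) - removed_x
      contribution <- contribution - x_len
    }
    per$contribution[k] <- contribution
  }
  total <- if (sex_aware_x) sum(per$contribution) else
    total_callable(per$callable)
  structure(list(per_trio = per, total = total, doubling_factor = 2L,
                 sex_aware_x = sex_aware_x),
            class = "callable_summary")
}

#' @export
print.callable_summary <- function(x, ...) {
  cat("callable_summary: total C =", format(x$total, big.mark = ","),
      "(x", x$doubling_factor, "diploid doubling",
      if (x$sex_aware_x) ", sex-aware X" else "", ")\n", sep = " ")
  print(x$per_trio, row.names = FALSE, ...)
  invisible(x)
}
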