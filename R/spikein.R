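#' Empirical alternate-allele depth distributions at heterozygous sites
#'
#' At autosomal biallelic sites where the two parents are homozygous for
#' different alleles, Mendelian inheritance forces every offspring to be
#' heterozygous. Each offspring's `(DP, AD_ALT)` observation at such a site,
#' with `DP` inside `dp_range` (default 10-100), contributes to a per-depth
#' frequency table of alternate-read counts. These tables drive the number
#' of reads altered when spiking synthetic mutations, so spiked allele
#' balances match the data's real heterozygote behaviour.
#'
#' @param records a [site_records()] object.
#' @param manifest a [sample_manifest()] with a confirmed father.
#' @param ploidy a [ploidy_map()].
#' @param dp_range inclusive total-depth range of the tables.
#' @return object of class `ad_distribution`: a list with `tables` (named
#'   list, one integer frequency table per observed depth) and `n_obs`
#'   (observations per depth; depths with zero observations are empty and
#'   sampling from them falls back to `Binomial(d, 0.5)`).
#' @export
build_ad_distributions <- function(records, manifest, ploidy,
                                   dp_range = c(10L, 100L)) {
  mom <- mother_id(manifest); dad <- confirmed_father(manifest)
  offs <- c(focal_ids(manifest), bait_ids(manifest))
  rec <- .autosomal_biallelic(records, ploidy)
  gm <- rec$gt[, mom]; gd <- rec$gt[, dad]
  opp <- !is.na(gm) & !is.na(gd) &
    ((gm == 0L & gd == 2L) | (gm == 2L & gd == 0L))
  dp <- rec$dp[opp, offs, drop = FALSE]
  ad <- rec$ad_alt[opp, offs, drop = FALSE]
  ok <- !is.na(dp) & !is.na(ad) & dp >= dp_range[1] & dp <= dp_range[2]
  dpv <- dp[ok]; adv <- ad[ok]
  depths <- seq.int(dp_range[1], dp_range[2])
  tables <- stats::setNames(vector("list", length(depths)),
                            as.character(depths))
  n_obs <- stats::setNames(integer(length(depths)), as.character(depths))
  for (d in depths) {
    v <- adv[dpv == d]
    n_obs[as.character(d)] <- length(v)
    if (length(v)) tables[[as.character(d)]] <- table(v)
  }
  structure(list(tables = tables, n_obs = n_obs, dp_range = dp_range,
                 n_total = length(dpv)),
            class = "ad_distribution")
}

#' @export
print.ad_distribution <- function(x, ...) {
  cat("ad_distribution:", x$n_total, "heterozygous observations over depths",
      x$dp_range[1], "-", x$dp_range[2], "(",
      sum(x$n_obs > 0), "non-empty depth bins )\n")
  invisible(x)
}

#' Draw alternate-read counts from an empirical depth-matched distribution
#'
#' Samples from the empirical table for depth `d`; depths with no
#' observations (or outside the table range) fall back to
#' `Binomial(d, 0.5)`, the exact heterozygote expectation.
#'
#' @param dist an [build_ad_distributions()] object.
#' @param d total depths (vector).
#' @return integer vector of alternate-read counts, one per element of `d`.
#' @export
sample_ad <- function(dist, d) {
  vapply(d, function(di) {
    tab <- dist$tables[[as.character(di)]]
    if (is.null(tab)) {
      stats::rbinom(1L, di, 0.5)
    } else {
      vals <- as.integer(names(tab))
      vals[sample.int(length(vals), 1L, prob = as.numeric(tab))]
    }
  }, 1L)
}

#' Spike synthetic mutations into one focal offspring's allele counts
#'
#' Chooses `n` distinct autosomal coordinates uniformly among coordinates
#' where both parents reach the mask depth threshold and no variant record
#' exists, and appends one new record per coordinate in which the focal
#' sample carries `AD_ALT = N` alternate reads (`N` drawn from the
#' depth-matched empirical table) of a random alternate base, with the
#' genotype re-called by [call_genotypes()]. Depths of all samples at the
#' new records are resampled from their own observed record depths
#' (parents conditionally on reaching the threshold, matching the
#' coordinate choice); non-carrier samples receive alternate reads at rate
#' `bg_alt_rate` (0 gives deterministic `AD_ALT = 0`; passing the dataset's
#' per-read error rate reproduces the stray-read veto channels of criteria
#' i-iii). Focal depths above the distribution's upper range are not spiked
#' (depth resampling is restricted to the range). All other samples' fields
#' at pre-existing records are untouched. Reproducible from `seed`.
#'
#' @param records a [site_records()] object.
#' @param masks named list of [depth_mask()] including both parents.
#' @param manifest a [sample_manifest()] with a confirmed father.
#' @param ploidy a [ploidy_map()].
#' @param focal focal sample id to spike.
#' @param n number of synthetic mutations (default 1000).
#' @param dist an [build_ad_distributions()] object (built from `records`
#'   if `NULL`).
#' @param bg_alt_rate background alternate-read rate for non-carrier
#'   samples at spiked records.
#' @param error_rate,min_call_depth genotype-calling parameters (must match
#'   the main analysis).
#' @param exclude optional data.frame (`chrom`, `pos`) of coordinates never
#'   to reuse (e.g. spikes already placed in other focal samples).
#' @param seed optional integer seed.
#' @return list with `records` (original plus spiked records) and `spikes`
#'   (data.frame: `carrier`, `chrom`, `pos`, `ref`, `alt`, `n_alt`, `dp`,
#'   `callable` = focal DP at or above the mask threshold).
#' @export
spike_mutations <- function(records, masks, manifest, ploidy, focal,
                            n = 1000L, dist = NULL, bg_alt_rate = 0,
                            error_rate = 5e-4, min_call_depth = 4L,
                            exclude = NULL, seed = NULL) {
  stopifnot(n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dist)) dist <- build_ad_distributions(records, manifest, ploidy)
  mom <- mother_id(manifest); dad <- confirmed_father(manifest)
  min_dp <- masks[[mom]]$threshold
  autos <- autosome_names(ploidy)

  pool <- GenomicRanges::intersect(
    mask_keep_chroms(masks[[mom]], autos)$ranges,
    mask_keep_chroms(masks[[dad]], autos)$ranges)
  taken <- data.frame(chrom = records$chrom, pos = records$pos)
  if (!is.null(exclude) && nrow(exclude))
    taken <- rbind(taken, exclude[, c("chrom", "pos")])
  taken_gr <- GenomicRanges::GRanges(taken$chrom,
                                     IRanges::IRanges(taken$pos, taken$pos))
  pool <- suppressWarnings(GenomicRanges::setdiff(pool, taken_gr))
  w <- as.numeric(GenomicRanges::width(pool))
  total <- sum(w)
  if (total < n)
    stop("only ", total, " qualifying coordinates available for ", n,
         " synthetic mutations")
  cc <- .sample_pool_coords(pool, n)
  sp <- .spike_at(records, manifest, cc$chrom, cc$pos, focal, dist,
                  bg_alt_rate, error_rate, min_call_depth, min_dp,
                  auto_rows = records$chrom %in% autos)
  list(records = bind_records(records, sp$records), spikes = sp$spikes)
}

# uniform draw of n distinct coordinates from a reduced GRanges pool
.sample_pool_coords <- function(pool, n) {
  w <- as.numeric(GenomicRanges::width(pool))
  off <- sort(sample.int(sum(w), n))
  cum <- c(0, cumsum(w))
  iv <- findInterval(off - 0.5, cum)
  list(chrom = as.character(GenomicRanges::seqnames(pool))[iv],
       pos = GenomicRanges::start(pool)[iv] + as.integer(off - cum[iv]) - 1L)
}

# build spiked records for one focal sample at given coordinates; depth
# resampling pools are restricted to autosomal records (male X depths differ)
.spike_at <- function(records, manifest, chrom, pos, focal, dist,
                      bg_alt_rate, error_rate, min_call_depth, min_dp,
                      auto_rows = rep(TRUE, n_sites(records))) {
  n <- length(pos)
  mom <- mother_id(manifest); dad <- confirmed_father(manifest)
  ids <- record_samples(records)
  dp_pool <- function(s, at_least = 0L, at_most = Inf) {
    v <- records$dp[auto_rows, s]
    v <- v[!is.na(v) & v >= at_least & v <= at_most]
    if (!length(v)) v <- records$dp[!is.na(records$dp[, s]), s]
    v
  }
  resample <- function(v, k) v[sample.int(length(v), k, replace = TRUE)]
  dp_f <- resample(dp_pool(focal, at_most = dist$dp_range[2]), n)
  n_alt <- sample_ad(dist, dp_f)

  ref <- .rand_base(n)
  alt <- .rand_alt(ref)
  gt <- matrix(NA_integer_, n, length(ids), dimnames = list(NULL, ids))
  dp <- matrix(NA_integer_, n, length(ids), dimnames = list(NULL, ids))
  ad_alt <- matrix(NA_integer_, n, length(ids), dimnames = list(NULL, ids))
  for (s in ids) {
    if (s == focal) {
      dp[, s] <- dp_f; ad_alt[, s] <- n_alt
    } else {
      lo <- if (s %in% c(mom, dad)) min_dp else 0L
      dp[, s] <- resample(dp_pool(s, at_least = lo), n)
      ad_alt[, s] <- stats::rbinom(n, dp[, s], bg_alt_rate)
    }
    gt[, s] <- call_genotypes(dp[, s], ad_alt[, s], error_rate,
                              min_call_depth, ploidy = 2L)
  }
  spiked <- site_records(chrom, pos, ref, alt, gt, dp, dp - ad_alt, ad_alt)
  spikes <- data.frame(carrier = focal, chrom = chrom, pos = pos,
                       ref = ref, alt = alt, n_alt = n_alt, dp = dp_f,
                       callable = dp_f >= min_dp, stringsAsFactors = FALSE)
  list(records = spiked, spikes = spikes)
}

#' Spike synthetic mutations into every focal offspring
#'
#' Spikes every focal sample with the same coordinate-selection rules as
#' [spike_mutations()] (parents at mask depth, no existing record), drawing
#' all coordinates in one pass so none is reused across samples.
#'
#' @inheritParams spike_mutations
#' @param n_per_focal synthetic mutations per focal offspring.
#' @param seed integer seed for the whole spike set.
#' @return list with `records` (original plus all spiked records) and
#'   `spikes` (row-bound spike table across focal samples).
#' @export
spike_dataset <- function(records, masks, manifest, ploidy,
                          n_per_focal = 1000L, dist = NULL, bg_alt_rate = 0,
                          error_rate = 5e-4, min_call_depth = 4L, seed = 1L) {
  set.seed(seed)
  if (is.null(dist)) dist <- build_ad_distributions(records, manifest, ploidy)
  mom <- mother_id(manifest); dad <- confirmed_father(manifest)
  foc <- focal_ids(manifest)
  min_dp <- masks[[mom]]$threshold
  autos <- autosome_names(ploidy)
  pool <- GenomicRanges::intersect(
    mask_keep_chroms(masks[[mom]], autos)$ranges,
    mask_keep_chroms(masks[[dad]], autos)$ranges)
  rec_gr <- GenomicRanges::GRanges(records$chrom,
                                   IRanges::IRanges(records$pos, records$pos))
  pool <- suppressWarnings(GenomicRanges::setdiff(pool, rec_gr))
  n_total <- n_per_focal * length(foc)
  if (mask_length(pool) < n_total)
    stop("only ", mask_length(pool), " qualifying coordinates available for ",
         n_total, " synthetic mutations")
  cc <- .sample_pool_coords(pool, n_total)
  assign_f <- sample(rep(foc, each = n_per_focal))
  auto_rows <- records$chrom %in% autos
  new_rec <- list(); spikes <- list()
  for (f in foc) {
    sel <- assign_f == f
    sp <- .spike_at(records, manifest, cc$chrom[sel], cc$pos[sel], f, dist,
                    bg_alt_rate, error_rate, min_call_depth, min_dp,
                    auto_rows = auto_rows)
    new_rec[[f]] <- sp$records
    spikes[[f]] <- sp$spikes
  }
  list(records = do.call(bind_records, c(list(records), unname(new_rec))),
       spikes = do.call(rbind, c(unname(spikes), list(make.row.names = FALSE))))
}

#' False-negative rate from a spike-in experiment
#'
#' `FNR = (callable_inserted - detected) / callable_inserted`, where
#' `callable_inserted` counts spikes whose focal depth reached the
#' threshold (parental depth holds by construction) and `detected` counts
#' callable spikes recovered by [detect_candidates()] run with the same
#' parameters as the main analysis.
#'
#' @param spikes the spike table from [spike_dataset()].
#' @param candidates the candidates data.frame from re-running
#'   [detect_candidates()] on the spiked records.
#' @return object of class `fnr_estimate` (see [fnr_from_counts()]), with
#'   an additional `inserted_total` field.
#' @examples
#' fnr_from_counts(9914, 7658)  # 22.8%
#' @export
estimate_fnr <- function(spikes, candidates) {
  key <- paste(spikes$chrom, spikes$pos, spikes$carrier)
  ckey <- paste(candidates$chrom, candidates$pos, candidates$carrier)
  callable <- spikes$callable
  detected <- sum(callable & key %in% ckey)
  out <- fnr_from_counts(sum(callable), detected)
  out$inserted_total <- nrow(spikes)
  out
}

#' False-negative rate from callable/detected counts
#' @param callable_inserted synthetic mutations inserted at callable sites.
#' @param detected of those, the number recovered by the detection filter.
#' @return object of class `fnr_estimate`: `callable_inserted`, `detected`,
#'   `missed`, `fnr` (fraction), and `correction` = inserted/detected.
#' @export
fnr_from_counts <- function(callable_inserted, detected) {
  if (callable_inserted <= 0)
    stop("FNR undefined: no synthetic mutations at callable sites")
  stopifnot(detected >= 0, detected <= callable_inserted)
  structure(list(callable_inserted = callable_inserted, detected = detected,
                 missed = callable_inserted - detected,
                 fnr = (callable_inserted - detected) / callable_inserted,
                 correction = if (detected > 0) callable_inserted / detected
                 else NA_real_),
            class = "fnr_estimate")
}

#' @export
print.fnr_estimate <- function(x, ...) {
  cat(sprintf("FNR = %d/%d = %.1f%% (correction factor %.4f)\n",
              x$missed, x$callable_inserted, 100 * x$fnr,
              x$correction))
  invisible(x)
}
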