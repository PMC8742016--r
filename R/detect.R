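#' Detect candidate de novo mutations with the four-criteria filter
#'
#' Applies the trio/bait filtering criteria to joint-called records and
#' returns the surviving candidate mutations together with the stagewise
#' filter funnel:
#' \enumerate{
#'   \item Both parents hom-ref with `DP >= min_dp` and `AD_ALT == 0`
#'     (positive evidence required: a parent with missing AD or DP fails).
#'   \item No bait sample shows any alternate read (`AD_ALT > 0` vetoes
#'     regardless of its call; a called bait genotype must be hom-ref, with
#'     AD observed zero; baits with missing genotype and no observed
#'     alternate reads do not veto).
#'   \item Every focal sample has a called genotype; exactly 1 or 2 focal
#'     samples are heterozygous carriers (or hemizygous-alt for males at X
#'     sites) with carrier `DP >= min_dp`; the remaining focal samples are
#'     hom-ref with `AD_ALT == 0`. A male X sample called heterozygous is a
#'     biologically impossible genotype and discards the site.
#'   \item Carrier allele balance: `aaf_low * DP <= AD_ALT <= aaf_high * DP`
#'     (inclusive), applied to autosomal carriers and to female carriers at
#'     X sites; hemizygous-alt male X carriers skip this criterion. The
#'     comparison is done in exact integer arithmetic
#'     (`27 * DP <= 100 * AD_ALT <= 73 * DP` at the defaults) so boundary
#'     cases cannot flip through floating point.
#' }
#' Records on chromosomes absent from the ploidy map are dropped up front
#' (count recorded as an attribute of the funnel), and non-biallelic records
#' are removed as the first funnel stage, so raw joint-call output can be
#' passed directly.
#'
#' @param records a [site_records()] object.
#' @param manifest a [sample_manifest()] with a confirmed (unique) father.
#' @param ploidy a [ploidy_map()].
#' @param min_dp minimum parental and carrier depth (default 10).
#' @param aaf_bounds inclusive allele-balance bounds as fractions of DP
#'   (default `c(0.27, 0.73)`); internally rationalised over denominator 100.
#' @return list with `candidates` (data.frame, one row per carrier:
#'   `chrom`, `pos`, `ref`, `alt`, `carrier`, `carrier_sex`, `ad_ref`,
#'   `ad_alt`, `dp`, `mean_parent_dp`, `mean_focal_dp`, `chrom_class`,
#'   `n_carriers`) and `funnel` (a `filter_funnel` data.frame of stage
#'   names and surviving-site counts).
#' @export
detect_candidates <- function(records, manifest, ploidy, min_dp = 10L,
                              aaf_bounds = c(0.27, 0.73)) {
  mom <- mother_id(manifest)
  dad <- confirmed_father(manifest)
  foc <- focal_ids(manifest)
  bt <- bait_ids(manifest)
  lo <- as.integer(round(100 * aaf_bounds[1]))
  hi <- as.integer(round(100 * aaf_bounds[2]))

  funnel <- data.frame(stage = character(), n = integer(),
                       stringsAsFactors = FALSE)
  push <- function(stage, n) {
    funnel <<- rbind(funnel, data.frame(stage = stage, n = n))
  }
  push("total_variants", n_sites(records))

  on_map <- records$chrom %in% ploidy$chrom
  n_unmapped <- sum(!on_map)
  records <- records[on_map]
  records <- filter_biallelic_snps(records)
  push("biallelic_snps", n_sites(records))

  gt <- records$gt; dp <- records$dp; ad <- records$ad_alt
  zero_alt <- function(s) !is.na(ad[, s]) & ad[, s] == 0L

  ## (i) both parents hom-ref, DP >= min_dp, AD_ALT observed zero
  p_ok <- rep(TRUE, n_sites(records))
  for (s in c(mom, dad))
    p_ok <- p_ok & !is.na(gt[, s]) & gt[, s] == 0L &
      !is.na(dp[, s]) & dp[, s] >= min_dp & zero_alt(s)
  records <- records[p_ok]
  gt <- records$gt; dp <- records$dp; ad <- records$ad_alt
  push("parents_homref_dp", n_sites(records))

  ## (ii) bait: no alternate reads; called baits hom-ref with AD zero
  if (length(bt)) {
    adb <- ad[, bt, drop = FALSE]
    gtb <- gt[, bt, drop = FALSE]
    veto <- rowSums(!is.na(adb) & adb > 0L) > 0L |
      rowSums(!is.na(gtb) & gtb != 0L) > 0L |
      rowSums(!is.na(gtb) & is.na(adb)) > 0L
    records <- records[!veto]
    gt <- records$gt; dp <- records$dp; ad <- records$ad_alt
  }
  push("no_alt_in_bait", n_sites(records))

  ## (iii) part 1: all focal called
  gtf <- gt[, foc, drop = FALSE]
  all_called <- rowSums(is.na(gtf)) == 0L
  records <- records[all_called]
  gt <- records$gt; dp <- records$dp; ad <- records$ad_alt
  push("called_in_every_focal", n_sites(records))

  ## (iii) part 2: 1-2 carriers with DP >= min_dp, others hom-ref AD zero
  sexes <- stats::setNames(manifest$sex, manifest$sample_id)
  cls <- ploidy$class[match(records$chrom, ploidy$chrom)]
  on_x <- cls == "X"
  gtf <- gt[, foc, drop = FALSE]
  dpf <- dp[, foc, drop = FALSE]
  adf <- ad[, foc, drop = FALSE]
  male_f <- matrix(rep(sexes[foc] == "male", each = n_sites(records)),
                   ncol = length(foc))
  x_site <- matrix(on_x, n_sites(records), length(foc))
  carrier <- (gtf == 1L & !(x_site & male_f)) |     # het (autosome/female X)
    (gtf == 2L & x_site & male_f)                   # hemizygous-alt male X
  impossible <- gtf == 1L & x_site & male_f         # male X called het
  homref_ok <- gtf == 0L & !is.na(adf) & adf == 0L
  nc <- rowSums(carrier)
  ok <- nc >= 1L & nc <= 2L &
    rowSums(impossible) == 0L &
    rowSums(carrier | homref_ok) == length(foc) &
    rowSums(carrier & (is.na(dpf) | dpf < min_dp)) == 0L
  records <- records[ok]
  carrier <- carrier[ok, , drop = FALSE]
  push("one_or_two_het_focal", n_sites(records))

  ## (iv) allele balance, exact rational comparison; male X carriers exempt
  dpf <- records$dp[, foc, drop = FALSE]
  adf <- records$ad_alt[, foc, drop = FALSE]
  cls <- ploidy$class[match(records$chrom, ploidy$chrom)]
  x_site <- matrix(cls == "X", n_sites(records), length(foc))
  male_f <- matrix(rep(sexes[foc] == "male", each = n_sites(records)),
                   ncol = length(foc))
  needs_band <- carrier & !(x_site & male_f)
  band_ok <- !is.na(adf) & !is.na(dpf) &
    (lo * dpf <= 100L * adf) & (100L * adf <= hi * dpf)
  pass <- rowSums(needs_band & !band_ok) == 0L &
    rowSums(carrier & is.na(adf)) == 0L
  records <- records[pass]
  carrier <- carrier[pass, , drop = FALSE]
  push("allele_balance_pass", n_sites(records))

  class(funnel) <- c("filter_funnel", "data.frame")
  attr(funnel, "n_unmapped_dropped") <- n_unmapped

  ## assemble candidate table: one row per carrier
  idx <- which(carrier, arr.ind = TRUE)
  if (nrow(idx)) {
    i <- idx[, 1]; j <- idx[, 2]
    cand <- data.frame(
      chrom = records$chrom[i], pos = records$pos[i],
      ref = records$ref[i], alt = records$alt[i],
      carrier = foc[j],
      carrier_sex = unname(sexes[foc[j]]),
      ad_ref = records$ad_ref[cbind(i, match(foc[j], record_samples(records)))],
      ad_alt = records$ad_alt[cbind(i, match(foc[j], record_samples(records)))],
      dp = records$dp[cbind(i, match(foc[j], record_samples(records)))],
      mean_parent_dp = (records$dp[i, mom] + records$dp[i, dad]) / 2,
      mean_focal_dp = rowMeans(records$dp[i, foc, drop = FALSE], na.rm = TRUE),
      chrom_class = ploidy$class[match(records$chrom[i], ploidy$chrom)],
      n_carriers = rowSums(carrier)[i],
      stringsAsFactors = FALSE)
    cand <- cand[order(match(cand$chrom, ploidy$chrom), cand$pos), ]
    rownames(cand) <- NULL
  } else {
    cand <- data.frame(chrom = character(), pos = integer(),
                       ref = character(), alt = character(),
                       carrier = character(), carrier_sex = character(),
                       ad_ref = integer(), ad_alt = integer(), dp = integer(),
                       mean_parent_dp = numeric(), mean_focal_dp = numeric(),
                       chrom_class = character(), n_carriers = integer(),
                       stringsAsFactors = FALSE)
  }
  list(candidates = cand, funnel = funnel)
}

#' @export
print.filter_funnel <- function(x, ...) {
  cat("filter funnel (surviving sites per stage):\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Flag candidates with a co-segregating nearby variant
#'
#' Mis-mapping artifacts typically show nearby variants on the same reads
#' that segregate identically with the candidate. As an automatable proxy
#' for manual read-level curation, a candidate is flagged (advisory only,
#' never removed) when another record within `window` bp shows alternate
#' reads both in the candidate's carrier and in at least one bait sample
#' while both parents are called hom-ref there. The parental condition
#' distinguishes an artifact signature (unexplained stray reads shared
#' between carrier and bait) from an ordinary segregating variant, whose
#' alternate allele is present in a parent; without it, any candidate in a
#' normally polymorphic neighbourhood would be flagged.
#'
#' @param candidates the `candidates` data.frame from [detect_candidates()].
#' @param records the full [site_records()] the candidates came from.
#' @param manifest a [sample_manifest()].
#' @param window flanking distance in bp (default 150, about one read).
#' @return the candidates data.frame with a logical `comapping_flag` column.
#' @export
flag_comapping_context <- function(candidates, records, manifest,
                                   window = 150L) {
  stopifnot(window > 0)
  bt <- bait_ids(manifest)
  mom <- mother_id(manifest); dad <- confirmed_father(manifest)
  flag <- logical(nrow(candidates))
  if (nrow(candidates)) {
    ad <- records$ad_alt
    gt <- records$gt
    bait_alt <- if (length(bt))
      rowSums(!is.na(ad[, bt, drop = FALSE]) &
                ad[, bt, drop = FALSE] > 0L) > 0L
    else rep(FALSE, n_sites(records))
    parents_homref <- !is.na(gt[, mom]) & gt[, mom] == 0L &
      !is.na(gt[, dad]) & gt[, dad] == 0L
    bait_alt <- bait_alt & parents_homref
    for (k in seq_len(nrow(candidates))) {
      near <- records$chrom == candidates$chrom[k] &
        records$pos != candidates$pos[k] &
        abs(records$pos - candidates$pos[k]) <= window
      carr_alt <- !is.na(ad[, candidates$carrier[k]]) &
        ad[, candidates$carrier[k]] > 0L
      flag[k] <- any(near & carr_alt & bait_alt)
    }
  }
  candidates$comapping_flag <- flag
  candidates
}
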