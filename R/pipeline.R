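#' Run the full mutation-rate pipeline on a pedigree dataset
#'
#' Convenience wrapper chaining every analysis stage on a dataset shaped
#' like a [simulate_pedigree()] result (records, masks, manifest, ploidy):
#' paternity confirmation (skipped when the father is already confirmed or
#' unique), candidate detection, co-mapping flags, callable-site
#' accounting, spike-in FNR estimation (re-running detection with identical
#' parameters on the spiked records), and the FNR-corrected rate estimate.
#'
#' `m` defaults to the number of unflagged candidate rows (the automatable
#' stand-in for post-curation confirmation); supply `confirmed` to override
#' with an externally validated list.
#'
#' @param data list with `records`, `masks`, `manifest`, `ploidy` (e.g. a
#'   `pedigree_sim`).
#' @param min_dp parental/carrier depth threshold (default 10).
#' @param aaf_bounds inclusive allele-balance bounds (default
#'   `c(0.27, 0.73)`).
#' @param n_spikes_per_focal synthetic mutations per focal offspring.
#' @param bg_alt_rate background alternate-read rate at spiked records
#'   (defaults to the generator's error rate when `data` carries a config,
#'   else 0).
#' @param error_rate,min_call_depth genotype re-calling parameters for
#'   spiked records (defaults from `data$config` when present).
#' @param run_paternity force (or skip) the paternity stage; default: run
#'   when more than one candidate father is present.
#' @param confirmed optional data.frame (`chrom`, `pos`, `carrier`) of
#'   externally confirmed mutations to use as `m`.
#' @param alpha CI error level.
#' @param seed seed for the spike-in stage.
#' @return list of class `dnm_pipeline`: `paternity`, `candidates`,
#'   `funnel`, `callable`, `spikes`, `fnr`, `rate`, `report`.
#' @export
run_pipeline <- function(data, min_dp = 10L, aaf_bounds = c(0.27, 0.73),
                         n_spikes_per_focal = 1000L, bg_alt_rate = NULL,
                         error_rate = NULL, min_call_depth = NULL,
                         run_paternity = NULL, confirmed = NULL,
                         alpha = 0.05, seed = 1L) {
  records <- data$records; masks <- data$masks
  manifest <- data$manifest; ploidy <- data$ploidy
  cfg <- data$config
  if (is.null(bg_alt_rate))
    bg_alt_rate <- if (!is.null(cfg)) cfg$error_rate else 0
  if (is.null(error_rate))
    error_rate <- if (!is.null(cfg)) cfg$error_rate else 5e-4
  if (is.null(min_call_depth))
    min_call_depth <- if (!is.null(cfg)) cfg$min_call_depth else 4L
  if (is.null(masks)) stop("pipeline requires per-sample depth masks")

  pat <- NULL
  if (is.null(run_paternity))
    run_paternity <- length(father_ids(manifest)) > 1L &&
      !any(manifest$role == "father")
  if (run_paternity) {
    pat <- assign_paternity(records, manifest, ploidy)
    manifest <- pat$manifest
  }

  det <- detect_candidates(records, manifest, ploidy, min_dp = min_dp,
                           aaf_bounds = aaf_bounds)
  cand <- flag_comapping_context(det$candidates, records, manifest)

  csum <- callable_summary(masks, manifest, records = records,
                           candidates = cand, ploidy = ploidy)

  dist <- build_ad_distributions(records, manifest, ploidy)
  sp <- spike_dataset(records, masks, manifest, ploidy,
                      n_per_focal = n_spikes_per_focal, dist = dist,
                      bg_alt_rate = bg_alt_rate, error_rate = error_rate,
                      min_call_depth = min_call_depth, seed = seed)
  redet <- detect_candidates(sp$records, manifest, ploidy, min_dp = min_dp,
                             aaf_bounds = aaf_bounds)
  fnr <- estimate_fnr(sp$spikes, redet$candidates)

  m <- if (!is.null(confirmed)) nrow(confirmed)
  else sum(!cand$comapping_flag)
  rate <- estimate_rate(m, csum$total, fnr$callable_inserted, fnr$detected,
                        alpha = alpha)
  report <- render_report(det$funnel, cand, csum, fnr, rate, paternity = pat)
  structure(list(paternity = pat, candidates = cand, funnel = det$funnel,
                 callable = csum, spikes = sp$spikes, fnr = fnr,
                 rate = rate, report = report),
            class = "dnm_pipeline")
}

#' @export
print.dnm_pipeline <- function(x, ...) {
  print(x$report)
  invisible(x)
}
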