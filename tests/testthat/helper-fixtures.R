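# Shared fixtures, built in code at test time.

# tiny ploidy map used throughout
toy_ploidy <- function() {
  ploidy_map(c("2", "3", "X"), c("autosome", "autosome", "X"),
             c(5e4, 5e4, 2e4))
}

# small all-autosome config for fast whole-pipeline runs
small_auto_config <- function(...) {
  defaults <- list(
    chromosomes = ploidy_map(c("A1", "A2"), c("autosome", "autosome"),
                             c(4e4, 4e4)),
    n_polymorphic_sites = 600L, n_candidate_fathers = 1L,
    n_focal = 4L, n_bait = 3L, mu_true = 6e-6,
    artifact_site_rate = 1e-5, seed = 1L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# paternity-design config: 4 candidate males, no masks (records only)
paternity_config <- function(...) {
  defaults <- list(
    chromosomes = toy_ploidy(), n_polymorphic_sites = 1500L,
    n_candidate_fathers = 4L, n_focal = 6L, n_bait = 5L,
    mu_true = 0, artifact_site_rate = 0, make_masks = FALSE,
    seed = 1L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# hand-built site_records: a list of per-sample entries
# each sample entry: c(gt, dp, ad_ref, ad_alt) with gt as dosage or NA
make_records <- function(chrom, pos, ref, alt, per_sample) {
  ids <- names(per_sample[[1]])
  n <- length(pos)
  take <- function(k) {
    m <- t(vapply(per_sample, function(site)
      vapply(site, `[`, 0, k), numeric(length(ids))))
    m <- matrix(as.integer(m), n, length(ids), dimnames = list(NULL, ids))
    m
  }
  site_records(chrom, pos, ref, alt,
               gt = take(1), dp = take(2), ad_ref = take(3), ad_alt = take(4))
}

# shorthand for one sample's (gt, dp, ad_ref, ad_alt)
gv <- function(gt, dp, ad_ref, ad_alt) {
  c(if (is.na(gt)) NA_real_ else gt, dp, ad_ref, ad_alt)
}

# a clean pass-everything site: both parents 0/0 DP 30 AD 30,0; one carrier
pass_site <- function(ids, mother, father, carrier, baits = character(),
                      others = character(), carrier_dp = 20L,
                      carrier_ad = 10L) {
  site <- stats::setNames(vector("list", length(ids)), ids)
  for (s in ids) {
    site[[s]] <- if (s %in% c(mother, father)) gv(0, 30, 30, 0)
    else if (s == carrier) gv(1, carrier_dp, carrier_dp - carrier_ad, carrier_ad)
    else gv(0, 15, 15, 0)
  }
  site
}
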