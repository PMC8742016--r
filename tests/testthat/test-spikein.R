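# toy dataset for distribution building: parents opposite-homozygous
opp_hom_records <- function(ad_vals, dp = 12L) {
  ids <- c("mo", "fa", "f1")
  n <- length(ad_vals)
  sites <- lapply(ad_vals, function(a)
    list(mo = gv(0, 30, 30, 0), fa = gv(2, 30, 0, 30),
         f1 = gv(1, dp, dp - a, a)))
  make_records(rep("2", n), seq_len(n) * 100L, rep("A", n), rep("T", n),
               sites)
}

spike_manifest <- function() {
  sample_manifest(c("mo", "fa", "f1"),
                  c("mother", "candidate_father", "focal"),
                  c("female", "male", "female"))
}

test_that("AD distribution tables collect depth-matched het observations", {
  rec <- opp_hom_records(c(5L, 6L, 7L))
  dist <- build_ad_distributions(rec, spike_manifest(), toy_ploidy())
  tab <- dist$tables[["12"]]
  expect_equal(as.integer(names(tab)), c(5L, 6L, 7L))
  expect_equal(unname(as.numeric(tab)), rep(1, 3))
  expect_equal(dist$n_obs[["12"]], 3L)
  # sampling from that depth is uniform over the three observed values
  set.seed(1)
  draws <- sample_ad(dist, rep(12L, 300))
  expect_setequal(unique(draws), c(5L, 6L, 7L))
  # empty depth bins fall back to Binomial(d, 0.5)
  set.seed(2)
  fb <- sample_ad(dist, rep(40L, 400))
  expect_equal(mean(fb), 20, tolerance = 1)
})

test_that("AD distribution support never exceeds the depth and the mean
           tracks d/2 on simulated data", {
  cfg <- small_auto_config(n_polymorphic_sites = 3000L)
  sim <- simulate_pedigree(cfg, seed = 19)
  man <- confirm_father(sim$manifest, sim$truth$true_father)
  dist <- build_ad_distributions(sim$records, man, sim$ploidy)
  for (d in names(dist$tables)) {
    tab <- dist$tables[[d]]
    if (is.null(tab)) next
    vals <- as.integer(names(tab))
    expect_true(all(vals >= 0 & vals <= as.integer(d)))
    n <- sum(tab)
    if (n >= 30) {
      m <- sum(vals * as.numeric(tab)) / n
      se <- sqrt(as.integer(d) * 0.25 / n)
      expect_lt(abs(m - as.integer(d) / 2), 3 * se + 1e-9)
    }
  }
})

test_that("depth-range bounds of the distribution are honoured", {
  rec <- opp_hom_records(c(4L, 5L), dp = 9L)          # below range
  rec2 <- opp_hom_records(c(60L), dp = 120L)          # above range
  dist <- build_ad_distributions(bind_records(rec, rec2), spike_manifest(),
                                 toy_ploidy())
  expect_equal(dist$n_total, 0L)
})

test_that("spiking alters only the intended records and is seed-stable", {
  cfg <- small_auto_config()
  sim <- simulate_pedigree(cfg, seed = 55)
  man <- confirm_father(sim$manifest, sim$truth$true_father)
  n0 <- n_sites(sim$records)
  sp1 <- spike_dataset(sim$records, sim$masks, man, sim$ploidy,
                       n_per_focal = 25L, seed = 7)
  sp2 <- spike_dataset(sim$records, sim$masks, man, sim$ploidy,
                       n_per_focal = 25L, seed = 7)
  expect_identical(sp1$records, sp2$records)
  expect_identical(sp1$spikes, sp2$spikes)
  # original records are untouched; spiked rows are appended
  expect_identical(sp1$records[seq_len(n0)], sim$records)
  expect_equal(n_sites(sp1$records), n0 + 25L * length(focal_ids(man)))
  # one spike per coordinate, never reused across focal samples
  expect_false(any(duplicated(paste(sp1$spikes$chrom, sp1$spikes$pos))))
  # spiked coordinates avoid existing records
  expect_false(any(paste(sp1$spikes$chrom, sp1$spikes$pos) %in%
                     paste(sim$records$chrom, sim$records$pos)))
  # different seed, different spike set
  sp3 <- spike_dataset(sim$records, sim$masks, man, sim$ploidy,
                       n_per_focal = 25L, seed = 8)
  expect_false(identical(sp1$spikes$pos, sp3$spikes$pos))
})

test_that("a degenerate empirical table spikes the exact read count", {
  cfg <- small_auto_config()
  sim <- simulate_pedigree(cfg, seed = 60)
  man <- confirm_father(sim$manifest, sim$truth$true_father)
  # degenerate distribution: every depth bin forces N = 6 at DP 12
  dist <- build_ad_distributions(opp_hom_records(rep(6L, 5)), spike_manifest(),
                                 toy_ploidy())
  # restrict the focal depth pool so every spike lands at DP 12
  rec <- sim$records
  f1 <- focal_ids(man)[1]
  rec$dp[, f1] <- 12L
  rec$ad_ref[, f1] <- 12L
  rec$ad_alt[, f1] <- 0L
  sp <- spike_mutations(rec, sim$masks, man, sim$ploidy,
                        focal = focal_ids(man)[1], n = 10L, dist = dist,
                        seed = 3)
  new <- sp$records[(n_sites(rec) + 1L):n_sites(sp$records)]
  expect_true(all(new$dp[, focal_ids(man)[1]] == 12L))
  expect_true(all(new$ad_alt[, focal_ids(man)[1]] == 6L))
  expect_true(all(new$ad_ref[, focal_ids(man)[1]] == 6L))
  # parents at spiked records reach the mask threshold with zero alt reads
  expect_true(all(new$dp[, c("F0-F01", confirmed_father(man))] >= 10L))
  expect_true(all(new$ad_alt[, confirmed_father(man)] == 0L))
})

test_that("spike coordinates demand parental mask coverage", {
  cfg <- small_auto_config()
  sim <- simulate_pedigree(cfg, seed = 65)
  man <- confirm_father(sim$manifest, sim$truth$true_father)
  sp <- spike_dataset(sim$records, sim$masks, man, sim$ploidy,
                      n_per_focal = 40L, seed = 4)
  gr <- GenomicRanges::GRanges(sp$spikes$chrom,
                               IRanges::IRanges(sp$spikes$pos, sp$spikes$pos))
  for (s in c(mother_id(man), confirmed_father(man)))
    expect_true(all(IRanges::overlapsAny(gr, sim$masks[[s]]$ranges)))
})

test_that("requesting more spikes than qualifying coordinates is fatal", {
  rec <- opp_hom_records(c(5L, 6L))
  masks <- list(mo = depth_mask("mo", "2", 1L, 50L),
                fa = depth_mask("fa", "2", 1L, 50L),
                f1 = depth_mask("f1", "2", 1L, 50L))
  expect_error(
    spike_mutations(rec, masks, spike_manifest(), toy_ploidy(), "f1",
                    n = 100L, seed = 1),
    "qualifying coordinates")
})

test_that("FNR arithmetic and degenerate cases", {
  f <- fnr_from_counts(9914, 7658)
  expect_equal(f$missed, 2256)
  expect_equal(round(100 * f$fnr, 1), 22.8)
  expect_equal(fnr_from_counts(100, 100)$fnr, 0)
  expect_error(fnr_from_counts(0, 0), "undefined")
})

test_that("FNR is monotone when the allele-balance band tightens", {
  cfg <- small_auto_config()
  sim <- simulate_pedigree(cfg, seed = 70)
  man <- confirm_father(sim$manifest, sim$truth$true_father)
  sp <- spike_dataset(sim$records, sim$masks, man, sim$ploidy,
                      n_per_focal = 150L, bg_alt_rate = cfg$error_rate,
                      seed = 5)
  fnr_at <- function(bounds) {
    det <- detect_candidates(sp$records, man, sim$ploidy,
                             aaf_bounds = bounds)
    estimate_fnr(sp$spikes, det$candidates)$fnr
  }
  wide <- fnr_at(c(0.27, 0.73))
  narrow <- fnr_at(c(0.40, 0.60))
  expect_gte(narrow, wide)
  expect_gte(wide, 0); expect_lte(narrow, 1)
})
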