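# shared toy pedigree: 2 parents, 3 bait, 4 focal
det_manifest <- function() {
  ids <- c("mo", "fa", paste0("b", 1:3), paste0("f", 1:4))
  sample_manifest(ids,
                  c("mother", "candidate_father", rep("bait", 3),
                    rep("focal", 4)),
                  c("female", "male", rep("female", 3),
                    c("male", "female", "male", "female")))
}

# one site specified by per-sample overrides on top of a clean background
det_site <- function(..., carrier = "f1", carrier_gt = 1L, carrier_dp = 20L,
                     carrier_ad = 10L) {
  over <- list(...)
  s <- list(mo = gv(0, 30, 30, 0), fa = gv(0, 30, 30, 0))
  for (b in paste0("b", 1:3)) s[[b]] <- gv(0, 12, 12, 0)
  for (f in paste0("f", 1:4)) s[[f]] <- gv(0, 18, 18, 0)
  if (!is.null(carrier))
    s[[carrier]] <- gv(carrier_gt, carrier_dp, carrier_dp - carrier_ad,
                       carrier_ad)
  for (nm in names(over)) s[[nm]] <- over[[nm]]
  s
}

det_records <- function(sites, chrom = NULL, pos = NULL) {
  n <- length(sites)
  if (is.null(chrom)) chrom <- rep("2", n)
  if (is.null(pos)) pos <- seq_len(n) * 1000L
  make_records(chrom, pos, rep("A", n), rep("G", n), sites)
}

test_that("a clean heterozygous focal site passes all four criteria", {
  det <- detect_candidates(det_records(list(det_site())), det_manifest(),
                           toy_ploidy())
  expect_equal(nrow(det$candidates), 1L)
  expect_equal(det$candidates$carrier, "f1")
  expect_equal(det$candidates$ad_alt, 10L)
  expect_equal(det$candidates$n_carriers, 1L)
})

test_that("allele-depth arithmetic on a confirmed-mutation profile passes", {
  # carrier with AD 15 ref / 8 alt: DP 23, fraction 0.348 within [0.27, 0.73]
  det <- detect_candidates(
    det_records(list(det_site(carrier_dp = 23L, carrier_ad = 8L))),
    det_manifest(), toy_ploidy())
  expect_equal(nrow(det$candidates), 1L)
  expect_equal(det$candidates$ad_ref, 15L)
})

test_that("any bait alternate read vetoes the site", {
  det <- detect_candidates(
    det_records(list(det_site(b2 = gv(0, 12, 11, 1)))),
    det_manifest(), toy_ploidy())
  expect_equal(nrow(det$candidates), 0L)
  expect_equal(det$funnel$n[det$funnel$stage == "no_alt_in_bait"], 0L)
  # a bait with a missing genotype and no observed alt reads does not veto
  det2 <- detect_candidates(
    det_records(list(det_site(b2 = gv(NA, 2, 2, 0)))),
    det_manifest(), toy_ploidy())
  expect_equal(nrow(det2$candidates), 1L)
})

test_that("allele-balance bounds are inclusive and exact at the boundary", {
  # DP 30: bounds are 8.1 and 21.9, so AD_ALT 8 fails, 9 passes, 21 passes,
  # 22 fails; DP 100 with AD 27 sits exactly on the bound and passes
  for (case in list(c(30, 8, 0), c(30, 9, 1), c(30, 21, 1), c(30, 22, 0),
                    c(100, 27, 1), c(100, 26, 0), c(100, 73, 1),
                    c(100, 74, 0))) {
    det <- detect_candidates(
      det_records(list(det_site(carrier_dp = case[1], carrier_ad = case[2]))),
      det_manifest(), toy_ploidy())
    expect_equal(nrow(det$candidates), case[3],
                 info = paste("DP", case[1], "AD", case[2]))
  }
})

test_that("parental depth, alt reads and missing AD all veto at stage one", {
  p <- toy_ploidy(); man <- det_manifest()
  cases <- list(
    det_site(mo = gv(0, 9, 9, 0)),        # mother DP < 10
    det_site(fa = gv(0, 30, 29, 1)),      # father has an alt read
    det_site(mo = gv(0, 30, NA, NA)),     # AD missing: no positive evidence
    det_site(fa = gv(1, 30, 15, 15)))     # father het
  det <- detect_candidates(det_records(cases), man, p)
  expect_equal(nrow(det$candidates), 0L)
  expect_equal(det$funnel$n[det$funnel$stage == "parents_homref_dp"], 0L)
})

test_that("criterion iii: carrier count, calls and depth are enforced", {
  man <- det_manifest(); p <- toy_ploidy()
  # three carriers -> rejected
  det <- detect_candidates(det_records(list(
    det_site(f2 = gv(1, 20, 10, 10), f3 = gv(1, 20, 10, 10)))), man, p)
  expect_equal(nrow(det$candidates), 0L)
  # two carriers -> accepted, one row per carrier
  det2 <- detect_candidates(det_records(list(
    det_site(f2 = gv(1, 20, 10, 10)))), man, p)
  expect_equal(nrow(det2$candidates), 2L)
  expect_setequal(det2$candidates$carrier, c("f1", "f2"))
  expect_equal(det2$candidates$n_carriers, c(2L, 2L))
  # a focal with a missing call -> rejected
  det3 <- detect_candidates(det_records(list(
    det_site(f3 = gv(NA, 2, 2, 0)))), man, p)
  expect_equal(nrow(det3$candidates), 0L)
  # carrier below DP 10 -> rejected
  det4 <- detect_candidates(det_records(list(
    det_site(carrier_dp = 9L, carrier_ad = 4L))), man, p)
  expect_equal(nrow(det4$candidates), 0L)
  # non-carrier focal with an alt read -> rejected
  det5 <- detect_candidates(det_records(list(
    det_site(f4 = gv(0, 18, 17, 1)))), man, p)
  expect_equal(nrow(det5$candidates), 0L)
})

test_that("male X hemizygous-alt carriers pass without the balance band", {
  man <- det_manifest(); p <- toy_ploidy()
  # f1 is male; X site called hemizygous alt with near-total alt reads
  det <- detect_candidates(det_records(list(
    det_site(carrier_gt = 2L, carrier_dp = 14L, carrier_ad = 14L)),
    chrom = "X", pos = 5000L), man, p)
  expect_equal(nrow(det$candidates), 1L)
  expect_equal(det$candidates$chrom_class, "X")
  # same profile on an autosome is a hom-alt focal, not a het carrier
  det2 <- detect_candidates(det_records(list(
    det_site(carrier_gt = 2L, carrier_dp = 14L, carrier_ad = 14L))), man, p)
  expect_equal(nrow(det2$candidates), 0L)
  # a male called het on the X is impossible and discards the site
  det3 <- detect_candidates(det_records(list(
    det_site(carrier = "f1", carrier_gt = 1L, carrier_dp = 20L,
             carrier_ad = 10L)), chrom = "X", pos = 5000L), man, p)
  expect_equal(nrow(det3$candidates), 0L)
  # a female X carrier is an ordinary het and the band applies
  det4 <- detect_candidates(det_records(list(
    det_site(carrier = "f2", carrier_dp = 30L, carrier_ad = 8L)),
    chrom = "X", pos = 5000L), man, p)
  expect_equal(nrow(det4$candidates), 0L)
})

test_that("funnel counts are monotone and unmapped contigs are dropped", {
  man <- det_manifest(); p <- toy_ploidy()
  sites <- list(det_site(), det_site(b1 = gv(0, 12, 11, 1)),
                det_site(carrier = NULL), det_site())
  rec <- det_records(sites, chrom = c("2", "3", "2", "contig_7"),
                     pos = c(100L, 200L, 300L, 400L))
  det <- detect_candidates(rec, man, p)
  expect_true(all(diff(det$funnel$n) <= 0))
  expect_equal(det$funnel$n[1], 4L)          # total includes unmapped
  expect_equal(attr(det$funnel, "n_unmapped_dropped"), 1L)
  expect_equal(nrow(det$candidates), 1L)
})

test_that("detection output is invariant under record order", {
  cfg <- small_auto_config()
  sim <- simulate_pedigree(cfg, seed = 12)
  man <- confirm_father(sim$manifest, sim$truth$true_father)
  det1 <- detect_candidates(sim$records, man, sim$ploidy)
  set.seed(1)
  perm <- sample(n_sites(sim$records))
  det2 <- detect_candidates(sim$records[perm], man, sim$ploidy)
  key <- function(d) sort(paste(d$chrom, d$pos, d$carrier))
  expect_identical(key(det1$candidates), key(det2$candidates))
  expect_identical(det1$funnel$n[-(1:2)], det2$funnel$n[-(1:2)])
})

test_that("co-mapping flag marks artifact-context candidates only", {
  man <- det_manifest(); p <- toy_ploidy()
  # candidate at 1000; artifact-like neighbour at 1040 shares stray alt
  # reads between the carrier and a bait while parents are hom-ref
  neighbour <- det_site(carrier = NULL,
                        f1 = gv(0, 20, 18, 2), b1 = gv(0, 12, 10, 2))
  far_neighbour <- neighbour
  segregating <- det_site(carrier = NULL, mo = gv(1, 30, 15, 15),
                          f1 = gv(1, 20, 10, 10), b1 = gv(1, 12, 6, 6))
  rec <- det_records(list(det_site(), neighbour,
                          det_site(), far_neighbour,
                          det_site(), segregating,
                          det_site()),
                     pos = c(1000L, 1040L, 9000L, 9400L,
                             20000L, 20040L, 30000L))
  det <- detect_candidates(rec, man, p)
  flagged <- flag_comapping_context(det$candidates, rec, man)
  expect_equal(nrow(flagged), 4L)
  fl <- setNames(flagged$comapping_flag, flagged$pos)
  expect_true(fl[["1000"]])     # artifact neighbour within 150 bp
  expect_false(fl[["9000"]])    # neighbour beyond the window
  expect_false(fl[["20000"]])   # ordinary segregating variant nearby
  expect_false(fl[["30000"]])   # isolated
})
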