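test_that("manifest validation enforces pedigree structure", {
  m <- sample_manifest(c("mo", "fa1", "fa2", "f1", "b1"),
                       c("mother", "candidate_father", "candidate_father",
                         "focal", "bait"),
                       c("female", "male", "male", "male", "female"))
  expect_s3_class(m, "sample_manifest")
  expect_identical(mother_id(m), "mo")
  expect_identical(father_ids(m), c("fa1", "fa2"))
  expect_error(confirmed_father(m), "unconfirmed")
  m2 <- confirm_father(m, "fa2")
  expect_identical(confirmed_father(m2), "fa2")
  expect_false("fa1" %in% m2$sample_id)

  expect_error(sample_manifest("a", "mother", "female"), "candidate father")
  expect_error(sample_manifest(c("a", "a", "b"),
                               c("mother", "candidate_father", "focal"),
                               c("female", "male", "male")), "unique")
  expect_error(sample_manifest(c("a", "b", "c", "d"),
                               c("mother", "mother", "candidate_father", "focal"),
                               c("female", "female", "male", "male")),
               "exactly one mother")
})

test_that("manifest and ploidy map TSV round trips are lossless", {
  m <- sample_manifest(c("mo", "fa", "f1"), c("mother", "candidate_father", "focal"),
                       c("female", "male", "female"))
  p <- toy_ploidy()
  fm <- tempfile(fileext = ".tsv"); fp <- tempfile(fileext = ".tsv")
  write_manifest(m, fm); write_ploidy_map(p, fp)
  expect_equal(as.data.frame(read_manifest(fm)), as.data.frame(m))
  expect_equal(as.data.frame(read_ploidy_map(fp)), as.data.frame(p))
})

test_that("copy number is 2 on autosomes and sex-dependent on X", {
  p <- toy_ploidy()
  expect_identical(copy_number(p, c("2", "X", "X"),
                               c("male", "male", "female")),
                   c(2L, 1L, 2L))
  expect_error(copy_number(p, "Y", "male"), "not in ploidy map")
})

test_that("biallelic SNP filter keeps A>T, drops multi-allelic and indels", {
  ids <- c("s1")
  rec <- make_records(c("2", "2", "2"), c(10L, 20L, 30L),
                      ref = c("A", "A", "AT"), alt = c("T", "T,C", "A"),
                      list(list(s1 = gv(0, 10, 10, 0)),
                           list(s1 = gv(NA, 10, 10, 0)),
                           list(s1 = gv(0, 10, 10, 0))))
  out <- filter_biallelic_snps(rec)
  expect_equal(n_sites(out), 1L)
  expect_equal(out$pos, 10L)
  # empty stream passes through empty
  expect_equal(n_sites(filter_biallelic_snps(rec[integer(0)])), 0L)
})

test_that("biallelic filter reproduces a known stream composition ratio", {
  # construct a stream in which 83.6% of records are biallelic SNPs and
  # check the output/input ratio equals the composition
  set.seed(42)
  n <- 1000L
  is_snp <- seq_len(n) %in% sample.int(n, 836L)
  ref <- ifelse(is_snp, "A", "AT")
  rec <- make_records(rep("2", n), seq_len(n), ref, rep("G", n),
                      lapply(seq_len(n), function(i) list(s1 = gv(0, 10, 10, 0))))
  expect_equal(n_sites(filter_biallelic_snps(rec)) / n, 0.836)
})

test_that("VCF round trip preserves GT dosage, DP and AD at biallelic sites", {
  man <- sample_manifest(c("mo", "fa", "f1"),
                         c("mother", "candidate_father", "focal"),
                         c("female", "male", "male"))
  rec <- make_records(
    c("2", "2", "X"), c(100L, 200L, 50L), c("A", "C", "G"), c("T", "G", "A"),
    list(list(mo = gv(0, 30, 30, 0), fa = gv(1, 22, 11, 11), f1 = gv(2, 18, 0, 18)),
         list(mo = gv(NA, 2, 1, 1), fa = gv(0, 25, 25, 0), f1 = gv(1, 20, 10, 10)),
         list(mo = gv(0, 15, 15, 0), fa = gv(2, 12, 0, 12), f1 = gv(0, 14, 14, 0))))
  path <- tempfile(fileext = ".vcf")
  write_joint_vcf(rec, path)
  back <- read_joint_vcf(path, man)
  expect_equal(back$chrom, rec$chrom)
  expect_equal(back$pos, rec$pos)
  expect_equal(back$ref, rec$ref)
  expect_equal(back$alt, rec$alt)
  expect_equal(back$gt, rec$gt)
  expect_equal(back$dp, rec$dp)
  expect_equal(back$ad_ref, rec$ad_ref)
  expect_equal(back$ad_alt, rec$ad_alt)
})

test_that("reading a VCF with a missing manifest sample names the sample", {
  man1 <- sample_manifest(c("mo", "fa", "f1"),
                          c("mother", "candidate_father", "focal"),
                          c("female", "male", "male"))
  rec <- make_records("2", 1L, "A", "T",
                      list(list(mo = gv(0, 9, 9, 0), fa = gv(0, 9, 9, 0),
                                f1 = gv(1, 9, 5, 4))))
  path <- tempfile(fileext = ".vcf")
  write_joint_vcf(rec, path)
  man2 <- sample_manifest(c("mo", "fa", "ghost"),
                          c("mother", "candidate_father", "focal"),
                          c("female", "male", "male"))
  expect_error(read_joint_vcf(path, man2), "ghost")
  # single-record file with a missing genotype: others stay intact
  back <- read_joint_vcf(path, man1)
  expect_equal(unname(back$gt[1, ]), c(0L, 0L, 1L))
})

test_that("multi-allelic records pass through read with all alternates", {
  man <- sample_manifest(c("mo", "fa", "f1"),
                         c("mother", "candidate_father", "focal"),
                         c("female", "male", "male"))
  rec <- make_records("2", 7L, "A", "T,C,G",
                      list(list(mo = gv(0, 20, 18, NA), fa = gv(0, 20, 19, NA),
                                f1 = gv(NA, 20, 10, NA))))
  path <- tempfile(fileext = ".vcf")
  write_joint_vcf(rec, path)
  back <- read_joint_vcf(path, man)
  expect_equal(back$alt, "T,C,G")
  expect_equal(n_sites(filter_biallelic_snps(back)), 0L)
})

test_that("depth mask merges overlapping intervals and measures exactly", {
  m <- depth_mask("s", c("2", "2"), c(1L, 11L), c(10L, 20L))
  expect_equal(mask_length(m), 20)
  expect_equal(length(m$ranges), 1L)
  m2 <- depth_mask("s", c("2", "2"), c(6L, 9L), c(10L, 12L))
  expect_equal(mask_length(m2), 7)   # [6,12] after merge
  expect_error(depth_mask("s", "2", 0L, 5L), "non-positive")
})

test_that("mask BED round trip is lossless and converts 0-based half-open", {
  m <- depth_mask("sampleA", c("2", "3", "X"), c(5L, 1L, 100L),
                  c(10L, 7L, 150L), threshold = 10L)
  path <- tempfile(fileext = ".bed")
  write_depth_mask(m, path)
  lines <- readLines(path)
  # 1-based closed [5,10] -> BED 0-based half-open [4,10)
  expect_true("2\t4\t10" %in% lines)
  back <- read_depth_mask(path)
  expect_equal(back$threshold, 10L)
  expect_equal(as.data.frame(back$ranges)[1:3],
               as.data.frame(m$ranges)[1:3])
  expect_equal(mask_length(back), mask_length(m))
})

test_that("unsorted BED warns and sorts; negative coordinates are fatal", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("2\t50\t60", "2\t0\t10"), path)
  expect_warning(m <- read_depth_mask(path), "unsorted")
  expect_equal(mask_length(m), 20)
  writeLines(c("2\t-5\t10"), path)
  expect_error(suppressWarnings(read_depth_mask(path)), "negative")
})

test_that("mask length is invariant under interval splitting", {
  set.seed(9)
  starts <- sort(sample.int(1000, 20))
  ends <- starts + sample.int(30, 20, replace = TRUE)
  whole <- depth_mask("s", rep("2", 20), starts, ends)
  # split every interval at its midpoint into two adjacent pieces
  mid <- pmax(starts, (starts + ends) %/% 2)
  split_m <- depth_mask("s", rep("2", 40), c(starts, mid + 1L),
                        c(mid, ends))
  expect_equal(mask_length(split_m), mask_length(whole))
})
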