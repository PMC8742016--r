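#' Joint-called variant site records
#'
#' Column-oriented container for a stream of joint-called variant sites: one
#' row per site, one column per sample in each per-sample matrix. Genotype
#' calls are stored as the alternate-allele dosage: 0 (hom-ref), 1 (het),
#' 2 (hom-alt, or hemizygous-alt for a male X call), `NA` (missing). Haploid
#' VCF calls `"0"`/`"1"` are normalised to dosage 0/2 on input so that
#' diploid-coded and haploid-coded hemizygous calls are equivalent.
#'
#' @param chrom character vector of chromosome names (length n).
#' @param pos integer vector of 1-based positions.
#' @param ref character vector of reference alleles.
#' @param alt character vector of alternate alleles; multi-allelic records
#'   keep all alternates comma-separated (they are removed downstream by
#'   [filter_biallelic_snps()]).
#' @param gt,dp,ad_ref,ad_alt integer matrices, n sites x n samples, with
#'   sample ids as column names. `ad_alt` at multi-allelic records refers to
#'   the first alternate and is set `NA` on input.
#' @return An object of class `site_records`.
#' @export
site_records <- function(chrom, pos, ref, alt, gt, dp, ad_ref, ad_alt) {
  n <- length(pos)
  stopifnot(length(chrom) == n, length(ref) == n, length(alt) == n)
  for (m in list(gt, dp, ad_ref, ad_alt)) {
    stopifnot(is.matrix(m), nrow(m) == n)
    stopifnot(identical(colnames(m), colnames(gt)))
  }
  if (is.null(colnames(gt))) stop("per-sample matrices need sample-id colnames")
  bad <- !is.na(ad_ref) & !is.na(ad_alt) & !is.na(dp) & (ad_ref + ad_alt > dp)
  if (any(bad)) stop("AD_REF + AD_ALT > DP at ", sum(bad), " entries")
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = as.character(ref), alt = as.character(alt),
                 gt = gt, dp = dp, ad_ref = ad_ref, ad_alt = ad_alt),
            class = "site_records")
}

#' @export
print.site_records <- function(x, ...) {
  cat("site_records:", n_sites(x), "sites x", length(record_samples(x)),
      "samples\n")
  if (n_sites(x) > 0)
    cat("  chromosomes:", paste(unique(x$chrom), collapse = ", "), "\n")
  invisible(x)
}

#' Number of sites in a `site_records` object
#' @param x a [site_records()] object.
#' @export
n_sites <- function(x) length(x$pos)

#' Sample ids of a `site_records` object
#' @param x a [site_records()] object.
#' @export
record_samples <- function(x) colnames(x$gt)

#' @export
`[.site_records` <- function(x, i, ...) {
  site_records(x$chrom[i], x$pos[i], x$ref[i], x$alt[i],
               x$gt[i, , drop = FALSE], x$dp[i, , drop = FALSE],
               x$ad_ref[i, , drop = FALSE], x$ad_alt[i, , drop = FALSE])
}

#' Concatenate site records
#' @param ... `site_records` objects with identical sample sets.
#' @return a single [site_records()] object.
#' @export
bind_records <- function(...) {
  xs <- list(...)
  xs <- xs[vapply(xs, n_sites, 1L) > 0 | seq_along(xs) == 1L]
  ids <- record_samples(xs[[1]])
  for (x in xs) stopifnot(identical(record_samples(x), ids))
  site_records(unlist(lapply(xs, `[[`, "chrom")),
               unlist(lapply(xs, `[[`, "pos")),
               unlist(lapply(xs, `[[`, "ref")),
               unlist(lapply(xs, `[[`, "alt")),
               do.call(rbind, lapply(xs, `[[`, "gt")),
               do.call(rbind, lapply(xs, `[[`, "dp")),
               do.call(rbind, lapply(xs, `[[`, "ad_ref")),
               do.call(rbind, lapply(xs, `[[`, "ad_alt")))
}

#' Keep only biallelic single-nucleotide variants
#'
#' Retains records with a single alternate allele where both reference and
#' alternate are single bases (no indels, no multi-allelic sites), preserving
#' input order. This is the first stage of the candidate-mutation funnel.
#'
#' @param records a [site_records()] object.
#' @return a filtered [site_records()] object.
#' @examples
#' # A->T kept; A->"T,C" and AT->A dropped
#' @export
filter_biallelic_snps <- function(records) {
  bases <- c("A", "C", "G", "T")
  keep <- records$ref %in% bases & records$alt %in% bases
  records[keep]
}

## ---- VCF I/O (vcfR-backed) -------------------------------------------------

# dosage from a GT string vector: counts of allele "1"; haploid "0"/"1" map to
# 0/2; any allele index > 1 (multi-allelic call) or missing -> NA
.gt_to_dosage <- function(g) {
  g <- sub(":.*", "", g)
  out <- rep(NA_integer_, length(g))
  out[g %in% c("0/0", "0|0")] <- 0L
  out[g %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  out[g %in% c("1/1", "1|1")] <- 2L
  out[g == "0"] <- 0L
  out[g == "1"] <- 2L
  out
}

.dosage_to_gt <- function(d) {
  c("0/0", "0/1", "1/1")[d + 1L]
}

#' Read a multi-sample joint VCF into site records
#'
#' Reads GT, DP and AD for every manifest sample. Multi-allelic records are
#' passed through with all alternate alleles (removal happens downstream in
#' [filter_biallelic_snps()]); their genotype dosage and `ad_alt` are `NA`.
#' At biallelic sites `ad_alt` is the second AD entry. Malformed AD/DP values
#' yield a record-level warning and missing fields; a manifest sample absent
#' from the VCF is a fatal error naming the sample.
#'
#' @param path path to a VCF (plain or bgzip/gzip).
#' @param manifest a [sample_manifest()]; all its samples must be present.
#' @return a [site_records()] object with manifest samples as columns.
#' @export
read_joint_vcf <- function(path, manifest) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  vcf_samples <- colnames(v@gt)[-1]
  missing <- setdiff(manifest$sample_id, vcf_samples)
  if (length(missing))
    stop("sample(s) missing from VCF: ", paste(missing, collapse = ", "))
  ids <- manifest$sample_id
  n <- nrow(v@fix)
  gt_raw <- vcfR::extract.gt(v, element = "GT", return.alleles = FALSE)
  dp_raw <- vcfR::extract.gt(v, element = "DP")
  ad_raw <- vcfR::extract.gt(v, element = "AD")
  if (n == 1L) {  # extract.gt drops to vector for single-record files
    fix_dim <- function(m) matrix(m, nrow = 1, dimnames = list(NULL, vcf_samples))
    if (!is.matrix(gt_raw)) gt_raw <- fix_dim(gt_raw)
    if (!is.matrix(dp_raw)) dp_raw <- fix_dim(dp_raw)
    if (!is.matrix(ad_raw)) ad_raw <- fix_dim(ad_raw)
  }
  gt_raw <- gt_raw[, ids, drop = FALSE]
  dp_raw <- dp_raw[, ids, drop = FALSE]
  ad_raw <- ad_raw[, ids, drop = FALSE]

  gt <- matrix(.gt_to_dosage(gt_raw), nrow = n, dimnames = list(NULL, ids))
  dp <- suppressWarnings(matrix(as.integer(dp_raw), nrow = n,
                                dimnames = list(NULL, ids)))
  n_bad_dp <- sum(!is.na(dp_raw) & dp_raw != "." & is.na(dp))
  ad1 <- suppressWarnings(as.integer(sub(",.*", "", ad_raw)))
  ad2 <- suppressWarnings(as.integer(sub("^[^,]*,", "", sub("(,[^,]*),.*", "\\1", ad_raw))))
  multi <- grepl(",", v@fix[, "ALT"])
  ad_ref <- matrix(ad1, nrow = n, dimnames = list(NULL, ids))
  ad_alt <- matrix(ad2, nrow = n, dimnames = list(NULL, ids))
  ad_alt[multi, ] <- NA_integer_
  n_bad_ad <- sum(!is.na(ad_raw) & ad_raw != "." & is.na(ad_ref))
  if (n_bad_dp + n_bad_ad > 0)
    warning(n_bad_dp, " malformed DP and ", n_bad_ad,
            " malformed AD entries set to missing")
  # guard against AD inconsistencies from the caller
  bad <- !is.na(ad_ref) & !is.na(ad_alt) & !is.na(dp) & (ad_ref + ad_alt > dp)
  if (any(bad)) {
    warning(sum(bad), " entries with AD_REF + AD_ALT > DP set to missing AD")
    ad_ref[bad] <- NA_integer_; ad_alt[bad] <- NA_integer_
  }
  site_records(v@fix[, "CHROM"], as.integer(v@fix[, "POS"]),
               v@fix[, "REF"], v@fix[, "ALT"], gt, dp, ad_ref, ad_alt)
}

#' Write site records as a multi-sample VCF
#'
#' Emits a VCF 4.2 with GT:DP:AD per sample. Genotypes are written
#' diploid-coded (`1/1` for dosage 2, including hemizygous male X calls);
#' the dosage-level round trip through [read_joint_vcf()] is lossless for
#' GT/DP/AD at biallelic SNP sites. Output is bgzip-compressed when `path`
#' ends in `.gz`, plain text otherwise.
#'
#' @param records a [site_records()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @importClassesFrom vcfR vcfR
#' @export
write_joint_vcf <- function(records, path) {
  n <- n_sites(records)
  ids <- record_samples(records)
  fix <- cbind(CHROM = records$chrom, POS = as.character(records$pos),
               ID = ".", REF = records$ref, ALT = records$alt,
               QUAL = ".", FILTER = "PASS", INFO = ".")
  fmt_gt <- matrix(".", nrow = n, ncol = length(ids))
  ok <- !is.na(records$gt)
  fmt_gt[ok] <- .dosage_to_gt(records$gt[ok])
  fmt_gt[!ok] <- "./."
  fmt_dp <- ifelse(is.na(records$dp), ".", as.character(records$dp))
  fmt_ad <- ifelse(is.na(records$ad_ref) | is.na(records$ad_alt), ".",
                   paste0(records$ad_ref, ",", records$ad_alt))
  gt <- matrix(paste(fmt_gt, fmt_dp, fmt_ad, sep = ":"),
               nrow = n, dimnames = list(NULL, ids))
  gt <- cbind(FORMAT = rep("GT:DP:AD", n), gt)
  meta <- c("##fileformat=VCFv4.2",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
            "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">")
  v <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  if (grepl("\\.gz$", path)) {
    vcfR::write.vcf(v, file = path)
  } else {
    tmp <- paste0(path, ".gz")
    vcfR::write.vcf(v, file = tmp)
    con_in <- gzfile(tmp, "rb"); raw <- readBin(con_in, "raw", 1e8)
    close(con_in)
    writeBin(raw, path)
    unlink(tmp)
  }
  invisible(path)
}
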