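#' Sample manifest for a single-mating pedigree
#'
#' A manifest assigns every sequenced sample a pedigree role. The design is a
#' single mother, one or more candidate fathers (only one of which is the true
#' mate), focal offspring (sequenced deep, screened for de novo mutations) and
#' bait offspring (sequenced shallow, used only to veto sites carrying shared
#' spurious alternate reads).
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param role character vector, one of `"mother"`, `"candidate_father"`,
#'   `"father"` (a confirmed candidate), `"focal"`, `"bait"`.
#' @param sex character vector, `"female"` or `"male"`.
#' @return A `data.frame` of class `sample_manifest` with columns
#'   `sample_id`, `role`, `sex`.
#' @examples
#' sample_manifest(c("F0-F01", "F0-M01", "F1-01"),
#'                 c("mother", "candidate_father", "focal"),
#'                 c("female", "male", "male"))
#' @export
sample_manifest <- function(sample_id, role, sex) {
  roles <- c("mother", "candidate_father", "father", "focal", "bait")
  stopifnot(length(sample_id) == length(role), length(role) == length(sex))
  if (anyDuplicated(sample_id))
    stop("sample ids must be unique: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  if (!all(role %in% roles))
    stop("unknown role(s): ", paste(setdiff(role, roles), collapse = ", "))
  if (!all(sex %in% c("female", "male")))
    stop("sex must be 'female' or 'male'")
  if (sum(role == "mother") != 1L)
    stop("manifest must contain exactly one mother")
  if (sum(role %in% c("candidate_father", "father")) < 1L)
    stop("manifest must contain at least one candidate father")
  if (sum(role == "father") > 1L)
    stop("at most one confirmed father allowed")
  if (sum(role == "focal") < 1L)
    stop("manifest must contain at least one focal offspring")
  if (any(role == "mother" & sex != "female") ||
      any(role %in% c("candidate_father", "father") & sex != "male"))
    stop("parental roles must match sex (mother female, fathers male)")
  out <- data.frame(sample_id = as.character(sample_id),
                    role = as.character(role), sex = as.character(sex),
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_manifest", "data.frame")
  out
}

#' @export
print.sample_manifest <- function(x, ...) {
  cat("sample_manifest:", nrow(x), "samples (",
      paste(names(table(x$role)), table(x$role), collapse = ", "), ")\n")
  print.data.frame(x, ...)
  invisible(x)
}

manifest_ids <- function(manifest, role) {
  manifest$sample_id[manifest$role %in% role]
}

#' Mother's sample id
#' @param manifest a [sample_manifest()].
#' @return character scalar.
#' @export
mother_id <- function(manifest) manifest_ids(manifest, "mother")

#' Candidate (or confirmed) father sample ids
#' @param manifest a [sample_manifest()].
#' @return character vector.
#' @export
father_ids <- function(manifest) manifest_ids(manifest, c("candidate_father", "father"))

#' Focal offspring sample ids
#' @param manifest a [sample_manifest()].
#' @return character vector.
#' @export
focal_ids <- function(manifest) manifest_ids(manifest, "focal")

#' Bait offspring sample ids
#' @param manifest a [sample_manifest()].
#' @return character vector.
#' @export
bait_ids <- function(manifest) manifest_ids(manifest, "bait")

#' Confirmed father of the manifest
#'
#' Returns the single confirmed father. A manifest with one remaining
#' candidate father is treated as confirmed; with several candidates the
#' father must first be fixed with [confirm_father()].
#'
#' @param manifest a [sample_manifest()].
#' @return character scalar sample id.
#' @export
confirmed_father <- function(manifest) {
  f <- manifest_ids(manifest, "father")
  if (length(f) == 1L) return(f)
  cand <- manifest_ids(manifest, "candidate_father")
  if (length(cand) == 1L) return(cand)
  stop("manifest has ", length(cand),
       " unconfirmed candidate fathers; run paternity analysis and confirm_father() first")
}

#' Confirm the true father and drop the other candidate males
#'
#' After paternity analysis the non-father candidate males are irrelevant to
#' mutation detection and are removed from the manifest.
#'
#' @param manifest a [sample_manifest()].
#' @param father_id sample id of the selected father (must be a candidate).
#' @return A [sample_manifest()] with the selected male as `father` and the
#'   other candidates removed.
#' @export
confirm_father <- function(manifest, father_id) {
  if (!father_id %in% father_ids(manifest))
    stop("'", father_id, "' is not a candidate father in the manifest")
  keep <- manifest$role != "candidate_father" | manifest$sample_id == father_id
  out <- manifest[keep, , drop = FALSE]
  out$role[out$sample_id == father_id] <- "father"
  rownames(out) <- NULL
  class(out) <- c("sample_manifest", "data.frame")
  out
}

#' Read / write a sample manifest as TSV
#'
#' Plain three-column TSV (`sample_id`, `role`, `sex`) with a header line.
#'
#' @param path file path.
#' @return [read_manifest()] returns a [sample_manifest()];
#'   [write_manifest()] returns `path` invisibly.
#' @export
read_manifest <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  sample_manifest(df$sample_id, df$role, df$sex)
}

#' @rdname read_manifest
#' @param manifest a [sample_manifest()].
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Chromosome ploidy map
#'
#' Declares the chromosome universe of the analysis and the copy-number class
#' of each chromosome. Autosomes carry two copies in every sample; the X
#' carries two copies in females and one in males (the karyotype is XX/XY).
#' The Y and unplaced contigs are excluded from the analysis entirely:
#' records on chromosomes absent from the map are dropped (with a count)
#' by the detection stage.
#'
#' @param chrom character vector of chromosome names.
#' @param class character vector, `"autosome"` or `"X"`.
#' @param length optional integer vector of chromosome lengths (bp).
#' @return A `data.frame` of class `ploidy_map`.
#' @examples
#' ploidy_map(c("2", "3", "X"), c("autosome", "autosome", "X"),
#'            c(5e5, 5e5, 2e5))
#' @export
ploidy_map <- function(chrom, class, length = NA_integer_) {
  stopifnot(length(chrom) == length(class))
  if (!all(class %in% c("autosome", "X")))
    stop("chromosome class must be 'autosome' or 'X'")
  if (anyDuplicated(chrom)) stop("duplicate chromosome names")
  out <- data.frame(chrom = as.character(chrom), class = as.character(class),
                    length = as.numeric(length), stringsAsFactors = FALSE)
  class(out) <- c("ploidy_map", "data.frame")
  out
}

#' Copy number of a chromosome in a sample of given sex
#' @param ploidy a [ploidy_map()].
#' @param chrom chromosome name(s).
#' @param sex `"female"` or `"male"` (recycled).
#' @return integer vector of copy numbers (2, or 1 for male X).
#' @export
copy_number <- function(ploidy, chrom, sex) {
  cls <- ploidy$class[match(chrom, ploidy$chrom)]
  if (anyNA(cls)) stop("chromosome(s) not in ploidy map: ",
                       paste(unique(chrom[is.na(cls)]), collapse = ", "))
  ifelse(cls == "X" & sex == "male", 1L, 2L)
}

autosome_names <- function(ploidy) ploidy$chrom[ploidy$class == "autosome"]

#' Read / write a ploidy map as TSV
#' @param path file path.
#' @return [read_ploidy_map()] returns a [ploidy_map()].
#' @export
read_ploidy_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  len <- if ("length" %in% names(df)) df$length else NA_integer_
  ploidy_map(df$chrom, df$class, len)
}

#' @rdname read_ploidy_map
#' @param ploidy a [ploidy_map()].
#' @export
write_ploidy_map <- function(ploidy, path) {
  utils::write.table(ploidy, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
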