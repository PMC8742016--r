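#' Configuration for the synthetic pedigree generator
#'
#' Defines the study conditions the generator emulates: a single mating pair
#' plus unrelated distractor males, deep-sequenced focal offspring and
#' shallow-sequenced bait offspring, segregating biallelic SNPs under
#' Hardy-Weinberg founder frequencies, planted de novo mutations at a known
#' per-site per-generation rate, negative-binomial depth sampling,
#' per-read sequencing error, and shared mis-mapping artifact sites.
#'
#' Default coverages follow the observed per-role means of the deeper of the
#' two study designs (mother 20x, candidate males 32x, focal 26x, bait 13x)
#' with 4 candidate males, 10 focal and 19 bait offspring. The default toy
#' genome is two 500 kb autosomes plus a 200 kb X.
#'
#' @param chromosomes a [ploidy_map()] with a `length` column (bp).
#' @param n_polymorphic_sites number of segregating founder SNPs.
#' @param af_range range of the uniform founder allele-frequency sampler.
#' @param n_candidate_fathers,n_focal,n_bait pedigree design counts.
#' @param coverage named numeric: mean depth for `mother`, `father`,
#'   `focal`, `bait`. Male X depth is halved (one copy).
#' @param depth_dispersion negative-binomial size parameter (overdispersed
#'   coverage; smaller = more dispersed).
#' @param error_rate per-read probability that a read shows the alternate
#'   allele at a site where the sample does not carry it (and vice versa).
#' @param artifact_site_rate expected mis-mapping artifact sites per bp.
#' @param artifact_share_prob probability each sample independently shows
#'   low-level alternate reads at an artifact site.
#' @param artifact_alt_fraction expected alternate-read fraction at an
#'   artifact site in an affected sample.
#' @param mu_true true de novo mutation rate per site per generation (per
#'   haploid genome copy).
#' @param min_call_depth minimum depth for a genotype call (below: missing).
#' @param mask_threshold depth threshold used for the per-sample masks.
#' @param make_masks if `FALSE`, skip per-base depth realisation (no masks;
#'   record depths drawn i.i.d.). Useful for paternity-only simulations.
#' @param seed default seed for [simulate_pedigree()].
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(chromosomes = ploidy_map(c("2", "3", "X"),
                                                c("autosome", "autosome", "X"),
                                                c(5e5, 5e5, 2e5)),
                       n_polymorphic_sites = 10000L,
                       af_range = c(0.05, 0.95),
                       n_candidate_fathers = 4L,
                       n_focal = 10L,
                       n_bait = 19L,
                       coverage = c(mother = 20, father = 32,
                                    focal = 26, bait = 13),
                       depth_dispersion = 8,
                       error_rate = 5e-4,
                       artifact_site_rate = 2e-5,
                       artifact_share_prob = 0.5,
                       artifact_alt_fraction = 0.12,
                       mu_true = 5e-7,
                       min_call_depth = 4L,
                       mask_threshold = 10L,
                       make_masks = TRUE,
                       seed = 1L) {
  stopifnot(inherits(chromosomes, "ploidy_map"), !anyNA(chromosomes$length))
  stopifnot(all(c("mother", "father", "focal", "bait") %in% names(coverage)),
            all(coverage > 0))
  stopifnot(error_rate >= 0, error_rate < 1,
            artifact_share_prob >= 0, artifact_share_prob <= 1,
            artifact_alt_fraction >= 0, artifact_alt_fraction <= 1,
            mu_true >= 0, n_candidate_fathers >= 1, n_focal >= 1, n_bait >= 0)
  if (n_polymorphic_sites > sum(chromosomes$length))
    stop("more polymorphic sites than genome coordinates")
  structure(as.list(environment()), class = "sim_config")
}

#' Maximum-likelihood genotype call from allele counts
#'
#' Calls the genotype maximising the binomial likelihood of the observed
#' alternate-read count: `Binomial(DP, q)` with `q` equal to the error rate
#' for hom-ref, 0.5 for het, and 1 - error rate for hom-alt. Haploid loci
#' (male X) are called among hom-ref/hemizygous-alt only. Calls are missing
#' below `min_depth`. Stands in for a joint variant caller at the level of
#' the fields this pipeline consumes.
#'
#' @param dp,ad_alt integer vectors: total depth and alternate-read count.
#' @param error_rate per-read alternate-allele error probability.
#' @param min_depth minimum depth for a call.
#' @param ploidy 1 or 2, recycled along sites.
#' @return integer vector of alternate-allele dosages (0/1/2, `NA` missing).
#' @examples
#' call_genotypes(30, 15)          # het
#' call_genotypes(30, 0)           # hom-ref
#' call_genotypes(25, 24, ploidy = 1)  # hemizygous alt -> dosage 2
#' @export
call_genotypes <- function(dp, ad_alt, error_rate = 5e-4, min_depth = 4L,
                           ploidy = 2L) {
  n <- max(length(dp), length(ad_alt))
  dp <- rep_len(dp, n); ad_alt <- rep_len(ad_alt, n)
  ploidy <- rep_len(ploidy, n)
  ll0 <- stats::dbinom(ad_alt, dp, error_rate, log = TRUE)
  ll1 <- stats::dbinom(ad_alt, dp, 0.5, log = TRUE)
  ll2 <- stats::dbinom(ad_alt, dp, 1 - error_rate, log = TRUE)
  ll1[ploidy == 1L] <- -Inf
  call <- max.col(cbind(ll0, ll1, ll2), ties.method = "first") - 1L
  call[is.na(dp) | dp < min_depth] <- NA_integer_
  call
}

# Mendelian transmission: one allele drawn from a diploid dosage vector
.transmit <- function(g) {
  het <- !is.na(g) & g == 1L
  out <- as.integer(g %/% 2L)
  out[het] <- stats::rbinom(sum(het), 1L, 0.5)
  out
}

# map global 1..sum(L) coordinate indices to (chrom, pos)
.idx_to_coord <- function(idx, chroms, lengths) {
  offsets <- c(0, cumsum(as.numeric(lengths)))
  ci <- findInterval(idx - 0.5, offsets)
  list(chrom = chroms[ci], pos = as.integer(idx - offsets[ci]))
}

.rand_base <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)
.rand_alt <- function(ref) {
  vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
}

#' Simulate a joint-called pedigree dataset with known ground truth
#'
#' Generates founder genotypes under Hardy-Weinberg, transmits alleles
#' Mendelianly from the mother and her (randomly designated) true mate,
#' plants de novo mutations per offspring as Poisson with mean
#' `copies x genome_length x mu_true` (2 copies on autosomes; 1 or 2 on the
#' X by offspring sex), samples depth per sample per site from a negative
#' binomial, draws alternate-read counts binomially (0.5 for true
#' heterozygotes, the error rate for homozygotes, ~1 for hemizygous alt),
#' injects shared mis-mapping artifact sites, calls genotypes with
#' [call_genotypes()], and records per-sample depth masks at the mask
#' threshold. Only polymorphic, planted and artifact sites are emitted as
#' records (invariant sites are carried implicitly by the masks, as in real
#' joint-call output). Fully reproducible from `seed`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (default `config$seed`).
#' @return A list of class `pedigree_sim` with elements `records`
#'   ([site_records()]), `masks` (named list of [depth_mask()], or `NULL`),
#'   `manifest`, `ploidy`, `truth` (true father, planted-mutation table,
#'   artifact table, true genotype matrix), and `config`.
#' @export
simulate_pedigree <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  pl <- config$chromosomes
  chroms <- pl$chrom; lengths <- pl$length
  total_len <- sum(as.numeric(lengths))
  is_x <- pl$class == "X"

  ## -- manifest ---------------------------------------------------------
  mother <- "F0-F01"
  fathers <- sprintf("F0-M%02d", seq_len(config$n_candidate_fathers))
  focal <- sprintf("F1-FOC%02d", seq_len(config$n_focal))
  bait <- if (config$n_bait > 0) sprintf("F1-BT%02d", seq_len(config$n_bait)) else character()
  offspring <- c(focal, bait)
  off_sex <- sample(c("female", "male"), length(offspring), replace = TRUE)
  manifest <- sample_manifest(
    c(mother, fathers, focal, bait),
    c("mother", rep("candidate_father", length(fathers)),
      rep("focal", length(focal)), rep("bait", length(bait))),
    c("female", rep("male", length(fathers)), off_sex))
  true_father <- sample(fathers, 1L)
  ids <- manifest$sample_id
  sex <- stats::setNames(manifest$sex, ids)
  n_samp <- length(ids)

  ## -- site coordinates -------------------------------------------------
  used <- logical(total_len)
  poly_idx <- sample.int(total_len, config$n_polymorphic_sites)
  used[poly_idx] <- TRUE
  poly <- .idx_to_coord(sort(poly_idx), chroms, lengths)
  n_poly <- length(poly$pos)
  poly_x <- poly$chrom %in% chroms[is_x]
  af <- stats::runif(n_poly, config$af_range[1], config$af_range[2])

  ## -- founder genotypes at polymorphic sites ---------------------------
  g <- matrix(NA_integer_, n_poly, n_samp, dimnames = list(NULL, ids))
  g[, mother] <- stats::rbinom(n_poly, 2L, af)
  for (f in fathers) {
    gf <- stats::rbinom(n_poly, 2L, af)
    gf[poly_x] <- 2L * stats::rbinom(sum(poly_x), 1L, af[poly_x])
    g[, f] <- gf
  }
  for (k in seq_along(offspring)) {
    o <- offspring[k]
    mat <- .transmit(g[, mother])
    if (off_sex[k] == "female") {
      pat <- integer(n_poly)
      pat[!poly_x] <- .transmit(g[!poly_x, true_father])
      pat[poly_x] <- g[poly_x, true_father] %/% 2L     # father's single X
      g[, o] <- mat + pat
    } else {
      go <- mat + .transmit(g[, true_father])
      go[poly_x] <- 2L * mat[poly_x]                   # son: maternal X only
      g[, o] <- go
    }
  }

  ## -- planted de novo mutations ----------------------------------------
  la <- sum(as.numeric(lengths[!is_x])); lx <- sum(as.numeric(lengths[is_x]))
  offsets <- c(0, cumsum(as.numeric(lengths)))
  draw_coord <- function(class_x) {
    ci <- which(is_x == class_x)
    repeat {
      ch <- if (length(ci) == 1L) ci else
        sample(ci, 1L, prob = lengths[ci])
      idx <- offsets[ch] + sample.int(lengths[ch], 1L)
      if (!used[idx]) { used[idx] <<- TRUE; return(idx) }
    }
  }
  mut <- list(chrom = character(), pos = integer(), carrier = character(),
              sex = character(), on_x = logical())
  for (k in seq_along(offspring)) {
    copies_x <- if (off_sex[k] == "male") 1L else 2L
    n_a <- stats::rpois(1L, 2 * la * config$mu_true)
    n_x <- if (lx > 0) stats::rpois(1L, copies_x * lx * config$mu_true) else 0L
    if (n_a + n_x > total_len - sum(used))
      stop("mu_true too large: planted mutations exceed available coordinates")
    for (j in seq_len(n_a)) {
      cc <- .idx_to_coord(draw_coord(FALSE), chroms, lengths)
      mut$chrom <- c(mut$chrom, cc$chrom); mut$pos <- c(mut$pos, cc$pos)
      mut$carrier <- c(mut$carrier, offspring[k])
      mut$sex <- c(mut$sex, off_sex[k]); mut$on_x <- c(mut$on_x, FALSE)
    }
    for (j in seq_len(n_x)) {
      cc <- .idx_to_coord(draw_coord(TRUE), chroms, lengths)
      mut$chrom <- c(mut$chrom, cc$chrom); mut$pos <- c(mut$pos, cc$pos)
      mut$carrier <- c(mut$carrier, offspring[k])
      mut$sex <- c(mut$sex, off_sex[k]); mut$on_x <- c(mut$on_x, TRUE)
    }
  }
  n_mut <- length(mut$pos)
  g_mut <- matrix(0L, n_mut, n_samp, dimnames = list(NULL, ids))
  for (j in seq_len(n_mut)) {
    # one inherited ref copy converted; a male X carrier becomes hemizygous alt
    g_mut[j, mut$carrier[j]] <-
      if (mut$on_x[j] && mut$sex[j] == "male") 2L else 1L
  }

  ## -- artifact sites ----------------------------------------------------
  n_art <- stats::rpois(1L, config$artifact_site_rate * total_len)
  art_idx <- integer(n_art)
  for (j in seq_len(n_art)) {
    repeat {
      idx <- sample.int(total_len, 1L)
      if (!used[idx]) { used[idx] <- TRUE; art_idx[j] <- idx; break }
    }
  }
  art <- .idx_to_coord(art_idx, chroms, lengths)
  art_affected <- matrix(stats::runif(n_art * n_samp) < config$artifact_share_prob,
                         n_art, n_samp, dimnames = list(NULL, ids))

  ## -- assemble site table, sorted by coordinate ------------------------
  chrom_all <- c(poly$chrom, mut$chrom, art$chrom)
  pos_all <- c(poly$pos, mut$pos, art$pos)
  n_site <- length(pos_all)
  g_all <- rbind(g, g_mut,
                 matrix(0L, n_art, n_samp, dimnames = list(NULL, ids)))
  kind <- rep(c("poly", "mutation", "artifact"), c(n_poly, n_mut, n_art))
  ord <- order(match(chrom_all, chroms), pos_all)
  chrom_all <- chrom_all[ord]; pos_all <- pos_all[ord]
  g_all <- g_all[ord, , drop = FALSE]; kind <- kind[ord]
  affected_all <- matrix(FALSE, n_site, n_samp, dimnames = list(NULL, ids))
  if (n_art > 0) {
    art_ord <- order(match(art$chrom, chroms), art$pos)
    affected_all[kind == "artifact", ] <- art_affected[art_ord, , drop = FALSE]
  }
  # ref/alt bases
  ref_all <- .rand_base(n_site)
  alt_all <- .rand_alt(ref_all)

  ## -- depth per sample per site (and masks) ----------------------------
  role <- stats::setNames(manifest$role, ids)
  role[role == "candidate_father"] <- "father"
  mean_cov <- config$coverage[role]
  names(mean_cov) <- ids
  site_x <- chrom_all %in% chroms[is_x]
  dp <- matrix(NA_integer_, n_site, n_samp, dimnames = list(NULL, ids))
  masks <- NULL
  if (isTRUE(config$make_masks)) {
    masks <- vector("list", n_samp); names(masks) <- ids
    for (s in ids) {
      mk_chrom <- character(); mk_start <- integer(); mk_end <- integer()
      for (ci in seq_along(chroms)) {
        mu_c <- if (is_x[ci] && sex[s] == "male") mean_cov[s] / 2 else mean_cov[s]
        d <- stats::rnbinom(lengths[ci], size = config$depth_dispersion,
                            mu = mu_c)
        r <- rle(d >= config$mask_threshold)
        ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
        keep <- r$values
        mk_chrom <- c(mk_chrom, rep(chroms[ci], sum(keep)))
        mk_start <- c(mk_start, starts[keep]); mk_end <- c(mk_end, ends[keep])
        here <- chrom_all == chroms[ci]
        dp[here, s] <- d[pos_all[here]]
      }
      masks[[s]] <- depth_mask(s, mk_chrom, mk_start, mk_end,
                               config$mask_threshold)
    }
  } else {
    for (s in ids) {
      mu_s <- ifelse(site_x & sex[s] == "male", mean_cov[s] / 2, mean_cov[s])
      dp[, s] <- stats::rnbinom(n_site, size = config$depth_dispersion,
                                mu = mu_s)
    }
  }

  ## -- allele depths, artifact injection, genotype calls ----------------
  eps <- config$error_rate
  q <- matrix(c(eps, 0.5, 1 - eps)[g_all + 1L], n_site, n_samp)
  q[affected_all & g_all == 0L] <- config$artifact_alt_fraction
  ad_alt <- matrix(stats::rbinom(n_site * n_samp, as.vector(dp), as.vector(q)),
                   n_site, n_samp, dimnames = list(NULL, ids))
  ad_ref <- dp - ad_alt
  pld <- matrix(2L, n_site, n_samp, dimnames = list(NULL, ids))
  pld[site_x, sex[ids] == "male"] <- 1L
  gt <- matrix(call_genotypes(as.vector(dp), as.vector(ad_alt), eps,
                              config$min_call_depth, as.vector(pld)),
               n_site, n_samp, dimnames = list(NULL, ids))

  records <- site_records(chrom_all, pos_all, ref_all, alt_all,
                          gt, dp, ad_ref, ad_alt)
  mut_ord <- order(match(mut$chrom, chroms), mut$pos)
  planted_key <- paste(mut$chrom, mut$pos)[mut_ord]
  site_key <- paste(chrom_all, pos_all)
  planted_rows <- match(planted_key, site_key)
  planted <- data.frame(chrom = mut$chrom[mut_ord], pos = mut$pos[mut_ord],
                        carrier = mut$carrier[mut_ord],
                        carrier_sex = mut$sex[mut_ord],
                        on_x = mut$on_x[mut_ord],
                        ref = ref_all[planted_rows],
                        alt = alt_all[planted_rows],
                        stringsAsFactors = FALSE)
  truth <- structure(list(
    true_father = true_father,
    planted = planted,
    artifacts = data.frame(chrom = art$chrom, pos = art$pos,
                           stringsAsFactors = FALSE),
    true_gt = g_all,
    site_kind = kind), class = "truth_set")
  structure(list(records = records, masks = masks, manifest = manifest,
                 ploidy = pl, truth = truth, config = config),
            class = "pedigree_sim")
}

#' @export
print.pedigree_sim <- function(x, ...) {
  cat("pedigree_sim:", n_sites(x$records), "sites,",
      nrow(x$manifest), "samples;",
      nrow(x$truth$planted), "planted mutations; true father",
      x$truth$true_father, "\n")
  invisible(x)
}

#' Write a simulated dataset to disk in standard formats
#'
#' Emits the joint VCF, per-sample BED depth masks, the sample manifest, the
#' ploidy map and the planted-mutation truth table -- exactly the inputs the
#' analysis stages consume.
#'
#' @param sim a [simulate_pedigree()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_joint_vcf(sim$records, file.path(dir, "joint.vcf"))
  write_manifest(sim$manifest, file.path(dir, "manifest.tsv"))
  write_ploidy_map(sim$ploidy, file.path(dir, "ploidy.tsv"))
  utils::write.table(sim$truth$planted, file.path(dir, "truth_mutations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sim$masks)) {
    mdir <- file.path(dir, "masks")
    dir.create(mdir, showWarnings = FALSE)
    for (s in names(sim$masks))
      write_depth_mask(sim$masks[[s]], file.path(mdir, paste0(s, ".bed")))
  }
  invisible(dir)
}
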