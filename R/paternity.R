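#' KING-robust kinship between two samples
#'
#' The between-sample robust kinship estimator computed from shared
#' heterozygosity and opposite-homozygote counts over autosomal biallelic
#' sites where both samples have a called genotype:
#' \deqn{\phi = \frac{N_{Aa,Aa} - 2\,N_{AA,aa}}{N_{Aa,i} + N_{Aa,j}}}
#' Expected values are ~0.5 for duplicates, ~0.25 for parent-offspring,
#' ~0 for unrelated samples; the estimator is robust to population
#' structure. A zero denominator (no heterozygous site in either sample)
#' yields an undefined result (`phi = NA`) rather than an error.
#'
#' @param g_i,g_j integer dosage vectors (0/1/2, `NA` missing) at the same
#'   sites.
#' @return list with `phi` and the supporting counts `n_both_het`,
#'   `n_opp_hom`, `n_het_i`, `n_het_j`, `n_sites` (sites called in both).
#' @examples
#' g <- c(0L, 1L, 2L, 1L, 0L)
#' king_kinship(g, g)$phi  # 0.5
#' @export
king_kinship <- function(g_i, g_j) {
  stopifnot(length(g_i) == length(g_j))
  ok <- !is.na(g_i) & !is.na(g_j)
  gi <- g_i[ok]; gj <- g_j[ok]
  n_both_het <- sum(gi == 1L & gj == 1L)
  n_opp <- sum((gi == 0L & gj == 2L) | (gi == 2L & gj == 0L))
  n_het_i <- sum(gi == 1L); n_het_j <- sum(gj == 1L)
  denom <- n_het_i + n_het_j
  phi <- if (denom > 0) (n_both_het - 2 * n_opp) / denom else NA_real_
  list(phi = phi, n_both_het = n_both_het, n_opp_hom = n_opp,
       n_het_i = n_het_i, n_het_j = n_het_j, n_sites = sum(ok))
}

# dosage matrix restricted to autosomal biallelic SNP sites
.autosomal_biallelic <- function(records, ploidy) {
  records <- filter_biallelic_snps(records)
  records[records$chrom %in% autosome_names(ploidy)]
}

#' Candidate-father x offspring kinship table
#'
#' Computes [king_kinship()] between every candidate father and every
#' offspring (focal and bait) over autosomal biallelic sites, with pairwise
#' deletion of missing calls. An optional minimum depth filter on both
#' members of each pair can be applied.
#'
#' @param records a [site_records()] object.
#' @param manifest a [sample_manifest()].
#' @param ploidy a [ploidy_map()].
#' @param min_dp optional minimum DP required of both samples at a site.
#' @return data.frame with columns `candidate`, `offspring`, `phi`,
#'   `n_sites`.
#' @export
kinship_table <- function(records, manifest, ploidy, min_dp = 0L) {
  rec <- .autosomal_biallelic(records, ploidy)
  cands <- father_ids(manifest)
  offs <- c(focal_ids(manifest), bait_ids(manifest))
  gt <- rec$gt
  if (min_dp > 0L) gt[is.na(rec$dp) | rec$dp < min_dp] <- NA_integer_
  grid <- expand.grid(candidate = cands, offspring = offs,
                      stringsAsFactors = FALSE)
  res <- mapply(function(ci, oi) {
    k <- king_kinship(gt[, ci], gt[, oi])
    c(phi = k$phi, n_sites = k$n_sites)
  }, grid$candidate, grid$offspring)
  grid$phi <- res["phi", ]
  grid$n_sites <- res["n_sites", ]
  grid
}

#' Rank-sum comparison of candidate-father relatedness
#'
#' For each candidate male, compares its kinship values with all offspring
#' against the pooled values of the other candidates by a one-sided
#' Wilcoxon rank-sum test (alternative: this candidate is more related).
#' The exact null distribution is enumerated when the combined sample size
#' is at most 20 and there are no ties; otherwise the normal approximation
#' with tie correction is used. If all values are tied the p-value is 1 and
#' selection falls back to the Mendelian concordance method.
#'
#' @param kin a [kinship_table()] result (or any data.frame with
#'   `candidate`, `offspring`, `phi`).
#' @return list with `table` (per-candidate mean/median phi and p-value)
#'   and `top` (the top-ranked candidate by mean kinship).
#' @export
rank_relatedness_test <- function(kin) {
  cands <- unique(kin$candidate)
  if (length(cands) < 2L) stop("need at least 2 candidate fathers")
  if (length(unique(kin$offspring)) < 3L) stop("need at least 3 offspring")
  out <- data.frame(candidate = cands, mean_phi = NA_real_,
                    median_phi = NA_real_, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(cands)) {
    own <- kin$phi[kin$candidate == cands[i]]
    rest <- kin$phi[kin$candidate != cands[i]]
    out$mean_phi[i] <- mean(own, na.rm = TRUE)
    out$median_phi[i] <- stats::median(own, na.rm = TRUE)
    own <- own[!is.na(own)]; rest <- rest[!is.na(rest)]
    if (length(unique(c(own, rest))) == 1L) {
      out$p_value[i] <- 1
    } else {
      exact <- (length(own) + length(rest) <= 20L) &&
        !anyDuplicated(c(own, rest))
      out$p_value[i] <- suppressWarnings(
        stats::wilcox.test(own, rest, alternative = "greater",
                           exact = exact)$p.value)
    }
  }
  list(table = out, top = out$candidate[which.max(out$mean_phi)])
}

#' Mendelian-concordance paternity test
#'
#' At autosomal biallelic sites where the mother and a candidate male are
#' homozygous for different alleles, every true offspring must be
#' heterozygous. For each candidate and each orientation (mother ref-hom x
#' candidate alt-hom, and the reverse) this counts the opposite-homozygote
#' sites and the subset at which all offspring with called genotypes are
#' heterozygous. The candidate maximising the total all-heterozygous count
#' is selected as the true father; a tie between candidates is an error
#' flagged for manual resolution.
#'
#' @param records a [site_records()] object.
#' @param manifest a [sample_manifest()].
#' @param ploidy a [ploidy_map()].
#' @return list with `table` (candidate, orientation, `n_sites`,
#'   `n_all_het`, `percent`) and `father` (selected candidate).
#' @examples
#' # mother 0/0, candidate 1/1 at 5 sites, all offspring 0/1 -> 5/5 = 100%
#' @export
mendelian_paternity <- function(records, manifest, ploidy) {
  rec <- .autosomal_biallelic(records, ploidy)
  mom <- mother_id(manifest)
  cands <- father_ids(manifest)
  offs <- c(focal_ids(manifest), bait_ids(manifest))
  gt <- rec$gt
  go <- gt[, offs, drop = FALSE]
  called <- !is.na(go)
  all_het <- rowSums(called & go == 1L, na.rm = TRUE) == rowSums(called) &
    rowSums(called) > 0L
  rows <- list(); totals <- numeric(length(cands))
  for (i in seq_along(cands)) {
    for (orient in c("ref_x_alt", "alt_x_ref")) {
      gm_target <- if (orient == "ref_x_alt") 0L else 2L
      gc_target <- 2L - gm_target
      sel <- !is.na(gt[, mom]) & !is.na(gt[, cands[i]]) &
        gt[, mom] == gm_target & gt[, cands[i]] == gc_target
      n_sites <- sum(sel)
      n_all_het <- sum(sel & all_het)
      rows[[length(rows) + 1L]] <- data.frame(
        candidate = cands[i], orientation = orient, n_sites = n_sites,
        n_all_het = n_all_het,
        percent = mendelian_percent(n_all_het, n_sites),
        stringsAsFactors = FALSE)
      totals[i] <- totals[i] + n_all_het
    }
  }
  tab <- do.call(rbind, rows)
  if (all(totals == 0))
    stop("no opposite-homozygote site supports any candidate; ",
         "cannot assess paternity")
  best <- which(totals == max(totals))
  if (length(best) > 1L)
    stop("tie between candidates ", paste(cands[best], collapse = ", "),
         "; manual resolution required")
  list(table = tab, father = cands[best])
}

#' Percentage of opposite-homozygote sites with all offspring heterozygous
#' @param n_all_het,n_sites integer counts.
#' @return percentage on the 0-100 scale, rounded to 2 decimals (`NA` when
#'   `n_sites` is 0).
#' @examples
#' mendelian_percent(6962, 9038)  # 77.03
#' @export
mendelian_percent <- function(n_all_het, n_sites) {
  ifelse(n_sites > 0, round(100 * n_all_het / n_sites, 2), NA_real_)
}

#' Full paternity analysis: kinship, rank-sum test and Mendelian concordance
#'
#' Runs both paternity strategies and selects the father by the Mendelian
#' all-heterozygous count (the sharper discriminator), with the kinship
#' rank-sum result reported as corroboration. A disagreement between the
#' two methods is reported with a warning.
#'
#' @param records a [site_records()] object.
#' @param manifest a [sample_manifest()] with >= 2 candidate fathers (with a
#'   single candidate the result is trivially that candidate).
#' @param ploidy a [ploidy_map()].
#' @return list of class `paternity_result`: `kinship`, `rank_test`,
#'   `mendelian`, `father`, and `manifest` (with the father confirmed and
#'   other candidates dropped).
#' @export
assign_paternity <- function(records, manifest, ploidy) {
  cands <- father_ids(manifest)
  kin <- kinship_table(records, manifest, ploidy)
  if (length(cands) >= 2L) {
    rt <- rank_relatedness_test(kin)
    mend <- mendelian_paternity(records, manifest, ploidy)
    if (!identical(rt$top, mend$father))
      warning("kinship top candidate (", rt$top,
              ") disagrees with Mendelian selection (", mend$father, ")")
    father <- mend$father
  } else {
    rt <- NULL
    mend <- mendelian_paternity(records, manifest, ploidy)
    father <- cands
  }
  structure(list(kinship = kin, rank_test = rt, mendelian = mend,
                 father = father,
                 manifest = confirm_father(manifest, father)),
            class = "paternity_result")
}

#' @export
print.paternity_result <- function(x, ...) {
  cat("paternity_result: selected father", x$father, "\n")
  print(x$mendelian$table, ...)
  if (!is.null(x$rank_test)) {
    cat("rank-sum relatedness test:\n")
    print(x$rank_test$table, ...)
  }
  invisible(x)
}
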