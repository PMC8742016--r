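# pedmut

Direct estimation of the spontaneous germline mutation rate — per site,
per generation — from whole-genome sequencing of a single mating pair
and its offspring.

`pedmut` is aimed at the pedigree/trio design used for insect (and
other high-fecundity) species: one mother, several candidate fathers of
which one is the true mate, deep-sequenced *focal* offspring screened
for de novo mutations, and shallow-sequenced *bait* offspring used only
to veto read-mismapping artifact sites shared between individuals. The
package provides the full analysis chain on joint-called VCF input, and
a synthetic pedigree generator with planted mutations for validating
every stage against known ground truth.

## The estimator

With `m` de novo mutations confirmed in the focal offspring, `C`
callable coordinates (depth ≥ 10 in mother, father and focal, summed
over trios, diploid-doubled, minus variant-caller-reported sites that
failed filtering), and a spike-in experiment in which `inserted`
synthetic mutations were placed at callable sites and `detected` of
them were recovered by the identical filters:

    mu = (m / C) x (inserted / detected)

The 95% CI applies the exact Poisson (Garwood) interval
`[chisq(a/2, 2m)/2, chisq(1-a/2, 2m+2)/2]` to `m` and scales it by the
same constants.

The detection filters: (i) both parents hom-ref, DP ≥ 10, zero
alternate reads; (ii) no alternate read in any bait sample; (iii) all
focal samples called, 1–2 heterozygous carriers (hemizygous-alt for
males on the X) with DP ≥ 10, the rest hom-ref with zero alternate
reads; (iv) carrier allele balance `0.27*DP <= AD_ALT <= 0.73*DP`
(inclusive, exact integer arithmetic). Paternity is confirmed
beforehand by KING-robust kinship (rank-sum compared across candidates)
and by Mendelian concordance at opposite-homozygote parental sites.

## Worked example

Simulate a pedigree at the default study-like conditions (4 candidate
males, 10 focal, 19 bait offspring, toy 1.2 Mb genome, true rate
2×10⁻⁶) and run the whole pipeline:

```r
library(pedmut)
cfg <- sim_config(mu_true = 2e-6, seed = 42)
sim <- simulate_pedigree(cfg)
res <- run_pipeline(sim, n_spikes_per_focal = 200, seed = 43)
res$funnel
#> filter funnel (surviving sites per stage):
#>                  stage     n
#>         total_variants 10155
#>         biallelic_snps 10155
#>      parents_homref_dp  1644
#>         no_alt_in_bait  1393
#>  called_in_every_focal  1366
#>   one_or_two_het_focal    25
#>    allele_balance_pass    23
res$fnr
#> FNR = 536/1942 = 27.6% (correction factor 1.3812)
res$rate
#> mutation rate: mu = 1.59e-06 per site per generation
#>   95% CI (1.01e-06, 2.38e-06)
#>   m = 23, C = 20,011,780, FNR correction = 1942/1406 = 1.3812
```

Read: of 10,155 variant records, 23 sites survived the four filters
(the true simulation planted 36 mutations in focal offspring, of which
the callable, in-band subset is recovered — with `m = 23` the ±1
Poisson fluctuation spans ~20%); the spike-in measured a 27.6% false
negative rate, and the corrected estimate 1.59×10⁻⁶ brackets the true
2×10⁻⁶ within its 95% interval. The paternity stage picked the true
father with kinship ≈ 0.25 versus ≈ 0 for distractors (rank-sum
p < 10⁻¹⁵).

On published study inputs the same estimator gives:

```r
estimate_rate(m = 3, callable = 3.89e9, inserted = 9914, detected = 7658)
#> mutation rate: mu = 9.98e-10 per site per generation
#>   95% CI (2.06e-10, 2.92e-09)
#>   m = 3, C = 3.89e+09, FNR correction = 9914/7658 = 1.2946
```

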