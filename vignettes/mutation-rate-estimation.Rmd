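---
title: "Estimating the spontaneous germline mutation rate from a sequenced pedigree"
author: "pedmut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the spontaneous germline mutation rate from a sequenced pedigree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedmut)
```

## The estimation problem

A direct estimate of the spontaneous single-nucleotide mutation rate
$\mu$ (per site, per generation) comes from sequencing a single mating
pair and many of its offspring, counting the de novo mutations $m$
observed in the offspring, and dividing by the number of opportunities
there were to see one. Two corrections make the denominator honest:

* **Callable sites** $C$: a mutation can only be seen at a coordinate
  where the mother, the father and the offspring were all sequenced
  deeply enough (here, depth $\ge 10\times$ in each). $C$ sums these
  coordinates over all deep ("focal") offspring and doubles the total,
  because each individual carries two chromosome copies at autosomal
  sites.
* **False negatives**: even at callable sites the filtering pipeline
  misses some true mutations (allele-balance cuts, stray reads in other
  samples). The miss rate is measured empirically by spiking synthetic
  mutations into the data and re-running the identical pipeline.

The estimator is
$$
\mu \;=\; \frac{m}{C}\times
\frac{\text{synthetic inserted}}{\text{synthetic detected}},
$$
with a 95% confidence interval obtained by applying the exact Poisson
(Garwood) interval to the count $m$,
$\big[\tfrac12\chi^2_{\alpha/2}(2m),\;
\tfrac12\chi^2_{1-\alpha/2}(2m+2)\big]$, and scaling by the same
constant $\frac{1}{C}\cdot\frac{\text{inserted}}{\text{detected}}$. The
chi-square construction was chosen because it reproduces the published
interval bounds of the study design this package targets to three
significant figures; treating the correction factor and $1/C$ as
constants is appropriate because their sampling error (thousands of
spikes, billions of sites) is negligible next to that of a count of
order 3–5.

```{r rate-example}
estimate_rate(m = 3, callable = 3.89e9, inserted = 9914, detected = 7658)
```

## Study design: focal and bait offspring

The pipeline assumes a mosquito-style design (karyotype XX/XY): one
mother, several candidate fathers of which exactly one is the true
mate, ~10 *focal* offspring sequenced deep (~20–46x) in which mutations
are sought, and ~20 *bait* offspring sequenced shallow (~9–20x). Bait
offspring exist only to veto sites: a genuine de novo mutation arises in
one individual, so any site where a bait sample also shows the
alternate allele is almost certainly a shared read-mismapping artifact,
not a mutation. This cheap redundancy is what makes the aggressive
artifact filtering possible.

## Paternity

Two independent methods identify the true father among the candidates,
using autosomal biallelic SNPs:

* **KING-robust kinship**: $\phi = (N_{Aa,Aa} - 2N_{AA,aa}) /
  (N_{Aa,i}+N_{Aa,j})$ for each candidate–offspring pair
  ($\approx 0.25$ parent–offspring, $\approx 0$ unrelated), compared
  across candidates by a one-sided Wilcoxon rank-sum test (exact
  enumeration up to a combined $n$ of 20, normal approximation with tie
  correction beyond).
* **Mendelian concordance**: at sites where the mother and a candidate
  are homozygous for different alleles, all true offspring must be
  heterozygous. The candidate maximising the all-heterozygous site
  count is selected. This is the decisive method (observed gaps are
  ~77–85% for the true father versus <0.2% for distractors); kinship
  corroborates it.

## Candidate mutation filtering

A biallelic SNP site is a candidate mutation if (i) both parents are
hom-ref with depth $\ge 10$ and zero alternate reads — missing AD is
treated as failure, because the criterion demands positive evidence of
zero; (ii) no bait sample shows any alternate read, and called bait
genotypes are hom-ref (baits with missing calls and no observed reads
do not veto); (iii) every focal sample is called, exactly 1 or 2 are
heterozygous carriers with depth $\ge 10$ (hemizygous-alternate for
males on the X; a male X het call is biologically impossible and
discards the site), the rest hom-ref with zero alternate reads; and
(iv) the carrier allele balance satisfies
$0.27\,\mathrm{DP} \le \mathrm{AD_{ALT}} \le 0.73\,\mathrm{DP}$,
inclusive, skipped for hemizygous male X carriers. The bounds are
compared in exact integer arithmetic ($27\,\mathrm{DP} \le
100\,\mathrm{AD_{ALT}} \le 73\,\mathrm{DP}$) so that boundary cases
cannot flip through floating-point rounding. The depth requirement in
(iii) is applied to carriers only; non-carriers need a call and zero
alternate reads. Each filtering stage logs its survivor count, giving
an auditable funnel.

Candidates surviving all four criteria may still be mis-mapping
artifacts; the study design resolves these by manual read inspection
and Sanger validation. As an automatable proxy, `flag_comapping_context()`
flags (but never removes) candidates with another record within 150 bp
(one read length) showing alternate reads in both the carrier and a
bait sample *while both parents are called hom-ref there*. The parental
condition is this package's design choice: without it any candidate in
a normally polymorphic neighbourhood is flagged, since nearby
segregating SNPs routinely place alternate reads in carrier and bait
alike; requiring unexplained parental-absent stray reads isolates the
artifact signature the manual step targets.

## Callable sites

Per-sample depth masks (BED intervals of coordinates at depth
$\ge 10$) are intersected exactly per mother–father–focal trio with
`GenomicRanges`. Coordinates reported by the joint caller that failed
the filters are then removed per trio — they have proven un-callable —
while surviving candidates' own coordinates remain. Totals are summed
over trios and doubled once. Two deliberate readings: the threshold is
inclusive ($\ge 10$) to stay consistent with criterion (i), and the
doubling is uniform across chromosomes, matching the study's
procedure; a `sex_aware_x` option is provided that counts male-focal X
coordinates once, documented rather than silently applied.

## Spike-in false-negative estimation

At sites where the parents are opposite homozygotes, every offspring is
an obligate heterozygote; the observed alternate-read counts at such
sites, binned by total depth 10–100, give an empirical allele-balance
distribution free of genotype-caller circularity. Synthetic mutations
are planted at random autosomal coordinates where both parents reach
the depth threshold: the focal sample's depth is resampled from its own
observed depths, the alternate-read count is drawn from the
depth-matched empirical table (empty bins fall back to
$\mathrm{Binomial}(d, 0.5)$, the obligate-het expectation), and the
genotype is re-called with the same caller settings as the main
analysis. The published workflow edits reads in BAM files; this package
spikes at the allele-count level instead, which is statistically
equivalent for a pipeline that consumes only GT/DP/AD, with the stated
limitation that alignment-level artifacts of read editing are not
emulated.

One consequence of count-level spiking required a design decision: at a
spiked (otherwise invariant) record the other samples' fields must be
synthesised too. Setting their alternate-read counts to a deterministic
zero would make the spike-in blind to a real miss channel — a single
stray alternate read in a parent (criterion i), bait (ii) or
non-carrier focal (iii) vetoes a genuine mutation, and read-level
spiking into real BAMs captures exactly that. `spike_mutations()`
therefore gives non-carrier samples background alternate reads at a
configurable rate `bg_alt_rate` (the pipeline wrapper uses the
dataset's per-read error rate). With the rate set to 0 the
deterministic-zero behaviour is recovered. Without this channel the
false-negative rate is underestimated and the corrected $\mu$ is biased
low by several percent at realistic error rates.

`FNR = (callable_inserted - detected) / callable_inserted`, counting
only spikes whose focal depth reached the threshold, and detection is
re-run with identical parameters.

## The synthetic pedigree generator

`simulate_pedigree()` generates the whole data shape the analysis
consumes, with ground truth for validation:

* founder genotypes under Hardy–Weinberg with allele frequencies
  uniform on [0.05, 0.95]; Mendelian transmission from the mother and
  one randomly designated true father; distractor males are unrelated
  founders; X transmission follows offspring sex (sons inherit the
  maternal X only).
* de novo mutations planted per offspring as Poisson with mean
  $2 L \mu_{\text{true}}$ on autosomes (1 or 2 $\times L_X \mu$ on the
  X by sex), at uniform coordinates not colliding with polymorphic
  sites.
* depth per sample per base negative-binomial (dispersion size 8,
  overdispersed as real coverage is; halved mean for male X);
  alternate-read counts binomial with success 0.5 for true hets,
  $\varepsilon$ for hom-ref, $1-\varepsilon$ for hom/hemizygous-alt.
  Masks are the exact runs of base depth $\ge 10$, so record depths and
  masks are mutually consistent.
* shared mis-mapping artifact sites at a configurable rate: each sample
  independently shows low-level alternate reads with probability 0.5
  (expected fraction 0.12 of depth), giving the bait veto something
  real to remove.
* maximum-likelihood genotype calls from the same binomial model, with
  calls below depth 4 set missing; hemizygous loci are called among the
  two homozygous states only.

Default conditions mirror the deeper of the two study designs: mean
coverages mother 20x / candidate males 32x / focal 26x / bait 13x, 4
candidate males, 10 focal, 19 bait, per-read alternate-error rate
$5\times10^{-4}$ (about a $1.5\times10^{-3}$ total miscall rate divided
over three alternate bases), true rate $5\times10^{-7}$ on a toy genome
of two 500 kb autosomes plus a 200 kb X. What the generator does *not*
emulate: read-level alignment, indels, recombination interference,
GC-coverage bias, and spatially autocorrelated coverage (mask intervals
are exact i.i.d.-depth runs, so real masks are blockier than simulated
ones). Passing tests therefore demonstrate the statistical correctness
of the estimator and filters under the stated generative model, not
robustness to alignment pathologies.

## Numerical and degenerate-input choices

* Allele-balance bounds inclusive, in integer arithmetic (above).
* Haploid VCF calls (`1`) and diploid-coded hemizygous calls (`1/1`)
  are normalised to the same dosage on input.
* A kinship denominator of zero returns an undefined $\phi$ rather than
  an error; an all-tied rank-sum comparison reports $p = 1$ and
  selection falls back to Mendelian concordance.
* A tie between candidate fathers in the Mendelian count is an error
  demanding manual resolution, not a silent choice.
* Zero detected spikes makes the correction undefined (fatal); zero
  observed mutations yields $\mu = 0$ with a zero lower and positive
  upper confidence bound.
* BED masks are 0-based half-open on disk, 1-based closed in memory;
  the conversion lives in one pair of helpers and is covered by a test.

## Validation scale

The shipped tests exercise every stage at desk scale, chosen so the
whole suite runs in minutes while each check retains statistical power:
paternity recovery uses 100 seeded 4-candidate pedigrees (1,500 SNPs
each); estimator calibration uses 500 replicates of an 80 kb toy genome
with 4 focal offspring and $\mu_{\text{true}} = 6\times10^{-6}$
(expected $m \approx 3.8$ per replicate, matching the published
regime of 3–5 events), checking mean recovery within 15% and $\ge 90\%$
CI coverage; spike/truth FNR consistency uses a 300 kb genome with
$\approx 100$ planted mutations compared at 3.5 combined standard
errors. Worked-number checks reproduce the published FNR percentages,
both corrected rates and all four CI bounds from their printed inputs.

## Limitations

Beyond the generator's stated simplifications: the package estimates a
single genome-wide rate (no per-chromosome or sex-specific
decomposition), treats two-carrier candidate sites as independent
events per carrier, does not model false positives (the study resolves
them by Sanger validation, proxied here by the advisory co-mapping
flag), and the X-chromosome callable accounting follows the uniform
doubling of the study design unless `sex_aware_x` is requested.
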