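# msatcc

Case–control association analysis for a single microsatellite locus, built
for wildlife disease studies where one polymorphic marker is suspected of
tagging a disease-susceptibility gene. The motivating design is a study of
urogenital carcinoma in California sea lions and the dinucleotide locus
Pv11 (intron 9 of the heparanase-2 gene *HPSE2*): diploid genotypes with
case/control status from two studies, paired skin/lesion electropherogram
peak heights for a heterozygote subset, and sequenced alleles of the form
(AC)₇(CA)ₙ…Cₘ.

The package covers, as plain R functions over data frames:

- **Homozygosity association** — the logit-link binomial model
  logit P(case) = β₀ + β₁·I(homozygous), with OR = e^β̂₁, 95% Wald
  intervals, likelihood-ratio p-values, and a two-sided Fisher exact test
  (probability method). Zero cells trigger a flagged Haldane–Anscombe
  correction.
- **Per-allele stratified analysis** — carriage strata (one per allele,
  heterozygotes in both their strata), Mantel–Haenszel common OR
  OR_MH = Σaᵢdᵢ/nᵢ ÷ Σbᵢcᵢ/nᵢ with Robins–Breslow–Greenland intervals,
  continuity-corrected CMH χ², and the Breslow–Day–Tarone homogeneity
  test.
- **Genotype risk profiles** — per-genotype binomial distributions on the
  probability grid 0.00–0.99 (step 0.01), with medians and 2.5th/97.5th
  percentile limits, ranked and compared by interval overlap.
- **Loss of heterozygosity** — the paired-tissue peak-height ratio
  (N₂/N₁)/(T₂/T₁), loss calls outside the strict (0.5, 2.0) band, a
  partial-loss flag, cohort summaries and the loss-by-status Fisher test.
- **Repeat structure** — parsing of (AC)-anchored CA microsatellites,
  somatic contraction/expansion detection between tissues, global
  alignment, sliding-window percent identity and low-identity masking.
- **Synthetic data** — a generator for the whole design (inbred genotype
  frequencies, homozygosity-linked disease, noisy peak heights with
  injected allele loss, repeat sequences with injected contractions) so
  every stage is testable end to end with no external data.

## Worked example

Simulate a cohort at the default study conditions (371 animals, 5 alleles
with one dominant, F = 0.10, true homozygosity OR 1.8) and run the full
association stage:

```r
library(msatcc)
rec <- simulate_cohort(sim_config(seed = 1))
associate_homozygosity(rec)[, c("analysis", "stratum", "odds_ratio",
                                "ci_low", "ci_high", "p_value")]
#>                analysis     stratum odds_ratio ci_low ci_high p_value
#> 1  homozygosity_glm_lrt      pooled      1.217  0.790    1.87   0.373
#> 2   homozygosity_fisher      pooled      1.216  0.771    1.91   0.379
#> 3          mh_common_or all_alleles      1.243  0.830    1.86      NA
#> 4              cmh_chi2 all_alleles      1.243  0.830    1.86   0.342
#> 5    tarone_homogeneity all_alleles      1.243     NA      NA   0.469
#> 6        allele_glm_lrt           1      1.161  0.708    1.90   0.555
#> ...
```

Row 1 is the pooled homozygosity odds ratio (1.22 here — a single cohort
of this size frequently fails to reach significance even with a true OR
of 1.8, which is exactly the power situation such studies face); rows 3–5
pool the same question over per-allele carriage strata, and the Tarone
p = 0.47 says the per-allele ORs are mutually consistent.

The canonical loss-of-heterozygosity cohort — 33 heterozygotes (7 cases,
26 controls), allele loss in exactly one case — and a constructed loss
animal:

```r
fisher_exact_two_sided(table2x2(1, 0, 6, 26))
#> assoc_result [fisher]
#>   OR = Inf (95% CI 0.09524, Inf)
#>   p = 0.2121

r <- loh_ratio(100, 100, 100, 44)   # (N2/N1)/(T2/T1) = 2.27
classify_loh(r, T1 = 100, T2 = 44)
#>   animal_id    ratio           call partial
#> 1      <NA> 2.272727 loss_suggested    TRUE
```

The ratio 2.27 exceeds the strict 2.0 threshold, so loss is suggested,
but both lesion peaks remain detectable — a partial rather than complete
loss — and the Fisher p of 0.212 says one loss among seven cases is not
evidence that LOH tracks disease.

Per-genotype risk profiles use a binomial distribution over a probability
grid:

```r
binomial_profile(5, 10)
#> risk_profile : k = 5 / n = 10, median = 0.50 (0.23, 0.77)
```

A command-line wrapper for the whole pipeline (simulate → assoc →
profile → loh → seqscan, with a reproducibility manifest) is installed at
`inst/scripts/msatcc`; see also `run_all()`.

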