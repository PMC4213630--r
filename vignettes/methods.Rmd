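---
title: "Methods: single-locus microsatellite case-control analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-locus microsatellite case-control analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msatcc)
```

## The study design this package models

msatcc implements the statistical core of a single-locus microsatellite
case-control study of the kind used to link homozygosity at a candidate
marker to a disease phenotype in a wild population — the motivating
application is urogenital carcinoma (UGC) in California sea lions and the
dinucleotide locus Pv11, which sits in intron 9 of the heparanase-2 gene
(*HPSE2*). Each animal contributes one diploid genotype (two allele labels),
a binary disease status, and a study label; subsets of animals additionally
contribute paired-tissue electropherogram peak heights (normal skin vs
lesion tissue) and sequenced alleles.

Five analysis questions are covered, each by one module:

1. Is homozygosity at the locus associated with disease? (logit-link
   binomial model, Fisher exact test)
2. Is the association consistent across allele groups? (Mantel-Haenszel
   common OR, CMH chi-squared, Breslow-Day-Tarone homogeneity)
3. Do specific genotypes carry elevated risk? (grid-based binomial risk
   profiles)
4. Do lesions lose one allele, or contract the repeat? (LOH peak-height
   ratio; repeat-structure comparison between tissues)
5. Where does the locus sit relative to a reference sequence? (global
   alignment, sliding-window identity, low-identity masking)

## Association model

The exposure is homozygosity (`allele_a == allele_b`), the outcome is
case status. `fit_logit_or()` fits

$$\mathrm{logit}\, P(\text{case}) = \beta_0 + \beta_1 \, I(\text{homozygous})$$

by iteratively reweighted least squares (deviance tolerance $10^{-10}$,
at most 100 iterations) and reports $\widehat{OR} = e^{\hat\beta_1}$, the
Wald interval $e^{\hat\beta_1 \pm 1.96\,SE}$, and a likelihood-ratio
p-value from $2(\ell_{\text{full}} - \ell_{\text{null}})$ against
$\chi^2_1$. With all four cells of the 2x2 table positive this equals the
cross-product ratio $ad/bc$ exactly; the test suite asserts agreement to
$10^{-8}$ relative. These are crude (unadjusted) odds ratios by design:
no covariate adjustment is attempted, and no multiplicity correction is
applied across the per-allele fits.

**Zero cells.** When a cell is zero the MLE lies on the boundary. The
package then applies the Haldane-Anscombe correction (+0.5 to all four
cells) to the point estimate and interval only, keeps the LRT p-value from
the uncorrected fit (the deviance limit is finite), and flags the result
`corrected = TRUE` so downstream reports can disclose the policy.

**Per-allele strata.** `build_allele_strata()` forms one stratum per
observed allele: stratum $i$ holds every carrier of allele $i$, with
exposure "homozygous $i,i$". A heterozygote $i,j$ therefore appears in
two strata. This carriage-based construction is deliberate and is the
conventional way to ask "does any allele drive the homozygosity signal",
but it means strata share animals and are **not independent**; the
Mantel-Haenszel machinery is used on them as a descriptive pooling device.
The simulation experiments below show that at the operating conditions
modelled here the CMH test's size is nevertheless close to nominal, but
this should not be assumed for very different designs. The
Mantel-Haenszel estimate is
$\widehat{OR}_{MH} = \sum_i a_i d_i / n_i \,/\, \sum_i b_i c_i / n_i$
with a Robins-Breslow-Greenland variance for the interval; the CMH
statistic uses the conditional hypergeometric mean and variance of each
stratum's exposed-case cell, with the 0.5 continuity correction **on by
default** (matching how such tests are conventionally reported for sparse
strata; switch it off with `continuity = FALSE`).

**Homogeneity.** `tarone_homogeneity()` evaluates the Breslow-Day
statistic at $\widehat{OR}_{MH}$: per stratum the expected exposed-case
cell $\tilde a_i$ solves the common-OR quadratic
$(1-\psi)\tilde a^2 + (n - r_1 - c_1 + \psi(r_1+c_1))\tilde a - \psi r_1 c_1 = 0$
in the fixed margins (the admissible root; the test suite checks the
residual to $10^{-10}$), and Tarone's correction
$(\sum_i (a_i - \tilde a_i))^2 / \sum_i \widehat{Var}(\tilde a_i)$ is
subtracted before referral to $\chi^2_{K-1}$. Strata with an empty margin
are inestimable and are dropped from both $K$ and the statistic.

**Fisher exact test.** Two-sided by the probability method: the p-value
sums every hypergeometric point probability on the support that does not
exceed the observed one (relative tolerance $1+10^{-7}$ for floating-point
ties). This is the convention that reproduces the textbook two-sided
values for sparse tables such as the loss-of-heterozygosity cohort below.

## Genotype risk profiles

For a genotype seen in $k$ cases out of $n$ animals,
`binomial_profile()` evaluates the binomial probability
$\binom{n}{k} p^k (1-p)^{n-k}$ on the grid
$p \in \{0.00, 0.01, \ldots, 0.99\}$ and normalises — equivalent to a
posterior under a uniform prior restricted to the grid. The phrase
"cumulative binomial distribution" is genuinely ambiguous between this
likelihood reading and the CDF $P(X \le k; n, p)$; the likelihood reading
is the default because it yields a proper, interpretable distribution of
the case probability, and `mode = "cdf"` provides the alternative. The
grid deliberately stops at 0.99 (no extrapolation to 1), and the median
and the 2.5th/97.5th percentile limits are taken at the **first crossing**
of the discrete cumulative weights — a deterministic, conservative
tie-break. The suite verifies that the grid median stays within one grid
step (0.01) of the conjugate Beta$(k+1, n-k+1)$ median for all
$k \le n \le 100$, is monotone in $k$, and moves by at most one coarse
step under grid refinement to 0.001.

`compare_profiles()` ranks genotypes by median and reports which other
genotypes' medians lie at or above the top genotype's lower limit — the
interval-overlap reading used to judge whether the apparently riskiest
genotype is actually distinguishable. No formal pairwise test is attached;
the stratified CMH analysis is the inferential complement.

## Loss of heterozygosity

For a heterozygote with matched normal (N) and lesion (T) tissue, the
ratio is $(N_2/N_1)/(T_2/T_1)$. Replicate runs are averaged per allele per
tissue before the ratio is formed (the aggregation has to happen
somewhere; averaging first keeps the ratio a ratio of mean signals).
Allele loss is called when the ratio is **strictly** below 0.5 or
**strictly** above 2.0 — a ratio of exactly 2.0 is retained — and the
calls are reciprocal-symmetric (0.4 and 2.5 are both loss). Alleles are
ordered by label identically in both tissues; the reciprocal symmetry
makes the call order-independent.

A loss call with both lesion peaks still detectable is flagged `partial`:
the genotype call is unchanged even though the balance shifted, i.e.
partial rather than complete allele loss. "Detectable" means above a
configurable floor, default 10% of the taller lesion peak — a typical
analysis threshold for calling an allele present on a capillary trace;
there is no canonical value, which is why it is exposed as
`floor_frac`. No modelling of stutter, pull-up or other electrophoresis
artefacts is attempted: heights arrive as numbers.

`loh_cohort_summary()` produces per-group ratio ranges and the loss-by-
status 2x2 table handed to the Fisher test. The canonical worked cohort —
33 heterozygotes (7 cases, 26 controls) with loss in exactly one case —
gives the table (a=1, b=0, c=6, d=26) and p = 7/33 = 0.212.

## Repeat structure and instability

The locus architecture is a lead of AC dinucleotide units (seven in the
modelled locus), a variable CA tract, and a trailing mononucleotide C run:
$(AC)_7 (CA)_n \ldots C_m$. `parse_repeat_structure()` anchors on the
**leftmost** maximal $(AC)^+$ run, then reads the longest $(CA)^+$ run
starting exactly at the lead's end, then the longest $C^+$ run. Leftmost —
not longest-anywhere — is essential: the interior of any $(CA)_n$ tract
itself contains an $(AC)_{n-1}$ run, so a longest-run rule would anchor
inside the variable tract of long alleles. Somatic instability is then a
difference in parsed CA counts between tissues (`detect_imbalance()`):
negative = contraction, positive = expansion. Poly-C differences are
reported but never enter the call, because mononucleotide runs slip during
amplification at rates that would swamp a biological signal.

## Sliding-window identity and masking

`sliding_identity()` works in alignment-column space: each window of
`window` columns (default 100, step 1) scores the fraction of columns
where both sequences carry the same unambiguous base. Gap-vs-base,
gap-vs-gap and anything involving N count as mismatches — the scan is a
conservative measure of demonstrated identity, and a column of two gaps
demonstrates nothing. Coordinates are 1-based inclusive window starts.

`low_identity_mask()` flags columns of persistently low identity using
per-column coverage semantics: a column is masked only when **every**
`span`-column window (default 50) covering it falls below `min_identity`
(default 25%). One geometric consequence deserves emphasis: with
identical flanks, a fully mismatched insert must be at least
span + 2·floor(span·min_identity/100) + 1 columns wide (75 for the
defaults) before any column loses all of its high-identity context — the
masked region of a wide insert is the insert minus ~37 columns at each
edge. The mask is therefore a high-specificity annotation of the
genuinely alignment-free core of a divergent region, such as the unstable
microsatellite itself inside otherwise conserved intronic sequence, not a
sensitive edge detector. Masked runs export as 1-based inclusive
intervals (`mask_intervals()`).

`global_align()` (Needleman-Wunsch, match +1, mismatch −1, linear gap −2)
is delegated to `Biostrings::pairwiseAlignment()` with a zero gap-opening
cost; its tie-break among co-optimal alignments is Biostrings' own
deterministic one. The optimal score — the only quantity downstream code
consumes — is tie-break independent, and the suite checks it against
exhaustive enumeration on short sequences.

## The synthetic-data generator

`sim_config()` fixes the study conditions the package is validated under:

| parameter | default | rationale |
|---|---|---|
| `n_animals` | 371 | combined two-study cohort size emulated |
| `allele_freqs` | 0.55, 0.20, 0.12, 0.08, 0.05 | 5-allele locus with one dominant allele |
| `inbreeding_f` | 0.10 | excess homozygosity typical of a polygynous, philopatric pinniped population |
| `baseline_logit` | qlogis(0.30) | necropsy cohorts are enriched for disease (~26% prevalence among necropsied strandings) |
| `hom_log_or` | log(1.8) | homozygotes roughly twice as likely to be cases |
| `loh_fraction` | 1/7 | one of seven heterozygous cases with allele loss |
| `loss_factor` | 0.44 | one lesion peak reduced to 44%, i.e. a noise-free ratio of 1/0.44 = 2.27 |
| `peak_cv` | 0.10 | multiplicative log-normal peak noise; heights are positive and instrument noise scales with signal |
| `replicate_fraction` | 0.5 | half the animals run twice |
| `contraction_count` | 3 | three animals with a somatic CA contraction |

Genotypes follow the inbreeding-adjusted frequencies
$P(ii) = p_i^2 + F p_i(1-p_i)$, $P(ij) = 2 p_i p_j (1-F)$; disease is
Bernoulli with $\mathrm{logit}^{-1}(\beta_0 + \beta_1 I(\text{hom}))$.
$F$ is phenomenological — there is no pedigree or coalescent behind it —
and the same $F$ applies to every allele. One global seed fans out to
fixed per-stage substreams, so regenerating one stage never perturbs
another and a full dataset is byte-identical under a fixed config.

What the generator does **not** emulate: genotyping error and allelic
dropout in the input genotypes, stutter and pull-up in peak heights,
study-specific allele frequency differences, linkage with other loci, and
any real pedigree structure. Passing tests therefore demonstrate that the
statistics recover the parameters of this idealised design, not that the
pipeline is robust to the artefacts of real capillary data.

Sequence constructs place constrained random flanks around the repeat
(the 5' flank contains no AC dinucleotide; the 3' flank cannot extend the
poly-C, convert a single trailing C into an extra CA unit, or extend the
lead when both tracts are empty) so that parsing inverts construction
exactly — a property the suite checks on 100 random constructs.

`sample_stratified_tables()` generates *independent* strata under an
exact common odds ratio (per-stratum baselines drawn uniformly); it is
the null configuration for the homogeneity test's size experiment,
deliberately free of the shared-animal dependence of carriage strata.

## Validation experiments and problem sizes

The test suite runs, at fixed seeds:

- parameter recovery: 200 cohorts of n = 500 at true OR 1.8, F = 0.1 —
  mean fitted log-OR within ±0.05 of log(1.8) and 95% CI coverage within
  [0.92, 0.98];
- size: 1000 null cohorts (n = 500, $\beta_1 = 0$) for the LRT and the
  corrected CMH on carriage strata, and 1000 independent-strata draws
  (K = 4, 100/stratum, common OR 1.8) for Tarone — each rejection rate
  within 3 Monte-Carlo standard errors of 0.05;
- oracle equivalence: 500 random tables against hypergeometric
  enumeration, 500 stratified configurations against direct-formula
  evaluation, plus the Beta-median, brute-force-identity and exhaustive-
  alignment checks described above.

These sizes were chosen so the Monte-Carlo error of each experiment is
small relative to the tolerance it asserts.

## Known limitations

- The combined-study analysis is pooled by default; a study-stratified
  variant is available by building per-study tables and passing them to
  the Mantel-Haenszel functions, but no study-adjusted logistic model is
  provided (the single-covariate model is the analysis being modelled).
- Carriage strata violate the independence assumptions of the CMH
  framework by construction (documented above).
- The allele labels are opaque: no binning of raw fragment sizes is
  performed, so instrument-side allele calling must happen upstream.
- The LOH partial-loss flag depends on the configurable detection floor;
  there is no universally accepted value.
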