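---
title: "Methods: haplotype structure and compound-genotype analysis of ERAP2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype structure and compound-genotype analysis of ERAP2}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erap2hap)
```

## The scientific setting

ERAP2 is an endoplasmic-reticulum aminopeptidase involved in antigen
trimming and a candidate gene for preeclampsia. Two of its SNPs carry the
functional load in this package's analyses:

* **rs2248374** (G/A): the G allele creates a splice variant removed by
  nonsense-mediated decay, so G is a functional **null** — full-length
  ERAP2 protein dosage equals the count of A alleles.
* **rs2549782** (T/G): a coding variant (N392K). The T allele encodes 392N,
  the G allele 392K; because only A-carrying haplotypes at rs2248374 are
  expressed, which 392 variant appears depends on the **phase** of the two
  SNPs.

In all previously characterized populations these two SNPs (plus rs2548538,
rs2287988, rs1056893) sit on two deeply diverged haplotypes in near-perfect
LD, so 392N is never expressed. A Chilean cohort breaks this pattern:
rs2549782 is only partially linked to the other four SNPs, making 392N
expression — and the double homozygote AA,TT that would express it from both
chromosomes — possible for the first time. The pipeline here quantifies that
structure and the conspicuous absence of AA,TT individuals.

## Data model

Genotypes are unphased biallelic calls stored as minor-allele dosage
(0/1/2/NA). Phase is never read from input: it cannot be measured by the
genotyping assays this data model represents, and enters only as an optional
argument to the expression predictor and as latent structure estimated by
EM. Missing calls are excluded per SNP (pairwise deletion); this mirrors
cohort tables whose two-SNP totals (1097) fall short of the cohort size
(1100).

## Haplotype frequency estimation (EM)

`em_haplotype_freqs()` maximizes the multinomial likelihood of unphased
K-locus genotypes over the $2^K$ haplotype frequencies (gene counting /
Excoffier–Slatkin). The E-step distributes each ambiguous multi-het
genotype over its $2^{h-1}$ compatible haplotype pairs in proportion to
current frequency products; the M-step re-counts. The log-likelihood is
non-decreasing (asserted in the test suite). Defaults: tolerance $10^{-9}$
on the log-likelihood change, 1000 iterations maximum, 5 starts (the first
an equal split of ambiguous mass, the rest Dirichlet draws under a fixed
seed), frequencies below $10^{-6}$ reported as zero and renormalized.
Samples missing any of the K SNPs are dropped for that estimate.

For two loci the only free parameter given the allele-frequency margins is
the coupling frequency, and the EM fixed point can be solved independently;
the tests compare the EM to that fixed point and to a $10^{-4}$-step grid
maximizer.

## LD statistics and a sign convention

For a SNP pair with minor-allele frequencies $p_a, p_b$ and minor–minor
haplotype frequency $p_{ab}$:

$$D = p_{ab} - p_a p_b,\qquad
D' = |D| / D_{max},\qquad
r^2 = D^2 / \big(p_a(1-p_a)\,p_b(1-p_b)\big)$$

with $D_{max} = \min\{p_a(1-p_b), (1-p_a)p_b\}$ for $D>0$ and
$\min\{p_a p_b, (1-p_a)(1-p_b)\}$ for $D<0$. **Convention:** $D$ is defined
on the haplotype carrying the minor allele at both SNPs. Relabelling either
SNP's alleles flips the sign of $D$ but leaves $|D|$, $D'$ and $r^2$
unchanged; for the Chilean fetal rs2248374–rs2549782 pair this convention
gives $D \approx +0.107$, $D' \approx 0.49$, $r^2 \approx 0.23$.

## Haplotype blocks

Three standard rules, all operating on input SNP order (no physical
distances; the five ERAP2 SNPs are treated as ordered along the locus):

* **Confidence intervals** (Gabriel-style): a likelihood-based CI for
  $|D'|$ is computed per pair by profiling the 2-locus genotype likelihood
  over a 0.01-step $|D'|$ grid at the observed margins and treating the
  normalized likelihood as a distribution (5%/95% bounds). A pair is in
  *strong LD* if CI-low ≥ 0.70 and CI-high ≥ 0.98, *recombinant* if
  CI-high < 0.90; a span is a block when its outer pair is strong and
  ≥ 95% of informative pairs are strong. These thresholds are the published
  defaults of the method; the CI construction itself is our choice, since
  none is prescribed by the rule's common statement.
* **Four-gamete rule**: a break between adjacent SNPs whenever all four
  2-locus haplotypes reach frequency 0.01 (EM-estimated); maximal unbroken
  runs are blocks.
* **Solid spine**: a run is a block when its first and last SNP each have
  $D' \ge 0.80$ with every intermediate SNP. Whether *interior* pairs are
  also in strong LD is reported as a diagnostic rather than enforced —
  matching how the rule is usually run, while still surfacing weakly linked
  interior pairs.

Longer candidate spans are accepted first, without overlap. Acceptance-level
checks require only block *membership* (5-SNP block vs 4-SNP block plus the
excluded SNP), not threshold-exact agreement with any particular tool,
because published analyses state "default parameters" without printing them.

## Compound genotypes and expected counts

`expected_counts()` supports two nulls for the 3×3 two-SNP table:

* **`naive_product`** — each cell's frequency is the bare product of its
  four constituent allele frequencies (the AA,TT cell is
  $0.34^2 \times 0.67^2 = 0.052$; the AA,TG cell is
  $0.34^2 \times 0.67 \times 0.33$, with *no* factor 2). This reproduces the
  published expectation tables exactly (57/28/14/111/215 at $n = 1100$),
  which demonstrably omit heterozygote multiplicity. It is the default for
  reproduction runs.
* **`hwe_multinomial`** — product of Hardy–Weinberg genotype probabilities
  ($2pq$ for heterozygotes), summing to $n$ exactly. This is the
  statistically standard null and the recommended mode for new analyses.
  Both are always reported side by side by `compound_report()`.

Allele frequencies feeding the expectations are rounded to 2 decimals in
paper-fidelity mode (matching printed 0.34/0.67) and used at full precision
otherwise. The observed-vs-expected test is a 1-df cell-versus-rest
chi-square, $(O-E)^2/E + ((n-O)-(n-E))^2/(n-E)$; the published per-cell
p-values were produced by an unstated construction and are matched only in
order of magnitude (the zero observed AA,TT count against expectation 57
gives $p \approx 10^{-14}$ here).

`detection_power()` deliberately exposes two models — the probability of
sampling at least one carrier, $1-(1-p)^n$, and the power of the
cell-vs-rest chi-square under a stated alternative — rather than asserting
any single published power figure, whose generating model is not stated and
is not reproducible from the printed frequencies.

## Expression prediction

ERAP2 dosage = number of rs2248374 A alleles. 392N dosage = number of
chromosomes pairing rs2248374-A with rs2549782-T: deterministic for eight
of the nine compound genotypes, and `phase_dependent` for the AG,GT double
heterozygote unless a phase is supplied. The test suite checks that
phase ambiguity arises exactly when the two compatible phases disagree.

## Association and epistasis

Hardy–Weinberg: exact conditional test (heterozygote-count distribution
given allele counts, two-sided by summing configurations no more probable
than observed) when the minor-allele count is below 100, chi-square
otherwise. Allelic association: two-sided Fisher exact on the 2×2 allele
table, with the Haldane 0.5 correction applied to the odds ratio only when
a cell is zero. Genotypic association: Pearson chi-square with zero rows
dropped. Multiple testing: Bonferroni. The interaction test regresses case
status on the two minor-allele dosages and their product (additive coding
0/1/2 by default, matching standard epistasis-testing practice; dominant
coding available) and reports the 1-df likelihood-ratio test, chosen over
the Wald test for stability at small cell counts.

## The synthetic cohort generator

`simulate_cohort()` draws two independent haplotypes per sample (random
mating, no inbreeding parameter) from fixed haplotype frequencies, collapses
them to unphased dosages, and masks calls independently at the configured
missingness. Defaults encode the study conditions: $n = 1100$, missingness
0.003 (reproducing two-SNP totals of ≈1097/1100), case fraction
$528/1103$ under the null risk model.

Presets:

* `african_american_5snp`: GTAGC/TAGAT at 0.436/0.564.
* `chilean_4snp_plus_partial`: block haplotypes TAGC/AGAT at 0.339/0.661
  with rs2549782 (G at 0.33) mixed on at a target block D' of 0.53 (the
  midpoint of the reported 0.52–0.54 range). The four 5-SNP class
  frequencies are free parameters because phased 5-SNP frequencies were
  never measured in Chileans; the default mix (G+TAGC 0.2275, T+TAGC
  0.1115, G+AGAT 0.1025, T+AGAT 0.5585) reproduces the printed marginals
  and intermediate D'. Setting the T+TAGC class (the A–T recombinant) to
  zero makes AA,TT structurally impossible, emulating its observed absence.

What the generator does **not** emulate: genotyping error, per-SNP
differential missingness, maternal–fetal relatedness (dyads are ignored;
every sample is independent), population admixture, and recombination or
mutation within the locus (haplotype frequencies are taken as given). Tests
passing on these simulations therefore validate the statistical machinery
under the declared structure, not robustness to those real-data features.

## Numerical choices and problem sizes

Degenerate inputs: monomorphic SNPs give flagged (NA) LD and a warned
p = 1 HWE result; zero expected cells raise; separation in the logistic
model is flagged, not raised. Ties in the Fisher and exact-HWE tail sums
use a $1+10^{-12}$ relative slack, the standard guard against
floating-point ties. EM restarts use a fixed seed and restore the caller's
RNG state.

Simulation-based checks use sizes chosen to keep the full suite fast while
leaving comfortable statistical margins: 100 seeds for block-structure
recovery, 400 replicates for type-I-error calibration (binomial SE ≈ 0.011
at $\alpha = 0.05$, against an acceptance band of [0.03, 0.07]), and
$n = 1100$ cohorts matching the study scale.

## Known limitations

* The EM returns population frequencies only; individual phase calls (and
  their uncertainty) are out of scope.
* Block calling is designed for the handful of ordered SNPs typical of a
  candidate-locus study, not genome-scale windows.
* Published raw-data association p-values (0.46, 0.78, 0.842) depend on
  per-SNP missingness patterns that the printed tables do not carry; the
  pipeline reproduces their non-significance, not their digits.
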