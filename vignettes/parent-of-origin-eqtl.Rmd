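---
title: "Mapping parent-of-origin cis-eQTLs in trios: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping parent-of-origin cis-eQTLs in trios: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pofoqtl)
```

## Why trios

A conventional eQTL regression of expression on diploid dosage assumes the
two parental alleles act identically. An imprinted regulatory element acts
on one parental allele only, so its true model is
$y = \beta_0 + \beta\,X_{par} + \varepsilon$ for one parent's allele
$X_{par}$, while the conventional test fits
$y = \beta_0' + \beta'\,(X_{MAT}+X_{PAT}) + \varepsilon$ and recovers a
slope near $\beta/2$ with the unmodeled haplotype acting as extra noise.
At stringent genome-wide thresholds that dilution is usually fatal.

Trios remove the ambiguity without external phase information. At a
biallelic SNP, a homozygous mother can only have transmitted her one
allele; the child's other allele is then paternal, whatever the father's
genotype. Working through the $3^3$ ordered genotype combinations shows
that parental origin in the child is determined exactly when the trio
contains at least one homozygote: the only unresolvable configuration with
complete genotypes is the all-heterozygous trio. Under Hardy–Weinberg
equilibrium and random mating the all-heterozygous probability is
$(2pq)^2/2$ — at worst (MAF 0.5) 12.5% of sites, and under a realistic
common-variant spectrum the package's phasing assigns roughly 92–95% of
fully genotyped sites. `assign_parental_origin()` implements the rules as
a 27-entry decision table; cells are flagged `missing`,
`unassigned_triple_het` or `mendelian_error` rather than guessed, and
every downstream test excludes all non-assigned cells.

Two deliberate choices here:

* **Mendelian errors are per-cell, not per-SNP.** A single inconsistent
  family does not discard a SNP for everyone; the inconsistent (child,
  SNP) cell alone becomes unusable. Nothing in the screening design
  requires a site-level error rule, and per-cell exclusion maximizes the
  usable data.
* **Input phase is ignored.** Phased VCFs are read as unordered genotype
  pairs; origin is always re-derived from the trio itself, so phased and
  unphased inputs give identical results.

## The four association regimes

For every SNP within ±1 Mb of a probe midpoint (`floor((start+end)/2)`,
boundary inclusive on both the window and the midpoint):

* **maternal / paternal** — OLS of log2 expression on the 0/1 minor-allele
  indicator of the stated haplotype, Wald $t$ with $n-2$ df, two-sided.
  The minor allele is fixed once per SNP over the combined cohort so that
  the coding is identical across regimes and populations (ties at
  frequency 0.5 take the B/ALT allele as minor).
* **heterozygote** — among phased heterozygotes, the two reciprocal
  classes ($A_{MAT}B_{PAT}$ vs $A_{PAT}B_{MAT}$) have identical genotype,
  so any expression difference is parent-of-origin evidence. The group
  indicator regression is algebraically the pooled-variance two-sample
  $t$-test, and the implementation is property-tested against `t.test()`
  for exact agreement. With fewer than `min_het = 8` informative
  heterozygotes the pair is reported untested — below that the test is
  uninformative at these effect sizes, and this mirrors the threshold the
  screening design applies.
* **conventional** — OLS on diploid dosage 0/1/2, the baseline every
  other regime is contrasted against.

Equivalent results are obtained by recoding the haploid parental alleles
as artificial homozygous diploids for a standard association tool; that
recoding doubles the dosage scale and halves the slope while leaving $t$
and $p$ unchanged. Betas here are reported on the natural 0/1 haploid
scale.

`min_n` defaults to 20 informative children for the regression regimes.
The screening design is silent on a minimum; 20 keeps the $t$
approximation and the dosage-class balance reasonable at the 59-trio scale
this method targets while discarding few pairs. Bonferroni correction is
per probe within each regime, with the multiplier equal to the number of
*tested* cis SNPs for that probe (untested pairs are excluded from the
universe), and `p_bonferroni = min(1, m p)`.

## Calling rules

Per probe and parental regime the best SNP is the minimum nominal $p$
among tested pairs, with deterministic tie-breaking by smaller distance to
the probe midpoint, then lexicographic SNP id (exact $p$ ties arise from
LD-duplicated genotypes). A call requires:

* best-SNP nominal $p < 10^{-6}$ (suggestive) or $< 10^{-7}$
  (significant), and
* the **same SNP**'s $p > 0.05$ in the other parental regime.

Nominal rather than Bonferroni $p$ drives both thresholds, with the
per-probe Bonferroni value reported alongside; the actual per-probe
multiplier is always written out rather than assuming a genome-wide
constant. The other-parent screen is judged at the same SNP, not at the
other regime's own best SNP — the contrast that matters is *this* variant
acting through one parent. A probe may in principle be called in both
directions through different SNPs; both rows are emitted and flagged
rather than silently resolved. Heterozygote, conventional and LRT
$p$-values for the chosen SNP are attached as supporting evidence where
those tests ran.

The screen has a quantifiable sensitivity cost: at a genuine one-parent
locus the other-parent $p$ is uniform, so ~5% of true loci are vetoed by
chance. Per-locus sensitivity at the suggestive threshold is therefore
bounded by $0.95 \times$ power, and the probability that *every* locus in
a multi-locus experiment survives simultaneously decays geometrically
(e.g. $\approx 0.78^{20} \approx 0.7\%$ for twenty planted loci at the
package's default simulation conditions). The acceptance script reports
both the per-locus sensitivity and the all-loci coverage fraction so this
trade-off stays visible.

## The imprinting LRT

The full model $y = \beta_0 + \beta_M X_{MAT} + \beta_P X_{PAT} +
\varepsilon$ nests the reduced model $y = \beta_0' + \beta_B'
(X_{MAT}+X_{PAT}) + \varepsilon$ (set $\beta_M = \beta_P$). Under Gaussian
errors the maximum-likelihood ratio statistic is
$n \ln(RSS_{reduced}/RSS_{full})$, referred to $\chi^2_1$. The screening
design names the test but not the statistic's finite-sample form; the
Gaussian-ML form is the natural choice and an extra-sum-of-squares $F$
variant with $(1, n-3)$ df is available behind `method = "ftest"` for
sensitivity analysis — the two are monotone transforms of the same RSS
ratio and rank any dataset collection identically (property-tested).

LRT fits use exactly the children with assigned phasing at the SNP — the
same exclusion set as the parental regimes — so all five tests see
identical samples. Refusals are explicit: rank-deficient designs
(constant $x$, or $x_{MAT} = x_{PAT}$ as vectors) are
`not_identifiable`; $RSS_{full}$ below $10^{-12}\sum y^2$ is
`degenerate_perfect_fit`. Tiny negative statistics from floating-point
cancellation are clamped to zero.

Geometry matters when comparing tests. At a one-parent-only locus
($\beta_P = 0$) the fitted $|\beta_M| > |\beta_P|$ with $\beta_B'$
intermediate, and the split test is the more powerful screen. At a
reciprocal locus ($\beta_M = -\beta_P$) the diploid slope cancels to zero
— the conventional test is structurally blind — while the LRT and the
heterozygote comparison both fire, and their $-\log_{10} p$ values are
strongly positively correlated across loci. Both geometries are planted
by the simulator and asserted in the test suite.

## QC and stratification filters

Defaults in `filter_config()` follow the screening design: per-population
MAF ≥ 0.10 and call rate ≥ 0.90 (both boundaries inclusive — "below
threshold" is removed), computed over all trio members of each
population; probe mean log2 intensity ≥ 6 and sample SD ≥ 0.2 (n−1
denominator). Whether the intensity cut is on the mean or median is not
pinned down by the design; the mean is the default with `intensity_stat`
configurable.

When two populations are pooled, frequency and expression differences
between them can masquerade as associations. Two screens remove the raw
material: SNPs whose minor/major allele counts differ between populations
(two-sided Fisher's exact, $p < 0.05$) and probes whose expression
differs (two-sided pooled-variance Student $t$, $p < 0.05$). The Fisher
table uses **founders only** by default: counting children would count
every transmitted allele twice and overstate significance; this is a
documented deviation configurable back to all individuals
(`strat_founders_only = FALSE`). All screens are two-sided — the
thresholds are stated without sidedness, and two-sided is the
conservative reading. A zero-pooled-variance $t$ contrast with unequal
means is reported as infinite $t$ and $p = 0$ (deterministic removal),
never jittered.

Probes map to genes by ≥ 1 bp overlap in 1-based inclusive coordinates
(BED input converted on read); multi-gene probes keep every label and
calling emits one row per gene, while enrichment counts unique genes.

## The simulator

`simulate_trios()` draws founder genotypes under HWE at each SNP's MAF,
transmits one uniformly random allele per parent to the child, and
records the transmissions as ground truth before any corruption.
`simulate_expression()` builds
$y = \text{baseline} + \beta_M x_{MAT} + \beta_P x_{PAT} +
\mathcal N(0, \sigma^2)$ per probe. Defaults encode the study conditions
the method targets: 60 trios (the scale at which the approach is
worthwhile and its power limits show), log2 baseline 8, residual SD 0.5,
MAF either fixed or uniform on a post-filter common-variant range, effect
sizes around 1 log2 unit per allele — the "relatively large effect" regime
this sample size can detect. Units are laid out one SNP plus one probe
each, spaced 3 Mb apart (wider than twice the 1 Mb half-window) so each
probe pairs only with its own causal SNP and planted effects stay
independent.

RNG discipline: the genotype and expression stages use separate streams
derived from the master seed, and each probe's noise has its own
substream, so enlarging the probe set never perturbs genotype draws and
regression-test fixtures stay stable. (The design sketch suggested
per-(module, probe, SNP) splitting; module-level streams with per-probe
expression substreams achieve the stated stability goal with simpler
code.)

What the simulator deliberately does **not** emulate: linkage
disequilibrium between SNPs (the method handles LD only through best-SNP
reporting, so simulated loci are LD-free), probe-level microarray
artifacts, non-Gaussian expression noise, and cell-type heterogeneity.
Passing tests therefore demonstrate correctness of the statistical
machinery under the stated generative model, not robustness to everything
real arrays do; on real data the QC filters and the enrichment check
against known imprinted genes are the external validity anchors.

## Test and verification sizes

The suite verifies phasing exhaustively over all 27 trio configurations
against a brute-force transmission enumerator, and stochastically on
100 trios × 1,000 SNPs (truth recovery is exact at every assigned cell).
Regression, heterozygote and LRT engines are checked against closed-form
OLS/t-test/RSS oracles on ~1,000 random small datasets at $10^{-8}$
tolerance. Type-I calibration uses 1,000 null pairs at 60 trios for all
five tests (99% binomial band around 0.05). End-to-end recovery runs 50
replicates of 200-unit cohorts with 20 planted maternal effects
($\beta = 1$, $\sigma = 0.5$, MAF 0.3). Exact-test oracles sweep random
2×2 tables and hypergeometric parameter sets with universes ≤ 200. These
sizes give tight checks while keeping the whole suite around a minute.

## Known limitations

* Power is the binding constraint at the 60-trio scale: only effects of
  roughly one residual-SD per allele are reliably detectable at
  $p < 10^{-6}$, and the false-negative cost of the other-parent screen
  (~5% per locus) is irreducible without changing the rule.
* The other-parent screen's `p > 0.05` requirement is evidence of
  *absence of signal*, not absence of effect; weak biallelic eQTLs with
  unequal parental effects can be vetoed.
* Triple-heterozygous sites are unassignable by design; statistical or
  panel-based phasing could rescue them but is out of scope.
* No covariate adjustment: population structure is handled entirely by
  the stratification screens, which assume exactly two labeled
  populations (other counts skip the screen with a notice).
* The CLI wrapper exposes `simulate` and `run` (with per-stage YAML
  toggles); stage-by-stage command-line chaining was considered and
  dropped in favor of the exported R functions, which are the natural
  stage-level interface and are what the pipeline itself calls.
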