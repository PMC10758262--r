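---
title: "Cumulative linkage disequilibrium: model, estimators and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cumulative linkage disequilibrium: model, estimators and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cLD)
```

## The statistic

Standard linkage disequilibrium between two bi-allelic variants $A$ and $B$
is built from the minor allele frequencies $P_A$, $P_B$ and the joint
haplotype frequency $P_{AB}$:

$$D = P_{AB} - P_A P_B, \qquad
  r^2 = \frac{D^2}{P_A(1-P_A)\,P_B(1-P_B)}.$$

Because the margins sit in the denominator, $\hat r^2$ is badly behaved when
$P_A$ or $P_B$ approaches zero — which is exactly the situation for rare
variants (MAF below, say, 0.5%). The cumulative statistic sidesteps this by
borrowing the collapsing idea of burden tests: within a region (typically a
gene), a haplotype is a *carrier* if it holds at least one rare minor
allele. The carrier frequency is the cumulative MAF (cMAF), and cumulative
LD (cLD) is the same $D$, $D'$ and $r^2$ machinery applied to the carrier
frequencies $P_A$, $P_B$ and the joint carrier frequency $P_{AB}$. Since a
carrier indicator is a Bernoulli variable, cLD $r^2$ is identically the
squared Pearson correlation of the two indicator vectors — the package's
test suite uses that equivalence as an independent oracle throughout.

All frequencies are population moments (divide by the haplotype count $n$,
not $n-1$), matching the $1/n$ definitions of the statistic. When a margin
is 0 or 1 the statistic does not exist; every function in the package then
returns an explicit `defined = FALSE` flag with `NA` values rather than a
silent 0, and all averaging steps exclude (and count) undefined entries.
Emitting 0 instead would bias every bin mean downward.

The $D'$ normalization divides $D$ by its Fréchet bound given the margins:
$D_{\max} = \min\{P_A(1-P_B),\,P_B(1-P_A)\}$ for $D>0$ and
$\min\{P_A P_B,\,(1-P_A)(1-P_B)\}$ for $D<0$; $D'$ at $D = 0$ is defined
as 0.

A worked example with six haplotypes (two region-A carriers, three region-B
carriers, one double carrier) gives $P_A = 1/3$, $P_B = 1/2$,
$P_{AB} = 1/6$ — and therefore $D = 1/6 - 1/6 = 0$ exactly, so $r^2 = 0$:
with these margins the single double-carrier is precisely the independence
expectation. The package reproduces the frequencies and reports the zero.

## Choice of region and rare-variant cutoff

The rare-variant filter is a strict inequality `0 < MAF < maf_cutoff`
(default 0.005), recomputed on the loaded sample; monomorphic columns are
always dropped. Region choice trades off against the cMAF: regions so large
that the cMAF approaches 1, or so small that it stays near 0, both produce
degenerate statistics. A gene is the practical default unit. Positions are
converted to 0-based half-open intervals on load, and a variant belongs to
the region whose `[start, end)` interval contains it, so adjacent regions
partition boundary variants deterministically.

Missing alleles are counted as major (non-carrier) and tallied per variant.
This keeps the indicator well defined without imputation, at the cost of a
slight downward bias in cMAF when missingness is non-trivial — a documented
limitation, not a modelling claim. Multi-allelic records are expanded into
one binary column per alternate allele, and every column is re-oriented so
the stored allele is the minor allele in the loaded sample (ties at 0.5
keep the ALT allele).

## Asymptotic variance

The four carrier combinations (both, A-only, B-only, neither) of a region
pair follow a multinomial law with cell probabilities
$(p_{11}, p_{10}, p_{01}, p_{00})$. Writing the statistic as a function
$g$ of the three free cells (the simplex covariance is singular in four
coordinates, so $p_{00}$ is eliminated; any full-rank parameterization
yields the same value), the delta method gives

$$\operatorname{Var}(\hat r^2) \approx
  \frac{\nabla g^{\mathsf T}\,(\operatorname{diag}(p) - p p^{\mathsf T})\,
        \nabla g}{n},$$

with the gradient computed analytically (`delta_variance()`). The identical
formula serves standard LD — only the input table changes from the carrier
table to the two-variant haplotype table — which is why the package exposes
one variance function fed by two table constructors.

Two caveats are inherent to the first-order expansion. At $D = 0$ the
gradient of the squared statistic vanishes and the first-order variance is
exactly zero; `delta_variance()` warns that the approximation degenerates
there, and the verification grids avoid $D = 0$. Second, the variance of
$\hat r^2$ depends on the value of $r^2$ itself. Comparisons between the
region-level and variant-level estimator are therefore made at matched
$r^2$: a carrier table with cMAF-scale margins against a variant table with
rare-MAF margins and the same $r^2$. On such matched tables the ratio
$\operatorname{Var}(\text{cLD})/\operatorname{Var}(\text{LD})$ is far below
one (about 0.03 for cMAFs 0.2/0.3 versus MAFs 0.002/0.003 at $r^2 = 0.01$,
and smaller as the MAFs shrink), which is the closed-form content of the
stability claim. The test suite verifies the closed form against the
Monte-Carlo variance of $\hat r^2$ over 20,000 multinomial draws at
$n = 2000$ on a 20-table grid (15% relative tolerance) and the analytic
gradient against central finite differences (relative $10^{-4}$).

For case/control screening, the variance of
$\Delta\text{cLD} = \text{cLD}_{\text{case}} - \text{cLD}_{\text{control}}$
under cohort independence is the sum of the cohort variances
(`delta_cld_variance()`); folding for the absolute value is left to the
caller, since the screening statistic is $|\Delta|$ and its null is
half-normal.

## Bootstrap stability protocol

`bootstrap_stability()` implements the half-sample protocol: in each
iteration exactly `floor(n/2)` haplotypes are drawn *without* replacement;
over the sampled gene pairs (same-chromosome pairs among `n_genes` sampled
regions) the bin-averaged cLD and the bin-averaged gene-pair LD are
recorded; finally each (bin, statistic) series is divided by its own mean,
so the standard deviation reads as a coefficient of variation. Design
choices that the protocol description leaves open, resolved here once:

* **Pair-level cMAF summary for binning** — mean of the two cMAFs
  (configurable `min`/`max`). Bins are half-open with the default edges
  0.05 / 0.10 / 0.20 / 0.40; pairs at or above the last edge are discarded
  and counted.
* **Bin assignment** — computed from the full-sample cMAFs and held fixed
  across iterations; bins are treated as population properties, not
  resampled quantities.
* **Normalization divisor** — the mean over iterations within each
  (bin, statistic) series. A population-wide divisor is an alternative
  reading of the protocol; it rescales all bins by a common factor and was
  not adopted.
* **Gene-pair LD** — the mean r² over cross-region rare variant pairs, all
  pairs when there are at most `max_pairs` (default 2000), otherwise that
  many sampled without replacement. Undefined pairs (a variant monomorphic
  in the subsample) are excluded from the mean and counted.
* Bins empty in at least 10% of iterations are flagged `unstable` rather
  than erroring.

### What the synthetic generator does and does not emulate

`make_fixture()` draws per-variant MAF targets uniformly from
`[maf_low, maf_high]`, derives the implied cMAF
$q = 1 - \prod_s (1 - m_s)$, draws the carrier indicator first (jointly
across designated region pairs via the 2×2 table matching a target
correlation $\rho$, with Fréchet-infeasible requests rejected), and then
gives each carrier at least one rare allele, including variant $s$ with its
conditional probability $m_s/q$. This reproduces the features the
estimators care about — a rare MAF spectrum, tens of variants per region,
controllable carrier correlation — and calibrates well: the empirical cMAF
matches its target within binomial error and $\sqrt{\text{cLD}}$ matches
$\rho$ for planted pairs.

It does **not** reproduce the haplotype structure of real populations:
variants are assigned (conditionally) independently among carriers, so
there is no identity-by-descent sharing, no LD blocks spanning regions, and
cross-region variant pairs in strong LD are much rarer than in sequencing
data. This matters for one result. On real data the bootstrapped LD
distributions are far wider than the cLD ones in every cMAF bin; under this
generator the gene-pair LD side — a mean over thousands of conditionally
independent variant-pair r² values — is *more* heavily averaged than the
single carrier-table r², and at desk scale the ordering can invert in the
higher cMAF bins. The package demonstrates the stability ordering where the
aggregation genuinely dominates the averaging (compact regions of about ten
very rare variants, lowest cMAF bin), and the closed-form variance ratio
carries the general claim. Passing tests here show the estimators and the
protocol are implemented correctly; they do not show that this generator
reproduces 1000-Genomes-scale instability, and it does not.

At 200 haplotypes a strict per-variant MAF below 0.005 admits no
polymorphic site (one copy is exactly 0.005), so fixtures at that scale are
generated from a sub-0.005 *target* spectrum and analyzed without
re-filtering; rare-filter semantics are tested at sample sizes where the
constraint is realizable.

## Enrichment comparisons

Gene pairs are stratified into 13 geometric distance groups (upper edges
35 kb × 2^k, k = 0..12, topping out just under the longest human
chromosome) by midpoint-to-midpoint distance (gap distance is a documented
alternative; midpoints are the default because region sizes vary less than
their separations at these scales). A pair is `in_interaction` when both
regions overlap an annotation interval by at least 1 bp, `discarded` when
exactly one does — discarded pairs never enter any count.

Within each stratum the 2×2 table of label × (statistic above the stratum
median) feeds the Mantel–Haenszel test (continuity correction on by
default, for the sparse long-distance strata; the single-stratum case uses
the identical closed form directly) and the Fisher exact test. The
per-stratum median is the default cutoff, recomputed within each distance
bin; a pooled median is available by flag. Strata lacking either label are
dropped with a note. Because the protocol is ambiguous about whether the
Fisher test applies per stratum or to pooled counts, both are emitted.

The cutoff-ratio curve reports, for each cLD cutoff, the ratio of labelled
to unlabelled pairs above the cutoff, both raw and normalized by class
size; the normalized form is the one comparable across unbalanced classes,
and the raw form matches count-based reporting. A zero denominator with a
positive numerator is reported as `Inf`, not dropped.

The distance-matched variant-pair comparison samples up to 2000 cross-region
rare variant pairs per labelled gene pair and matches each to the unlabelled
pool's nearest distance (ties toward the smaller distance), with matching
done with replacement over the pool.

## Case/control screening

`delta_cld()` computes cLD per cohort and ranks pairs by
$|\Delta\text{cLD}|$ descending, ties broken lexicographically by region
names so the ranking is reproducible. Rare-variant status is determined on
the pooled cohorts by default so both cohorts use the identical variant
set; per-cohort filtering is available but makes the two cLD values
measure different variant sets. No significance threshold is applied — the
ranking is a screen, and the delta-method variance can annotate records
with an exploratory z-like score only.

## Forward-time decay simulator

`simulate_decay()` models two regions on a haplotype with per-generation
events in the order selection → recombination → mutation, with growth
realized jointly with selection by sampling `round(N * growth_rate)`
offspring in proportion to fitness

$$w = (1+s_{\text{neg}})^{m_A + m_B}\,(1+s_{\text{syn}})^{\,c_A c_B},$$

where $m_A, m_B$ count regional mutations, $c_A c_B$ is the double-carrier
flag, and the synergy term applies only when `interaction_on`. Growth plus
negative selection are the two forces that keep variants rare; the synergy
term is the genetic interaction whose footprint cLD is meant to capture.
Recombination exchanges the region-B segment with an independently drawn
parent with probability `rec` per offspring. New mutations arrive as
Poisson(`mu`) fresh columns per region on random haplotypes; extinct
columns are pruned. Defaults — founders $n_0 = 500$, growth 1.02 per
generation, $\mu = 0.5$ per region per generation, $s_{\text{neg}} = -0.01$,
$s_{\text{syn}} = 0.05$, `rec = 0.02`, 50 generations, founder carrier
frequencies 0.2 with correlation 0.9 seeded over 5 variants per region —
were chosen once as a biologically plausible regime in which decay is
visible within 50 generations; the claims tested are orderings (decay under
recombination, conservation under pure drift, slower decay with interaction
across seed-matched replicate pairs), never curve shapes.

The switching-error model walks each individual's heterozygous positions in
genomic order and toggles a swap state with the given probability per het
site (switches at homozygous sites are undetectable); while the state is
on, the two haplotypes' alleles are exchanged, producing the contiguous
mis-phased segments characteristic of statistical phasing. The toggled site
itself is included in the exchanged segment. Re-phasing never changes an
individual's per-site allele multiset, and swapping a whole individual
leaves every cLD exactly unchanged (the indicator multiset is preserved) —
both are asserted in the tests. The robustness experiment reports the mean
proportion of cLD change over pairs with true cLD at least `min_r2`
(default 0.05): a relative change against a near-zero baseline is noise
divided by noise, and including such pairs would swamp the average.

## Numerical and testing notes

* All stochastic functions take explicit seeds and restore the caller's
  RNG state; identical seeds give bit-identical results.
* Pairwise computations use one cross-product per iteration and per-pair
  blocks rather than materializing full variant-by-variant matrices.
* Test problem sizes are chosen to exercise each claim at the smallest
  scale where the signal is unambiguous: the Monte-Carlo variance grid uses
  $n = 2000$ with 20,000 draws; the bootstrap demonstrations use 100–200
  iterations on 20–40 regions; simulator orderings use 50 seed-matched
  replicate pairs; the planted case/control recovery uses 20 cohorts of
  1000 haplotypes per arm.
* Fisher exact p-values are validated against full enumeration over the
  hypergeometric support for every 2×2 table with total at most 20, and
  both stratified tests are checked for calibration under label
  permutation.
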