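# cLD — cumulative linkage disequilibrium between genomic regions

Linkage disequilibrium (LD) measured as r² is unreliable for rare variants:
the allele frequencies in its denominator approach zero and the estimator's
variance explodes, which is why LD analyses conventionally drop everything
below a few percent minor allele frequency. **cLD** works at the level of
*regions* instead of variants. Within each region (typically a gene), the
rare variants (MAF < 0.5% by default) are collapsed into a per-haplotype
carrier indicator — the burden-test idea behind the cumulative minor allele
frequency (cMAF) — and the classical disequilibrium statistics are applied
to the carrier frequencies:

    P_A  = fraction of haplotypes carrying >= 1 rare variant in region A
    P_B  = likewise for region B
    P_AB = fraction carrying >= 1 rare variant in both
    D    = P_AB - P_A * P_B
    r²   = D² / (P_A (1 - P_A) P_B (1 - P_B))

Because the cMAFs are far from zero even when every contributing variant is
rare, the region-level estimator is dramatically more stable than variant-level
rare-variant LD, and it picks up co-segregation driven by biological
interaction between regions, not only local lack of recombination.

The package is aimed at population geneticists working with phased haplotype
panels (e.g. 1000 Genomes-style VCFs) who want region-level rare-variant
association structure: scanning gene pairs, comparing labelled versus
unlabelled pairs (chromatin-contact or database-interaction annotations)
across distance strata, or screening case/control cohorts for pairs whose
cLD differs (ΔcLD).

## What's inside

* **I/O** — `load_haplotypes()` (phased VCF → binary haplotype matrix, minor
  allele oriented, multi-allelics expanded), `load_regions()` (BED4),
  `filter_rare()`, `write_haplotypes()`.
* **Statistics** — `carrier_profile()`, `cld()`, `ld()`, `gene_pair_ld()`
  (averaged variant-pair LD with a 2000-pair sampling cap), `pairwise_cld()`,
  `rare_common_cld()`.
* **Asymptotics** — `delta_variance()`: closed-form delta-method variance of
  r̂² under a multinomial haplotype-table model (one formula for LD and cLD;
  only the table differs), `variance_ratio()`, `delta_cld_variance()`.
* **Resampling** — `bootstrap_stability()`: the half-sample protocol
  comparing mean-normalized cLD and LD spread in cMAF bins, plus
  `stability_summary()`.
* **Enrichment** — geometric distance groups (35 kb doubling, 13 bins),
  `label_pairs()`, per-stratum median cutoffs, `mantel_haenszel()`,
  `fisher_exact()`, `cutoff_ratio_curve()`, `hypergeom_enrichment()`.
* **Case/control** — `delta_cld()` ranking, `top_pairs()`.
* **Simulation** — `simulate_decay()` (forward-time Wright–Fisher with
  growth, negative selection, epistatic synergy and recombination),
  `inject_switch_errors()` / `switch_error_experiment()` (phasing
  robustness), `make_fixture()` (synthetic phased rare-variant data with
  tunable between-region carrier correlation).

A thin command-line wrapper ships in `inst/cli/cld`
(`cld compute | variance | bootstrap | enrich | delta | simulate | fixture`);
every subcommand echoes its resolved configuration and seed as `#key=value`
header lines in its TSV output.

## Worked example

Six haplotypes, two regions. Haplotypes 1 and 4 carry a rare variant in
region A; haplotypes 3, 4 and 5 carry one in region B:

```r
library(cLD)
h       <- load_haplotypes("toy.vcf")      # 6 haplotypes, 3 variants
regions <- load_regions("toy.bed")         # regions A and B
a <- carrier_profile(h, regions[1, ])
b <- carrier_profile(h, regions[2, ])
cld(a, b)
#> cLD A ~ B (n = 6 haplotypes)
#>   p_a = 0.3333  p_b = 0.5  p_ab = 0.1667
#>   D = 0  D' = 0  r2 = 0
```

P(A) = 2/6 ≈ 0.33, P(B) = 3/6 = 0.50, and one haplotype carries both, so
P(AB) = 1/6 ≈ 0.17. With these margins the single double-carrier equals the
independence expectation 1/3 × 1/2 = 1/6, so D — and with it r² — is
exactly zero: the two regions show no cumulative disequilibrium.

The closed-form asymptotic variance at a given carrier table:

```r
delta_variance(cell_probs(0.3, 0.2, 0.1, 0.4), n = 500)
#> r2 = 0.166667, asymptotic Var = 0.00108333 at n = 500
```

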