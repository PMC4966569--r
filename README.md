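# niebtools

Analysis pipeline for **nucleosome-inhibiting energy barriers (NIEBs)**
— AT-rich, sequence-intrinsic regions that resist nucleosome formation —
and for the question whether the chromatin pattern they anchor (a
nucleosome-depleted region flanked by a few well-positioned nucleosomes)
is under selection.

It is written for genomicists who have a barrier catalog (BED), MNase-seq
dyad tags, a four-species primate alignment and a SNP table, and want
the full chain of analyses:

- **Spacing**: border-to-border interdistances, their Poisson-like
  exponential tail, the quantized small-spacing comb `d = 117 + 153k` bp,
  and crystal-like classes of inter-barrier regions holding `n = 1..5`
  nucleosomes (`d > 800` bp: fuzzy).
- **Profiles**: any per-base statistic averaged at 1-bp resolution
  against signed distance to the nearest barrier border (negative =
  inside), with count-weighted smoothing, reverse-complement
  symmetrization, and heat maps over size-ordered inter-barrier regions.
- **Occupancy Z-test** per barrier, interior vs the two 300-bp flanks
  over mappable sites:

  `z = (m2 − m1) / sqrt(s1²/n1 + s2²/n2)`

  with G1 (depleted, `z > 1.645`), G2 (enriched), G3 (neither), and
  exclusion at ≤30 usable sites.
- **Divergence and selection**: isolated human-lineage substitutions
  (three-outgroup ancestral base, flank-identity filter, CpG masking),
  intraspecies changes from SNPs above a 1 % MAF, per-offset rates
  `dInter = InterDiff / ancestralBase` (Eq. form used throughout), a
  background from the central ±300 bp of large inter-barrier regions,
  and the McDonald–Kreitman-style ratio

  `S = (dInter / bgInter) / (dIntra / bgIntra)`

  per base change and 10-bp window, with a bootstrap neutral null (one
  random 10-bp window per large region, 10,000 repetitions, 95 %
  limits), context-dependent rates (tTt→tAt, sTs→sAs, ...), and the
  equilibrium GC content implied by the substitution matrix.
- **A synthetic-data generator** reproducing the statistical structure
  of all inputs (Poisson-placed AT-rich barriers with poly(dA:dT)
  edges, statistically positioned dyads, neutral or selected
  substitution processes with CpG hypermutability, patchy mappability)
  with full ground truth, so every stage is testable end to end.

## Worked example

```r
library(niebtools)

# a 1.2-Mb synthetic world with known truth
ds <- simulate_dataset(synth_truth(), n_chrom = 4, chrom_length = 3e5,
                       seed = 7)
clen <- chrom_lengths(ds$genome)

# spacing: the exponential tail recovers the placement mean
fit <- fit_exponential_tail(interdistances(ds$catalog, ds$genome), 0)
round(c(mean = fit$mean, se = fit$se))
#> mean   se
#> 1508   56        # truth: 1541 bp

# occupancy: barriers are seen as depleted
z <- ztest_classify(ztest_inputs(ds$catalog, ds$tags, ds$mappability, clen))
round(group_summary(z)$fractions, 3)
#>    G1    G2    G3
#> 0.990 0.007 0.003   # 0.15x interior depletion, deep coverage

# selection ratio on neutral divergence: pooled distal S ~ 1
tab <- divergence_tables(ds$aln, ds$catalog, clen, ds$variants)
bg <- background_rates(tab)
rp_i <- rate_profile(tab, "inter"); rp_p <- rate_profile(tab, "intra")
pooled <- function(rp) {
  far <- rp$offset > 300
  sum(rp$events[far]) / sum(rp$eligible[far])
}
s_far <- (pooled(rp_i) / (sum(bg$events_inter) / sum(bg$eligible))) /
         (pooled(rp_p) / (sum(bg$events_intra) / sum(bg$eligible)))
round(s_far, 2)
#> [1] 1.03           # neutral: no selection signal
```

`G1 = 0.99` says 99 % of testable barriers are significantly depleted in
dyad tags relative to their flanks; the pooled distal `S = 1.03` says the
background-corrected interspecies/intraspecies ratio shows no selection
on neutral data — injected selection multipliers are recovered by the
same machinery (see `tests/testthat/test-acceptance.R`).

The `analysis/` directory holds the narrative workflow
(`01_simulate.R` … `05_selection.R`); run them from the repository root
with `Rscript analysis/01_simulate.R` etc.; they print their findings
and write tables under `results/`.

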