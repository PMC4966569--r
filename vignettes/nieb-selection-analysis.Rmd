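---
title: "Barrier-anchored nucleosome ordering and selection on divergence rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Barrier-anchored nucleosome ordering and selection on divergence rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis

`niebtools` implements an analysis pipeline around *nucleosome-inhibiting
energy barriers* (NIEBs): AT-rich, sequence-intrinsic regions that resist
nucleosome formation. Against a catalog of such barriers it computes

1. **spacing statistics** — border-to-border interdistances, their
   exponential (Poisson-like) tail, the quantized small-spacing comb
   `d = 117 + 153k` bp, and the assignment of each inter-barrier region to
   a crystal-like class holding `n = 1..5` nucleosomes (regions above
   800 bp are "fuzzy": only their first flanking nucleosomes stay
   positioned);
2. **border-aligned profiles** — any per-base statistic (MNase dyad
   density, GC, homopolymer coverage, substitution indicators) averaged at
   1-bp resolution against signed distance to the nearest barrier border
   (negative inside), plus heat maps over size-ordered inter-barrier
   regions;
3. **a per-barrier occupancy Z-test** — each barrier's interior tag
   density against its two 300-bp flanks over mappable sites,
   `z = (m2 - m1) / sqrt(s1^2/n1 + s2^2/n2)`, classifying barriers as
   significantly depleted (G1, `z > 1.645`), enriched (G2) or neither
   (G3), with barriers of 30 or fewer usable sites on either side
   excluded;
4. **divergence and selection** — position-resolved interspecies
   (human-lineage, three-outgroup) and intraspecies (SNP) rates per base
   change, `dInter = InterDiff / ancestralBase` and likewise `dIntra`;
   backgrounds taken from the central ±300 bp of large (>800 bp)
   inter-barrier regions; the McDonald–Kreitman-style ratio
   `S = (dInter/bgInter) / (dIntra/bgIntra)` per change and 10-bp offset
   window, with a bootstrap neutral null (one random 10-bp window per
   large region, 10,000 repetitions, 2.5/97.5-percentile limits);
   context-dependent variants of the same rates (tTt→tAt, sTs→sAs, ...);
   and the equilibrium GC content implied by the per-offset substitution
   matrix.

Every coordinate in the package is 0-based half-open (BED-native);
1-based formats are converted at the reader boundary.

# Filtering rules

*Isolated substitutions.* A site has a defined ancestral base when
chimpanzee, orangutan and macaque agree on a real base; it is eligible
when additionally both immediate neighbors are identical across all four
species and the human base is real. Multiple substitutions are ignored by
design — with two outgroups and small primate divergences they are rare,
and the flank-identity filter removes most alignment artifacts.

*CpG masking.* A position is a CpG "C" when its dinucleotide across
human/chimp/orangutan/macaque matches NG/CG/CG/CG, CG/NG/CG/CG,
CN/CG/CG/CG or CG/CN/CG/CG; the next position is the paired "G". Flagged
sites are excluded from the eligible counts of all C-ancestral rates, and
(because every profile is reverse-complement symmetrized) symmetrically
from G-ancestral rates; `cpg_strand_symmetric = FALSE` disables the G
side. Equilibrium-GC matrices use the CpG-*inclusive* rates: the
composition a sequence evolves toward includes deamination flux.

*Intraspecies changes.* Only alleles above a 1 % frequency qualify; the
ancestral allele must be among the observed qualifying alleles (falling
back to the chimpanzee base where the interspecies ancestral base is
undefined); each other qualifying allele contributes one change. The
eligible-site denominator is the same ancestral-base count as for
interspecies rates, so the denominators cancel inside S.

*Undefined values.* `0/0` rates, ratios against a zero background, and S
with zero intraspecies events are `NA`, never 0 or infinity, and `NA`
offsets are dropped from confidence-interval comparisons.

# Conventions chosen where the procedure was open

- **Interior offsets** are measured to the nearer border, ties to the 5'
  border; flank sites take the nearer of the two surrounding borders
  (exterior ties to the 3' border of the preceding barrier). A flank site
  interior to the next barrier is interior there, which prevents double
  counting between close barriers.
- **Reverse-complement symmetrization**: the profile of change X→Y pools
  sites measured from 3' borders with the complementary change on 5'
  sides; backgrounds stay per-change (central regions carry no side).
- **Standard deviations** in the Z-test use the population form
  (denominator `n`); above the 30-site requirement the difference from
  `n-1` is negligible.
- **Bootstrap windows** are drawn uniformly from the non-overlapping
  10-bp tiling of each central span (60 windows per region). The tiling
  matches the "independent non-overlapping windows" framing under which
  p-values need no multiple-test correction, and makes the 10,000-rep
  bootstrap a precomputed gather-and-sum.
- **Exceedance estimation**: S is semi-discrete at desk scale (small
  Poisson counts), so the probability mass sitting exactly on a
  percentile limit is not negligible. When estimating the per-side
  exceedance probability of the 95 % limits, ties with the limit are
  mid-counted (half weight) — the standard unbiased convention for
  discrete test statistics; strict counting would bias the estimate low.
- **Smoothing** is a centered count-weighted moving average; even windows
  put the extra position on the right; windows shrink at the axis ends.
- **Crystal classes** are assigned by the nearest comb tooth
  `d = 117 + 153(n-1)` clipped to `[1, 5]` for `d ≤ 800` bp. The comb
  detector scores offset/period combs on a lightly smoothed 1-bp
  histogram and then refines the best comb on the raw histogram; a comb
  must stand six grid standard deviations above the mean score, so
  exponential spacing yields a null result.
- **The 270-bp flank span** in coverage accounting is the unique value
  consistent with the reference catalog's printed flanking-nucleosome
  coverage (945,219 large regions × 540 bp = 510,418,260 bp); it is a
  configurable default.
- **Unsequenced inter-barrier regions** are those containing an N run of
  at least 100 bp (configurable); they are dropped from spacing
  statistics.

# The synthetic generator

The generator (`synth_truth()`, `simulate_dataset()`) emulates the
statistical structure the analysis assumes, not any particular genome:

- **Barrier placement**: exponential border-to-border gaps, mean 1541 bp;
  widths `36 + Gamma(2.2, 53)` clipped to 450 bp (mean ≈153 bp).
- **Composition**: barrier GC 26.5 % (the interior draw is raised to
  compensate the GC-free poly(dA:dT) edges, 5–12 bp per side), bulk GC
  37.9 %, flank GC decaying from the border with length 400 bp and
  calibrated so the 300-bp flank mean is 42.5 %, with a 5-percentage-point
  oscillation at the 153-bp repeat length peaking at +74 bp.
- **Dyads**: boundary-anchored statistical positioning — 147-bp
  footprints grow from each border with geometric linkers (mean 6 bp),
  filled from both ends toward the middle where accumulated linker
  variance destroys order. This renewal construction reproduces the
  damped density oscillation that an equilibrium hard-rod (Tonks) gas
  shows against a wall, at a fraction of a grand-canonical Monte Carlo's
  cost; regions narrower than one footprint stay empty, so the crystal
  class `n = 1` (d ≈ 117 bp < 147 bp) is not populated — a deliberate
  simplification (real nucleosomes partially unwrap). Each dyad emits
  Poisson tags (jitter sd 10 bp); barrier interiors emit residual tags at
  0.15× the genome rate; a `"uniform"` mode provides the iid null.
- **Divergence**: the generated sequence is ancestral; three outgroups
  get 0.2 %/site independent noise (keeping >97 % of sites
  flank-eligible); the human lineage mutates at transition 3×10⁻³ /
  transversion 1×10⁻³ per site (≈0.5 % total, the autosome-wide scale),
  ×8 on CpG deamination channels, × any configured selection multiplier.
  SNPs arise the same way with Beta(0.05, 2) derived-allele frequencies,
  leaving ≈17 % above the 1 % MAF filter; qualifying SNP intensity is
  0.44× the interspecies intensity (emulating ≈0.22 % qualifying SNP
  density against 0.5 % divergence).
- **Tracks**: unmappable patches (rate 10⁻⁴/bp, mean 250 bp → ≈2.5 %
  unmappable), repeat mask (≈30 %), rare N gaps.

What the generator does *not* emulate: real repeat families and their
insertion biases, neighbor-dependent substitution beyond CpG,
coalescent-accurate allele frequencies, biased gene conversion, genes and
expression (TSS-anchored profiling is exercised on constructed tracks
instead). Passing tests therefore demonstrate that the *pipeline*
measures what it claims on data with the assumed structure — not that any
particular biological conclusion transfers to a real genome.

# Problem sizes and calibration checks

The test suite runs three scales, chosen as the smallest sizes at which
each check is statistically decisive:

- **Z-test calibration**: the 1.645 threshold is checked analytically and
  with 10⁵ simulated barriers of iid per-site values in the CLT regime
  (Gaussian), where the exceedance must sit within three binomial
  standard errors of 5 %. With low-intensity Poisson tags the same test
  shows a small genuine skewness excess in P(G1) (≈6 % at 0.3 tags/bp);
  a separate property test documents that behavior with an honest
  tolerance rather than hiding it.
- **Bootstrap exceedance**: a 6-Mb neutral genome (20 × 300 kb) gives
  >2,000 large inter-barrier regions; after a 10,000-rep null, 4,000
  fresh draws per change estimate the per-side exceedance, expected at
  0.025.
- **Selection recovery**: a 40-Mb genome (20 × 2 Mb) with a 1.5×
  interspecies S→W multiplier inside barriers. A power calculation sets
  this scale: the null upper limit for the pooled S→W ratio scales like
  `1 + 3/sqrt(events per bootstrap realization)` and falls to ≈1.33 at
  ≈14,000 large regions, while the pooled barrier-interior estimate is
  1.5 ± 0.05 — both sides of the detection contract then hold with wide
  margin. Per-change 10-bp-window detection of a 1.5× effect is *not*
  attainable at desk scale (the reference analysis had 600× more
  sequence); the pooled S→W class over barrier-interior offsets is the
  faithful desk-scale statistic.

# Known limitations

- The exponential-tail fit assumes memorylessness; it reports the MLE
  `mean(d - d_min)` and its standard error, nothing more.
- `equilibrium_gc_profile()` needs all 12 per-window rates defined;
  sparse offsets yield `NA`, and at neutral generator settings the
  equilibrium GC is *below* the generated GC (CpG flux is S→W biased and
  nothing restores GC) — on real data the gap between current and
  equilibrium GC is the signal, on neutral synthetic data it is expected.
- The dyad simulator produces no nucleosomes in sub-147-bp regions and
  no remodeling; G1 fractions on positioned synthetic data are therefore
  higher than any in vivo dataset would give.
- `run_pipeline()` is deterministic per configuration (stage seeds are
  derived from the master seed), but artifacts are not byte-stable across
  R versions (numeric formatting in TSV output).
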