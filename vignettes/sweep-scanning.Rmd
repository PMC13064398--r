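---
title: "Dosage-based selective sweep scanning: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dosage-based selective sweep scanning: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`polysweep` detects selection signatures in autopolyploid SNP panels
scored as unphased allele dosages. This vignette is the package's own
account of the statistical machinery: what is assumed, which knobs
matter, what the synthetic generator does and does not emulate, and where
the method's limits are.

## The diversity model

A biallelic locus in a tetraploid carries a dosage genotype in
{0, 1, 2, 3, 4}. Three per-locus statistics summarize diversity:

* **Observed heterozygosity** `Ho = N_het / N_total`, where the
  heterozygote set is the non-homozygous dosage classes
  `1..ploidy-1`. `Ho` is purely empirical — no equilibrium assumption.
* **Expected heterozygosity** `He = 1 − (p² + q²) = 2pq`, with `p`
  estimated as mean dosage divided by ploidy. This is the
  random-pairing expectation for a single allele draw pair; it assumes
  dosage calls are unbiased estimates of allele counts.
* **Nucleotide diversity** `π = n/(n−1) · 2p(1−p)`, the unbiased
  per-site estimator, with `n` the non-missing genotype count. The
  identity `π = He · n/(n−1)` holds exactly and is used as an internal
  cross-check (asserted to 1e−12 in the tests).

Missing dosages are excluded from every count — crucially, a missing
call is never treated as dosage 0. A locus with fewer than two
genotypes has undefined `π`; an all-missing locus propagates `NA`
through window means rather than erroring.

Between two groups A and B, the comparative statistics are
`π ratio = π_A/π_B`, `ΔHo = Ho_A − Ho_B`, `ΔHe = He_A − He_B`, and
`FST = (H_T − H_S)/H_T` with `H_T = 2p̄(1−p̄)`. Two conventions were
genuinely open and are resolved as follows:

* `p̄` and `H_S` are **unweighted** two-group means by default (a
  sample-size-weighted variant sits behind `weighted_hs = TRUE`). With
  both unweighted, `H_T − H_S = (p_A − p_B)²/2 ≥ 0` algebraically, so
  `FST ∈ [0, 1]` whenever `H_T > 0`.
* Undefined values — `FST` at loci monomorphic across both groups,
  `π ratio` where `π_B = 0` — are stored as missing and excluded from
  window means and quantiles. Imputing 0 (or clamping ratios) would
  fabricate extreme windows precisely where the data say least.
* Both `ΔHo` and `ΔHe` are computed; `ΔHo` drives the comparative
  caller. Where a heterozygosity difference is meant as a selection
  signal, the observed rate is the quantity that does not lean on the
  allele-frequency model, and it is the one plotted group-wise.

## Windows and deviation tracks

Two window schemes are built per chromosome: a fixed count of 100
consecutive SNPs stepped by 10 (robust to density fluctuations), and a
fixed 1 Mb width stepped by 500 kb (comparable across density). The
physical scheme drops windows with fewer than `min_loci = 10` SNPs —
sparse windows produce wild means that the bands would otherwise have to
absorb. The SNP scheme emits complete windows only; trailing partial
windows are dropped so per-window variance stays comparable, which the
rank bands implicitly assume.

A track records each window's mean of a per-locus metric and its
**deviation from the genome-wide mean**. The genome mean is taken over
all retained loci, not over windows, so heavily overlapping windows do
not multiply-count loci in the baseline. Window position for all region
arithmetic is the midpoint `mid_bp`; the ±1 Mb extension around a
selected minimum needs a point anchor.

## Bootstrap and simultaneous rank bands

Sampling uncertainty is at the accession level: the panel is one draw of
accessions from a germplasm pool. The bootstrap therefore resamples
whole accessions (rows) with replacement — resampling loci would destroy
the linkage disequilibrium between neighboring loci that windowed
statistics depend on. Every replicate recomputes the locus metrics, the
window means, the genome-wide mean and the deviations; each replicate is
recentered by **its own** genome mean (the alternative, recentering by
the point-estimate mean, is available via `center = "point"`). The
recomputed-mean default mirrors what the point estimate itself does and
makes the band a statement about the deviation statistic as actually
computed.

Adjacent windows share up to 90% of their loci, deviations are means of
discrete-valued statistics at modest n, and a chromosome holds dozens to
hundreds of windows — so pointwise intervals would be both
distributionally doubtful and massively multiplicity-inflated. The band
construction is rank-based and joint: per window, order the B bootstrap
deviations `t(1) ≤ … ≤ t(B)`; the band at symmetric depth k is
`[t(k), t(B+1−k)]`; choose the largest k such that the fraction of
bootstrap replicates lying inside the band at *every* window of the
chromosome simultaneously is at least 1 − α. Properties worth noting:

* With a single window, B = 1000 and α = 0.05 the construction selects
  k = 26 with joint coverage exactly (B − 2k + 2)/B = 0.95.
* More (or less dependent) windows force smaller k, i.e. wider bands;
  with 50 independent windows even k = 1 can be the selected depth —
  real tracks are strongly autocorrelated, which is exactly what the
  joint selection exploits.
* Ties are resolved with closed comparisons (≤ / ≥), which can only
  raise coverage; degenerate (all-identical) bootstrap matrices give a
  zero-width band with coverage 1 at the maximal depth ⌊(B+1)/2⌋.
* If even k = 1 cannot reach 1 − α, the band warns that B is too small
  (B ≥ ⌈2/α⌉ is enforced as a precondition).

Bands are computed per chromosome and per metric; a genome-wide joint
band is deliberately out of scope.

## The two callers

**Within-group.** Per chromosome and metric, only negative deviations
are eligible. Candidate centers are local minima of the deviation
profile within ±2 windows, using an asymmetric tie rule (strictly
smaller than finite left neighbors, no greater than finite right
neighbors) so that exactly the leftmost entry of a tied run qualifies
and a constant profile yields a single candidate. A candidate is kept
when its deviation is at or below the 5% quantile of **all** negative
deviations of that chromosome and metric — the literal empirical
distribution, not just the minima. Kept minima become ±1 Mb regions,
clipped to the chromosome, merged when overlapping, and a consensus
region must be supported by at least 2 of {Ho, He, π} ("multiple
metrics" is read as ≥2; `min_metrics` is configurable). The
simultaneous band enters as annotation: `band_significant` records
whether the band's upper limit at the minimum is below zero. A strict
mode (`require_band = TRUE`) turns that into a filter; it is off by
default because the operative selection rule is the quantile, with the
band as the uncertainty statement.

**Comparative.** FST contributes its upper tail; ΔHo and π ratio both
tails. Tail thresholds use the 1% quantile of the metric's
**genome-wide** window distribution; local extrema (±1 window, same tie
rule mirrored for maxima) are detected per chromosome. This tail-scope
split is a deliberate design choice: a per-chromosome 1% tail flags each
chromosome's own most extreme windows *by construction*, every
chromosome, every metric — measured on null simulations it produces
several-fold more false clusters than the genome-wide scope
(`tail_scope = "chromosome"` remains available). A quantile threshold
that fails to separate from the distribution's bulk (possible for flat
or heavily tied tracks, e.g. π ratio of two identical groups) flags
nothing. Extrema of different metrics whose windows are adjacent (index
distance ≤ 1) or physically overlapping chain into clusters; a cluster
with ≥2 distinct metrics becomes a ±1 Mb region around the cluster
center, taken as the mean of member window midpoints (the median and the
most-extreme member were considered; the mean is the only choice that
uses all members symmetrically and it is what the center-error
validation measures). Direction is polarized by tail votes: low ΔHo /
low π ratio vote "reduced in A", the high tails "reduced in B", and a
pure-FST or balanced cluster reports "elevated differentiation".

## The synthetic generator

`simulate_panel()` emulates the target study design so the pipeline can
be validated against known truth: 7 chromosomes, ~87 SNPs/Mb, tetraploid
dosages, two groups of 95 and 190 accessions. Default chromosome length
is 10 Mb — a deliberate desk-scale compression that keeps ~90 windows
per chromosome, enough for the quantile and band machinery to behave as
at full scale. Choices that matter:

* **Dosage model**: each genotype is Binomial(ploidy, p) — the
  random-bivalent-pairing idealization for an autotetraploid. Array
  data carry no phase, so this is the minimal sufficient model.
* **Group structure**: per-locus group frequencies are the base
  frequency (uniform on [0.05, 0.95]) plus truncated-normal jitter of
  scale `group_divergence = 0.05`, kept inside [0.01, 0.99]. This
  yields a realistic nonzero background FST rather than an artificially
  identical pair of groups.
* **Sweep injection acts on the generating frequency**, not post hoc on
  dosages: inside a truth interval, p moves toward a boundary by the
  sweep `intensity` (p ← p·(1−intensity), or symmetrically toward 1).
  The boundary is anchored on the *base* frequency so a sweep shared by
  several groups fixes the same allele in all of them, as a shared
  haplotype sweep would. Intensity 1 fixes the interval: He = π = 0
  exactly, the analytically known end state. Because the truth
  frequencies are stored, expected diversity reductions are available
  in closed form as an oracle.
* **Missingness** is independent per call at rate 0.08 — just under the
  10% per-locus filter threshold, so that a realistic fraction of loci
  (~10–20% depending on panel size) actually exercises the filter.
* **Positions** are uniform, sorted, with +1 bp collision shifts:
  windowing requires strictly increasing positions.

What the generator does **not** emulate: linkage disequilibrium between
loci (dosages are independent across loci given frequencies), ascertained
array SNP spacing, population structure beyond two exchangeable groups,
genotype-calling error, and soft sweeps (standing variation with several
haplotypes). Consequently, passing recovery tests demonstrates that the
scan machinery finds frequency-based diversity troughs of the injected
size and depth; it does not demonstrate robustness to LD-driven window
dependence beyond what accession resampling captures, nor power against
soft sweeps.

## The missingness filter

Loci are dropped when their missing fraction is *strictly greater* than
`max_missing = 0.10` — a locus missing in exactly 10% of samples
survives. The filter is panel-wide by default; `per_group = TRUE`
removes a locus when any single group exceeds the threshold, for designs
where group-specific call-rate artifacts are a concern. The operation is
idempotent and never touches samples.

## Numerical and formatting conventions

* Coordinates are 1-based inclusive everywhere internally; BED output
  converts to 0-based half-open only at the write boundary.
* Quantiles use R's default type-7 definition.
* Region merging unions metric sets and peak lists, orders output
  deterministically by (chromosome, start), and is idempotent and
  input-order invariant.
* Enrichment: one-sided (over-representation) Fisher exact test per
  term, BH correction within each region's tested terms, terms with no
  sweep-gene member skipped, background = all genes in the supplied
  table. Term-hierarchy filtering is out of scope; the term universe is
  whatever the gene-to-term map supplies.
* Determinism: every stochastic stage takes an explicit seed;
  `run_scan()` with the same config and seed produces byte-identical
  outputs.

## Validation problem sizes

The test suite validates exact claims (formula identities, window means
against naive loops, band depth selection against an exhaustive k-scan,
minima against a brute-force double loop, Fisher p against a
hypergeometric summation) at fuzz sizes of 10³–10⁴ cases, and stochastic
claims on the generator at study scale: 20 seeds of 7 × 10 Mb genomes
with 285 accessions and B = 200 bootstrap replicates for within-group
recovery (three shared 2.5–3 Mb sweeps at intensity 0.7), and 20 + 20
seeds for comparative recovery and null specificity. These sizes were
chosen to give stable rates while keeping a full validation run in the
low minutes on a single core.

## Known limitations

* **Comparative null specificity.** ΔHo and π ratio are built from the
  same group-wise window means and share accession-sampling noise; their
  window tracks correlate (~0.5 on null simulations) even when the
  groups differ only by jitter. Their 1% tail extrema therefore
  co-locate by chance more often than independence would suggest, and
  the ≥2-metric cluster rule admits roughly two spurious regions per
  null genome at study scale (measured over 20 seeds) rather than the
  near-zero a naive multiple-testing intuition might promise. The
  genome-wide tail scope and strict clustering already minimize this;
  users should treat comparative calls without FST support, or without a
  within-group counterpart, with caution. The acceptance suite reports
  this rate honestly rather than hiding it.
* The quantile rule of the within-group caller ranks windows *within*
  each chromosome, so some trough is eligible on every chromosome with
  negative deviations; the consensus requirement and the band
  annotation are the guards, not the quantile itself.
* `FST` here is the heterozygosity-based two-group formulation; it is
  not Weir–Cockerham variance-component FST and makes no
  ploidy-specific sampling correction beyond the dosage-based frequency
  estimates.
* LD decay (`ld_decay()`) uses squared Pearson correlation of dosages
  (the additive model); with unphased autotetraploid data this
  underestimates gametic LD and is intended for window-size guidance
  only.
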