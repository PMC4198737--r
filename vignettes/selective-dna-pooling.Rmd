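---
title: "Selective DNA pooling association scans with poolSDP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective DNA pooling association scans with poolSDP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolSDP)
```

## The design

Selective DNA pooling (SDP) replaces individual genotyping with array
genotyping of pooled DNA from the two phenotypic extremes of a trait
distribution. In the dairy-cattle setting this package targets, sires are
ranked on a deregressed breeding value (DP-EBV) for somatic cell score — an
indirect measure of mastitis resistance — and the top and bottom 20% form
the *high* and *low* tails. The pooled B-allele frequency (BAF) reported by
the array is an estimator of the allele frequency of the animals in the
pool, so a QTL affecting the trait shifts the BAF of linked SNPs between
the tails.

Technical replication is layered so that the null variability of the
estimator can be measured from the data themselves:

* each tail is split into **two sub-pools** of distinct animals (even and
  odd ranks within the tail, so both sub-pools have comparable mean
  phenotype);
* each sub-pool is re-constructed as **two duplicate DNA pools** from the
  same samples (capturing pool-construction error);
* each duplicate pool is genotyped as **three array replicates**.

A full design therefore occupies 2 × 2 × 2 × 3 = 24 chip positions per
SNP. `buildPoolDesign()` reproduces this structure, including a per-tail
cap on pool size for the common situation where fewer biobank samples are
available than the nominal tail size (a 275-sample biobank capped at
40/39 yields the 20/20 and 20/19 sub-pools of the motivating study).

## The statistic

For each SNP, all measurements of a (tail, sub-pool) cell are averaged
into a sub-pool mean. Two contrasts of these means are formed:

* `Dtest` — mean of the high-tail sub-pool means minus mean of the
  low-tail sub-pool means (the association signal);
* `Dnull` — the difference between the two sub-pool means *within* each
  tail (two values per SNP; animal-sampling plus technical noise, but no
  association signal, because both sub-pools share the tail's phenotype).

The test statistic is

$$Z = \frac{D_{test}}{\widehat{SD}(D_{test} \mid H_0)}, \qquad
  Z^2 \sim \chi^2_1 \text{ under no association},$$

with genome-wide control by Bonferroni: a SNP is significant when its
p-value is at most $\alpha / M$ for $M$ retained SNPs (the boundary
counts as significant). With $\alpha = 0.05$ and $M = 655{,}665$ markers
this nominal threshold is $7.62\times10^{-8}$.

### Calibrating SD against the null

`sdDnull()` estimates the null SD from the root-mean-square (RMS) of the
Dnull contrasts. Two points deserve care.

**The design factor.** A single Dnull value is a difference of two
sub-pool means, so its null variance is $2v$ when each sub-pool mean has
variance $v$. `Dtest` averages $k$ sub-pool means per tail
($k = 2$ here) before differencing, so its null variance is $2v/k$. The
raw Dnull RMS therefore over-estimates the null SD of `Dtest` by
$\sqrt{k}$, and dividing `Dtest` by it would make $Z^2$ roughly
$\chi^2_1/k$ — a severely conservative test whose Q-Q plot sags below
the identity line. `sdDnull(calibrate = TRUE)` (the default) multiplies
the RMS by $\sqrt{1/k}$ so that the statistic is referred to the correct
null scale; this is what makes the empirical type-I error match its
nominal level in the package's calibration tests. The uncalibrated RMS
remains available with `calibrate = FALSE`.

**Smoothing.** With two sub-pools per tail there are only two Dnull
values per SNP — a 2-degree-of-freedom variance estimate whose
reciprocal has heavy tails, so the per-SNP statistic would be strongly
anti-conservative at genome-wide thresholds. The default
`binned_smoothed` estimator ranks SNPs by their tail-balanced mean BAF,
partitions them into bins of `binSize` (default 1000) and assigns every
SNP the bin-pooled RMS. Binning on mean BAF matters because the
animal-sampling component of the null variance is proportional to
$p(1-p)$; pooling across frequencies would over-test intermediate-
frequency SNPs. When fewer than `binSize` × 10 SNPs are tested the
effective bin size shrinks to `max(50, floor(M/10))` so the estimator
still tracks the frequency dependence on small panels. The per-SNP
estimator (`per_snp_rms`) is retained for transparency; on panels where
all SNPs share one Dnull distribution the two agree closely (the test
suite checks < 5% relative difference at 10,000 SNPs).

Zero or non-finite estimates (e.g. a SNP whose sub-pool means are
identical to machine precision) are floored at the 0.1 percentile of the
positive estimates and flagged, so every retained SNP receives a finite
test. p-values that underflow are floored at the smallest positive
double; the chi-square survival function itself is computed by
`pchisq(..., lower.tail = FALSE)`, which is accurate without explicit
log-space handling throughout the representable range.

## Quality control

Three pre-test filters are applied, in this order:

1. **Replicate variability** — the 1% of SNPs with the noisiest array
   replicates are excluded. The published criterion ("size of the mean
   measures from the replicate array within tail") is ambiguous; this
   package scores each SNP by the within-chip-pool replicate SD, pooled
   across a tail's pools and averaged over tails, because replicates
   within one chip pool are the only purely technical contrast in the
   design. Exactly `floor(fraction * M)` SNPs are dropped, ties broken by
   (score descending, snp id) so the result is deterministic and
   order-invariant.
2. **Monomorphic SNPs** — pooled data carry no per-animal genotypes, so a
   SNP is monomorphic when every non-missing measurement is within
   `epsilon` (default 0.02 BAF) of 0 or of 1.
3. **Incomplete design** — the null contrast needs two sub-pool means per
   tail, so SNPs missing a whole sub-pool in some tail are set aside.

Whether the original analysis applied the variability exclusion before or
after monomorphic removal is not documented; this package applies
variability first and reports both sets separately in the `QcReport`, so
the order can be audited. Normality of the pooled Dnull distribution is
summarised by Anderson-Darling, Shapiro-Wilk (on a seeded subsample of at
most 5,000 values) and Kolmogorov-Smirnov tests; the KS variant uses
sample-estimated parameters, so its p-value carries the usual
Lilliefors caveat.

## Regions and annotation

Significant SNPs are merged into candidate regions by single linkage
within chromosomes: consecutive SNPs at most `regionMaxGap` (default
1 Mb) apart join one region, and regions with at least `regionMinSnps`
(default 3) members are reported. The 1-Mb gap is adopted because it
exactly reproduces the split of the published chromosome-15 signals into
three regions (internal gaps of the 50.4–51.6 Mb run are below 1 Mb;
the gap to the 31.3–32.0 Mb run is far above it). Region length is
defined as `end - start` — not `end - start + 1` — because that is the
convention the published region table arithmetic follows, verified
against all thirteen printed rows in the test suite.

Annotation is interval arithmetic on 1-based inclusive coordinates (BED
input is converted at the boundary): a SNP inside any gene is
`intragenic` (distance 0, all containing genes listed); otherwise, if the
nearest gene start/end lies within `annotationWindow` (default 1 Mb,
boundary inclusive) it is `nearby`; otherwise `intergenic`. Distance is
the unsigned base-pair offset to the nearest gene boundary; no
strand-aware upstream/downstream call is attempted because the source
material uses no consistent convention.

## The synthetic generator

Because the raw pooled-array intensities behind the motivating study are
not deposited, every stage is validated against simulated data generated
by the package itself:

* per SNP, a population frequency $p \sim U(0.05, 0.95)$ and independent
  genotypes $g \sim \mathrm{Binomial}(2, p)$ (no linkage
  disequilibrium);
* DP-EBV $= \sum_q a_q (g_q - 2p_q) + \varepsilon$,
  $\varepsilon \sim N(0, \sigma^2)$, so with $\sigma = 1$ planted effects
  are in residual-SD units; reliabilities are drawn $U(0.45, 0.65)$ to
  match the descriptive range of the motivating cohort and are carried
  for summaries only;
* measurement = true sub-pool frequency + one $N(0, \sigma_{pool}^2)$
  draw per duplicate pool + an independent $N(0, \sigma_{array}^2)$ per
  replicate, clipped to $[0, 1]$.

The two error strata mirror what duplicate pools and array replicates can
physically disentangle. No published estimate of either magnitude exists
for pooled high-density bovine chips; the defaults
$\sigma_{pool} = 0.01$ and $\sigma_{array} = 0.015$ BAF were fixed once
as values that keep the replicate design informative (technical noise
visible but not dominant over animal sampling at 20-sire sub-pools), and
both are configuration-exposed precisely because they are conventions,
not measurements.

What the simulation does **not** emulate: linkage disequilibrium (each
SNP segregates independently, so region recovery is exercised with
clusters of independently planted causal SNPs rather than LD blocks);
pedigree structure; the test-day model and deregression that produce real
DP-EBVs; array intensity artefacts beyond Gaussian noise (no wave,
GC or cluster-separation effects). Passing tests therefore demonstrate
the statistical machinery under its own assumptions, not robustness to
real-array pathologies.

### Validation scales

The test-suite and the acceptance script validate at sizes chosen to
exercise the asymptotics while staying desk-sized: type-I calibration on
20,000 null SNPs with a 275-sire cohort and 40/39 tails (the empirical
rejection rate at $\alpha = 0.01$ must fall inside the exact binomial
99% interval); power and recovery on 2,000 sires and 5,000 SNPs with
planted effects of 0.25, 0.5 and 1.0 residual SD; and a 500-SNP, 80-sire
toy fixture for end-to-end and antisymmetry checks. At the toy scale the
expected causal-SNP $z$ is only about 2–4 (16-sire tails), so the
fixture demonstrates pipeline mechanics and seed-stable recovery of the
stronger signal rather than guaranteed genome-wide discovery of every
planted QTL — an honest reflection of SDP power at very small cohort
sizes.

## Numerical and convention choices

* Tail sizes use `floor(fraction * n)`; ranking ties break by sire id, so
  selection is a total order and input-order invariant.
* Sub-pool means, not raw measurement means, are the unit of both
  contrasts: they equalise the weight of 20- versus 19-sire sub-pools
  and of unequal replicate counts after missingness.
* Duplicate-pool contrasts are technical-only and are *not* included in
  Dnull: the null contrast must carry the animal-sampling variance that
  also affects Dtest.
* Q-Q expected quantiles use $(i - 0.5)/n$; rows are emitted with the
  expected column increasing. The Manhattan x-coordinate is the position
  plus the summed maximum positions of preceding chromosomes, in natural
  chromosome order (numeric labels first, then others).
* Chromosome labels are opaque strings; no assembly awareness or
  liftover is attempted, so mixed-assembly coordinate tables cannot be
  reconciled and must be declared on one assembly by the user.
* All randomness flows through explicit integer seeds; identical seeds
  give byte-identical simulated fixtures and bit-identical result tables.

## A worked toy run

```{r toy, eval = FALSE}
dir <- tempfile("sdp")
fx <- makeToyFixture(dir, seed = 1)
out <- runPipeline(sdpConfig(), fx$paths["baf"], fx$paths["map"],
                   fx$paths["genes"], file.path(dir, "run"))
out$summary
```

The summary reports the SNP accounting (input, the three dropped sets,
retained), the nominal Bonferroni threshold `alpha / n_retained`, and the
significant-SNP and region counts; `results.tsv`, `regions.tsv`,
`annotations.tsv`, `qq.png` and `manhattan.png` are written next to it.

## Limitations

The test assumes pool construction draws equal DNA amounts per animal and
that BAF is an unbiased frequency estimator after array normalisation;
systematic per-SNP BAF bias cancels between tails only if it is shared,
so probe-level bias that differs by genotype cloud is not modelled.
Bonferroni is the only multiplicity control offered, matching the method
this package implements; no kinship or mixed-model correction is
available, so cryptic relatedness inflates the test exactly as it does in
the original design (the family-structure check flags over-represented
sire families but does not correct for them).
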