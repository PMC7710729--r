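---
title: "Methods: haplotype-based selection scans and channel-function quantification"
author: "sweepfunc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype-based selection scans and channel-function quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

sweepfunc ties together four analyses that, in combination, characterize a
recent positive-selection event on an ion-channel gene and its functional
consequences: a haplotype-based selection scan with simulation-derived
significance thresholds, population-genetic summary statistics, whole-cell
patch-clamp quantification, and hydrogen-bond statistics over conformational
ensembles of protein models. This vignette explains the models behind each
stage, the tunable parameters and their defaults, and the design choices
made where several reasonable conventions exist.

## The selection scan

### EHH, iHH and iHS

For a biallelic core SNP with alleles polarized as ancestral (0) and derived
(1), the extended haplotype homozygosity (EHH) at an offset site is the
probability that two randomly drawn carriers of the same core allele are
identical at every site between the core and that offset. We compute it
exactly as a pair count: carriers are partitioned into identity groups that
refine site by site moving away from the core, and

EHH = sum over groups of C(n_g, 2) / C(n, 2),

computed separately leftward and rightward. A haplotype with a missing call
inside the interval leaves the pair count from that offset outward (the
denominator shrinks with it; once fewer than two carriers remain the curve
is 0 and cannot recover, so the walk stops).

iHH is the trapezoidal integral of the EHH curve over physical distance in
bp, per side, truncated at the first offset where EHH drops below
`ehh_cutoff` (default 0.05, the convention of the standard EHH software; the
trapezoid reaching the truncation offset is included). Three exclusion rules
apply, each a typed outcome rather than an error:

* **gap rule** — if two adjacent informative sites more than `gap_limit_bp`
  apart (default 20 kb) are crossed before truncation, the variant is
  excluded;
* **border rule** — if the panel edge is reached while EHH is still at or
  above the cutoff, the integral is not fully observable. Two policies are
  offered: `border = "exclude"` (the default, and the convention of the
  standard software) drops the variant; `border = "truncate"` integrates
  the observable span for both allele classes. On genome-scale data the
  two differ only at chromosome ends. On a short simulated panel, however,
  exclusion removes a large share of variants — whole stretches in
  long-haplotype regions — leaving windows with one or two surviving SNPs
  whose "mean" scores are pure noise and dominate the null tail; the
  simulation harness therefore runs with `"truncate"`, which biases edge
  scores mildly toward zero (both classes are truncated at the same
  boundary) and keeps windows well populated;
* **MAF rule** — sites with minor allele frequency not strictly greater
  than 0.05 are never scored ("higher than" is read as a strict
  inequality).

The unstandardized score is `uiHS = ln(iHH_A / iHH_D)`. The sign convention
matters and is easy to get backwards: **positive values mean extended
homozygosity around the ancestral allele; a sweep on the derived allele
drives the score negative.** Scores are standardized within
derived-allele-frequency bins (width 0.05 by default) to mean 0 and unit
standard deviation; bins with fewer than two scored variants are flagged and
excluded, never merged.

`standardize_ihs()` accepts a `reference` — the bin statistics of a previous
(typically neutral-simulation) standardization. This exists because a short
candidate region has no neutral background of its own: standardizing a
300 kb sweep panel against itself absorbs the sweep into the bin means and
destroys the signal. Genome-wide empirical standardization, as done on real
data, is approximated here by standardizing candidate panels against the
pooled neutral-replicate bins.

### Windows and the neutral threshold

Scored SNPs are aggregated into non-overlapping 30 kb windows anchored at
coordinate 0 (half-open intervals, 1-based positions mapped by
`floor((pos - 1)/30000)`). Two window statistics are always computed:
`|mean(iHS)|` and `mean(|iHS|)`. The default reported score is
`|mean(iHS)|`, following the phrase "average of iHS scores across SNPs"
with the absolute value taken afterwards; which statistic was configured is
recorded in the output. The critical value is the empirical 99.99th
percentile (linear interpolation between order statistics) of the window
scores from neutral replicates, and windows whose score strictly exceeds it
are called candidates.

### The neutral simulator

The null distribution comes from a forward-in-time Wright–Fisher simulator:
discrete non-overlapping generations, multinomial resampling of diploid
parents, Poisson crossovers at uniform positions, infinite-sites mutation at
uniform continuous positions, population splits, epoch-wise size changes and
per-generation backward migration. One simulator serves neutral nulls and
selective sweeps, which keeps a single code path under test. Haplotypes are
sparse sorted mutation lists, so runtime scales with diversity rather than
sequence length.

A sweep is planted as standing variation: at `start_gen` the selected allele
is assigned to a fraction `f0` of haplotypes in the target population, and
from then on diploid parents are drawn with fitnesses 1, 1 + hs, 1 + s.
Losing the allele is a typed `sweep_lost` outcome. `stop_freq` ends the
simulation (and samples immediately) when the derived frequency first
reaches a target, emulating sampling near fixation.

### Reduced problem sizes and what they show

The study-scale null (a published human three-population demography,
genome-scale replication, critical value 2.54) is out of reach on a
desktop, so the package ships a scaled-down demography
(`inst/extdata/demography_three_pop.yaml`) chosen once as follows: an
African-like founder of N = 120 diploids with a 10 N generation burn-in,
European-like and Asian-like daughters (N = 80) splitting 360 and 240
generations before sampling, migration 5e-5 per generation, and per-bp
rates mu = r = 1.05e-6 so that the population-scaled diversity
(theta = 4 N mu ~ 5e-4/bp) and recombination (rho ~ 5e-4/bp) match
human-like values; 40 diploids are sampled from the target population over
300 kb (ten 30 kb windows). The neutral null uses 1000 replicates (10,000
windows), the smallest size at which the 99.99th percentile is defined by
interpolation rather than the maximum. Estimating a 1-in-10,000 quantile
from 10,000 draws is intrinsically noisy: independent seeds give critical
values that scatter by several tenths around the long-run value, and any
power estimate against such a threshold inherits that scatter. The tests
therefore assert *reproducibility* (thresholds from independent seeds
agree within bootstrap error of the percentile; the percentile is monotone)
rather than a particular constant — the study-scale critical value 2.54
rests on external demographic parameters and genome-scale replication that
a desk run cannot reproduce.

The sweep-power harness plants a single-copy standing variant
(`f0 = 1/2N`) with s = 5/3 (2Ns = 400), h = 0.5, and samples when the
population frequency first reaches 0.8. Three choices here deserve
explanation:

* **single copy rather than f0 = 0.05**: at 2N = 240, five percent standing
  frequency means ~12 founder haplotypes; selection then lifts several
  distinct backgrounds at once (a soft sweep), which iHS is well known to
  miss. At human population sizes the same f0 behaves much closer to a hard
  sweep because the pre-selection coalescent time of the carriers is short
  relative to the sweep. A single-copy variant — still standing, neutral
  variation when selection begins — restores the hard-sweep footprint the
  test is about.
* **sampling at 0.8 rather than higher**: sampling binomially from a
  population at 0.9+ routinely yields sample frequencies above 0.95, and
  the core site itself is then removed by the MAF filter.
* **window score `mean(|iHS|)` for the power harness**: in a swept window
  at this scale, hitchhikers carry strongly negative scores while
  low-frequency escapees carry strongly positive ones, so the signed mean
  partially cancels. Both statistics are computed everywhere; the package
  default remains `|mean|`.

Passing these tests shows that the estimator chain (EHH -> iHH -> iHS ->
windows -> percentile -> calls) is correct and internally consistent and
that the pipeline detects hard sweeps of the stated strength at this scale.
It does not show that real human data would reproduce the study's critical
value, nor anything about soft-sweep power.

## Population-genetic summaries

Allele frequency from genotype fractions is
`p = hom_derived + het/2`. Two-locus haplotype frequencies are plain counts
over phased haplotypes (haplotypes missing either allele leave the
denominator). LD follows the textbook definitions: `D = p11 - pA pB`,
`D' = |D|/Dmax` (with Dmax the frequency-bound appropriate to the sign of
D), `r^2 = D^2 / (pA(1-pA) pB(1-pB))`; `D'` is reported unsigned. Per-site
Fst defaults to the Hudson estimator with sample-size correction —
numerator `(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`, denominator
`p1(1-p2) + p2(1-p1)` — because it behaves well under unequal sample sizes;
Weir–Cockerham and the uncorrected plug-in form are available, and the
estimator name is always recorded. Negative corrected values are reported
as computed, not clamped. Phased input is required; genotype-based (EM)
LD is deliberately out of scope.

## Electrophysiology quantification

The step protocol is 400 ms pulses from -100 to +160 mV in 10 mV
increments with a 200 ms post-pulse at -100 mV, sampled at 10 kHz.
Per voltage:

* **steady state** — mean over the final 10% of the test pulse (the
  averaging window is a package choice; it is configurable and logged);
* **instantaneous tail** — the extremum within 5 ms after repolarization,
  after a 0.5 ms capacitive blanking window (both windows configurable).
  Note the estimator's intrinsic bias: the true instantaneous amplitude
  decays by `exp(-blank/tau)` before the first usable sample;
* both are divided by membrane capacitance (pA/pF).

AUC is the trapezoidal integral of current density over voltage; for
steady-state curves only voltages >= 0 enter (the outward limb), tails are
integrated over the full range and may be negative. Units are
pA/pF x mV; whether a printed AUC integrated density or raw current is not
deducible from the source material, and this implementation documents its
own choice.

Single-channel amplitude is the peak-to-peak distance between adjacent
Gaussian component means fitted to the amplitude histogram (EM via mclust,
initialized from a deterministic subsample; a fit whose level separation is
below the summed component standard deviations is reported as
"components not resolvable"). NPo divides the mean absolute
baseline-subtracted current of a long (conventionally 40 s) recording by
the unitary amplitude; the baseline is the largest-weight component mean,
justified by the low open probability at hyperpolarized potentials (closed
dwell dominates). Slope conductance is an ordinary least-squares fit of
unitary current against voltage at -60/-80/-100 mV, reported in pS; a
non-zero reversal potential lands in the intercept. Deactivation is a
bounded Levenberg–Marquardt mono-exponential fit `I(t) = A exp(-t/tau) + C`
started from a log-linear regression.

The gating simulator advances N independent two-state channels at the
sampling interval with transition probabilities `1 - exp(-k dt)` (a
discrete-time update, chosen because the estimators consume sampled traces;
a warning is recorded when `k dt > 0.1`). The unitary current is
`i_u = g (V - E_rev)/1000` pA, so openings at negative potentials are
negative (inward) — note that NPo and the amplitude histogram are
sign-agnostic. Synthetic noise is white; the 1 kHz low-pass of real
acquisition chains is *not* re-simulated, which makes synthetic histograms
slightly sharper than real ones.

## Structural-ensemble hydrogen bonds

The analysis consumes only distances: for a residue pair such as Asp390
(OD1/OD2) against Lys452 (NZ), the per-model distance is the minimum over
the cross atom pairs (carboxyl oxygens are chemically equivalent; mean and
named-atom reductions are available). The hydrogen-bond criterion is
distance-only — 3.5 A bonded, plus a 0.5 A acceptance margin. Because "3.5
with a 0.5 margin" is ambiguous (acceptance at 3.5 or at 4.0?), the policy
keeps both thresholds explicit in every report: *accepted* means distance
<= cutoff + margin, while the *non-bonded* distance statistics are computed
over the strict > 3.5 A complement (the margin never moves distances
between the bonded-fraction numerator and the non-bonded sample). No
donor–acceptor angle term is applied, mirroring the distance-only
criterion of the source analysis.

The toy-ensemble generator writes one minimal PDB per model with the four
named atoms placed on orthogonal axes so that each pair's minimum distance
equals its sampled target exactly (OD1 at the origin, OD2 offset 0.5 A
along x, K452 NZ on the negative x axis, K455 NZ on the y axis). Only the
named pairwise distances are meaningful — there is no realistic side-chain
geometry, no clashes, no physics. Distances are drawn either from a normal
distribution (distance-recovery studies) or from a two-regime mixture
controlled by a bond probability (fraction-recovery studies).

The Mann–Whitney U test enumerates all C(n1+n2, n1) rank assignments
exactly for tie-free samples of at most 10 per group, and otherwise uses
the normal approximation with tie correction and continuity correction;
the method actually used is part of the result. The reference p-values of
the source analysis (1.1e-106, 7.3e-54) depend on its Rosetta ensembles and
are not reproduced; the package's tests instead verify the statistic
against enumeration, the reference implementation in `stats`, and a
permutation estimate.

## Pipeline and reproducibility

Every generator is a pure function of (configuration, seed). The pipeline
derives per-stage seeds from a single run seed via a stage-name hash, so a
stage can be rerun in isolation and still match the full run. Outputs are
plain TSV/JSON with a run report listing every file and its checksum;
summary tables are rebuilt from the on-disk outputs alone. Identical seeds
give byte-identical outputs.

## Known limitations

* The forward simulator is infinite-sites and biallelic; no gene
  conversion, no mutation-model refinements.
* iHS integration is over physical distance; a genetic-map hook exists but
  defaults to uniform.
* The scaled-down demography reproduces scaled diversity, not human
  genealogical depth; absolute thresholds are not comparable to
  genome-scale studies.
* Synthetic recordings use white noise and mono-exponential kinetics;
  multi-exponential deactivation and filtered noise are not modelled.
* Ensemble geometry is schematic; only the configured pair distances carry
  information.
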