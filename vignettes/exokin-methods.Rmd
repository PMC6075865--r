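---
title: "exokin: models, generators and numerical choices"
author: "exokin authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{exokin: models, generators and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exokin)
```

This vignette is the package's own account of the science it
implements: the models, the assumptions behind them, the synthetic-data
generators used to validate every estimator, and the numerical choices
made where the underlying experimental conventions leave the algorithm
open.

# Flash-evoked capacitance decomposition

## Model

After flash photolysis of caged Ca²⁺, the whole-cell membrane
capacitance of a neuroendocrine cell rises in a stereotyped way: a fast
and a slow exponential burst component — interpreted as fusion of the
readily releasable (RRP) and slowly releasable (SRP) vesicle pools —
followed by a linear sustained component reflecting ongoing priming and
fusion:

$$ f(t) = A_0 + A_1\left(1 - e^{-t'/\tau_1}\right)
              + A_2\left(1 - e^{-t'/\tau_2}\right) + k\,t', \qquad
   t' = t - t_0 . $$

`fitFlashResponse()` estimates $A_0$ (pre-flash capacitance, fF),
$A_1,\tau_1$ (RRP amplitude and time constant), $A_2,\tau_2$ (SRP), $k$
(sustained rate, fF/s) and the burst onset $t_0$ by damped
(Levenberg–Marquardt) least squares.

The *secretory delay* is classically constructed geometrically: the
fast exponential is back-extrapolated and intersected with the
baseline, and the delay is the time from the flash to that
intersection. For an exponential rising from a flat baseline this
construction is exactly equivalent to fitting a free onset time $t_0$
at which the burst components start (components zero before $t_0$,
baseline continuing), and the free-onset parameterization is
numerically much better behaved, so that is what the package fits;
`secretoryDelay()` returns $t_0 - t_{\text{flash}}$ in ms.

## Numerical choices

* **Multi-start.** The sum of two exponentials has local minima when
  the time constants initialize poorly. Four starts are tried
  ($\tau_1 \in \{10, 30\}$ ms $\times$ $\tau_2 \in \{150, 400\}$ ms,
  amplitudes from trace quantiles, $k$ from the late-trace slope); the
  lowest residual wins, ties broken towards the smaller $\tau_1$.
* **Bounds.** $\tau_1 \in [1, 100]$ ms, $\tau_2 \in [50, 2000]$ ms,
  amplitudes $\ge 0$, $t_0 \in [t_{\text{flash}},
  t_{\text{flash}} + 100\,\text{ms}]$. These bracket the physiological
  ranges of chromaffin-cell burst kinetics with a wide margin.
* **Label stability.** RRP/SRP labels are assigned by *ordering the
  fitted time constants after optimization* ($\tau_{\text{RRP}} <
  \tau_{\text{SRP}}$), so no choice of starting values can swap pools.
* **Sign of k.** The sustained rate is deliberately left unconstrained
  and reported as fitted: a negative estimate is diagnostic (endocytosis
  or drift), and constraining it would silently bias the burst
  amplitudes.
* **Convergence.** `nlsLM` with `ftol = ptol = 1e-15`; on noise-free
  generator traces all parameters are recovered to better than 1e-6
  relative error (verified in the test suite). Non-convergence returns
  a flagged result with a warning rather than an error.

`tonicRate()` is the least-squares slope of capacitance over a window
(premature secretion at sub-micromolar or elevated constant Ca²⁺).
`deltaCm()` reports the total rise over an elapsed time; each endpoint
is read from a short (default 1 s) least-squares line evaluated
*exactly at the endpoint*. A median window — the more obvious smoother
— is biased by slope·w/2 on ramp-like traces, while the local-line
endpoint is unbiased for linear trends and exact on noise-free ramps;
`smooth_s = 0` gives the raw-sample definition.

# Amperometric spike and foot analysis

## Signal model

Carbon-fiber amperometry resolves single-granule catecholamine release
as current spikes (25 kHz sampling, 2 kHz low-pass). Many events begin
with a small *prespike foot* — flux through the nascent fusion pore —
whose fast fluctuations ("flickers") report attempts of the machinery
to widen the pore.

## Detection

* **Baseline**: running median over 200 ms. The window is long against
  events (ms) and robust to their presence; the convention is not
  standardized in the literature, so it is a configurable parameter.
* **Noise SD**: median absolute deviation of the baseline-subtracted
  current, floored at 0.05 pA so noise-free synthetic traces remain
  analyzable.
* **Thresholds**: events open above baseline + 4 SD and extend to the
  surrounding 2 SD re-crossings (hysteresis), placing boundaries at the
  return to baseline. Regions must persist at least 1 ms above the
  hysteresis level: secretory events last milliseconds, while
  single-sample noise excursions occasionally clear any amplitude
  threshold (without the width rule the false-discovery rate on
  synthetic recordings rises from <1% to ~30%).
* **Eligibility**: the published selection cuts are applied *after*
  detection, as flags — amplitude > 4 pA with charge 10–5000 fC for
  frequency analysis, amplitude > 7 pA for kinetic analysis.

## Per-event quantities

Charge is the trapezoidal integral of the baseline-subtracted current
(pA·ms ≡ fC). Rise time (50→90%) and half width use interpolated
crossings; the analysis window is padded by 1 ms beyond the detection
boundaries because the 50% level of a large spike can lie below the
detection hysteresis. Events with a second prominent peak are flagged
as overlapping and their kinetics withheld rather than guessed.

The foot is delimited by (i) the first sustained rise above baseline +
3 SD and (ii) the main-spike *takeoff*, located at the maximum of the
smoothed second derivative within a 2 ms window before the peak.
Restricting the takeoff search to the upstroke region is essential:
curvature inside the foot (flicker edges) would otherwise masquerade
as the takeoff. Because the curvature maximum of a smooth upstroke
sits partway up the rise, measured foot durations overshoot the
underlying plateau end by a sub-millisecond offset; the effect is
visible against generator ground truth and documented in the tests.
Feet shorter than 0.5 ms are reported absent; the fluctuation analysis
is restricted to feet longer than 2 ms (`foot_analyzable`), a
published convention retained here.

## Flickers and rms noise

The current derivative (pA/ms) is low-pass filtered at 1.2 kHz and
excursions beyond ±6 pA/ms are counted — one count per contiguous
suprathreshold run, polarities counted separately and summed; the
fluctuation frequency is the count divided by the foot duration.
Runs touching the foot boundaries are not counted: at the start they
reflect the foot onset ramp, at the end the spike upstroke, neither a
pore flicker. The fixed ±6 pA/ms threshold is the default; an adaptive
4×SD-of-derivative mode is available and the threshold used is
recorded per event. The rms noise — a threshold-independent pore
statistic — is computed after removing a 3rd-order polynomial trend
from the foot current (removes the slow ramp without absorbing
millisecond fluctuations; order configurable).

`cellSummary()` aggregates the way cell-based studies report: median
per cell, then unweighted mean ± SEM across cells with more than 20
events, so prolific cells do not dominate.

## What the generator emulates

`simulateAmperometry()` renders Poisson-placed events (log-normal
amplitude distribution, log-normal-shaped spike template whose rise
time, half width and charge are analytically known), optional
ramp-to-plateau feet, flicker slope pulses, Gaussian noise, and the
2 kHz acquisition filter, returning ground truth for every event.
Three generator choices are deliberate co-designs with the detector's
contracts:

* flickers are *alternating-sign slope pulses confined to the foot
  plateau* — each pulse yields exactly one suprathreshold derivative
  run, and pulses never superpose on the onset ramp (where slopes
  would add and make nominally sub-threshold pulses cross threshold);
* the foot decays under the spike over 2 ms, keeping its own
  derivative sub-threshold;
* same-polarity pulses are spaced so the 1.2 kHz derivative filter
  cannot merge their runs.

Within these constraints injected and counted flickers agree *exactly*
on noise-free recordings (200/200 feet in the test suite). The
generator does not emulate electrode drift, overlapping-event
deconvolution, kiss-and-run kinetics, or non-Gaussian electrode noise —
so passing tests demonstrate correctness of the estimators under the
stated model, not robustness to every pathology of real recordings.

# Second-order SNARE assembly kinetics

For the equimolar bimolecular reaction A + B → P ($A_0 = B_0$) the
integrated rate law gives the assembled-complex signal

$$ SC(t) = SC_0 + (SC_\infty - SC_0)\,
           \frac{A_0 k t}{A_0 k t + 1} . $$

`fitAssembly()` estimates $SC_0$, $SC_\infty$ and $k$ with $A_0$
*fixed* at the limiting reactant concentration (default 3 µM): $k$ and
$A_0$ enter only as a product and are not separately identifiable from
one curve. Times are minutes, $k$ in M⁻¹s⁻¹. The starting $k$ comes
from the observed half-rise time ($A_0 k t_{1/2} = 1$). Flat time
courses are refused with a k→0 boundary flag instead of a meaningless
estimate. `normalizeTimeCourse()` divides by the value at a reference
time (default 240 min), making curves scale-free.

The generator default $k = 300$ M⁻¹s⁻¹ (half-saturation ≈ 19 min at
3 µM) was chosen to emulate assembly assays whose time courses plateau
well before the 240-min normalization point, consistent with reported
SNARE-assembly rate constants; with ~10% multiplicative densitometry
noise (the generator's `cv_noise = 0.1`) unweighted least squares then
recovers $k$ with a mean bias below 2%. On barely-saturating curves
(half-saturation beyond half the observation window) $k$ and
$SC_\infty$ become strongly correlated and multiplicative noise
inflates the mean $k$ by several percent — a genuine property of
unweighted NLS on this law, worth remembering when designing assays.

`compareAssemblyRates()` reports each group's mean rate as percent of
the control mean (SEM by first-order error propagation), a
Kruskal–Wallis omnibus test, and Dunn's post-hoc comparisons against
control. Dunn's z statistic (pooled mean ranks, tie-corrected
variance) is implemented in the package — no installed dependency
provides it — and is verified against a hand-computed small-sample
case; the Bonferroni adjustment is the default and switchable.

# SN1-mimicry scoring

## Percent similarity

A position is *similar* iff its BLOSUM62 substitution score is
positive (identities included), and the percentage is taken over
aligned, non-gap columns — the similarity convention of the standard
global-alignment tools. Equal-length segments are compared gaplessly;
unequal lengths are first aligned globally with affine gaps (open 10,
extend 0.5, the conventional defaults, via `Biostrings`). On the
built-in segment pairs the optimal global alignment is gap-free, so
both modes agree — an invariant the tests check.

## Hydrophobic moment

$$ \mu_H = \frac{1}{N}\sqrt{\Big(\sum_n H_n \sin n\delta\Big)^2 +
                            \Big(\sum_n H_n \cos n\delta\Big)^2} $$

with the Eisenberg normalized consensus scale and $\delta = 100°$ per
residue (ideal α helix). The scale is exposed as a named, swappable
table (`hydrophobicityScale()`); the moment is invariant to the phase
origin (checked property-style) and bounded by $\max_n |H_n|$.
`helicalWheel()` returns the deterministic projection table (residue
$n$ at $(n-1)\delta \bmod 360°$).

## Built-in segments

`snareSegments()` ships the complexin-II C-terminal domain peptide
(residues 101–134), its scrambled control, the 18-residue CTD
comparison region (117–134, hydrophobic layers +2…+7 of the SNARE
alignment), and the length-matched membrane-proximal SNARE segments:
SNAP25a SN1 60–77 (note: the *exon-5a isoform* sequence — the SN1
region is one of the few places where the 5a/5b isoforms differ),
SNAP25 SN2 183–200, SybII 63–80 and Syx1A 233–250, following the
canonical mouse sequences. The SN2 register was fixed by requiring the
segment to satisfy both of its published summary statistics
(hydrophobic moment and percent similarity) simultaneously, which
pins it two residues C-terminal of the naive equal-offset register.

`scanMimicry()` slides a window along one or more query proteins,
scores every window against every target, and summarizes per target
the mean ± SEM of each query's best window — the form used to average
one motif over several species. Cross-species inputs are the user's
responsibility; the package ships no external sequence retrieval.

# Group statistics

One-way ANOVA with `TukeyHSD` (Tukey–Kramer under unequal n) and the
two-sided Wilcoxon rank-sum test wrap the stock R implementations;
the Mann–Whitney p is exact for small samples (both n ≤ 8, no ties)
and normal-approximated with tie and continuity correction otherwise,
and is verified against brute-force enumeration of all group
assignments. `ecdfTable()` returns the right-continuous empirical CDF
at the sorted unique values. Stars follow the usual convention
(* p<0.05, ** p<0.01, *** p<0.001).

# Test problem sizes

The suite validates estimators at sizes chosen to give tight
Monte-Carlo conclusions while keeping the default run fast: 50 noisy
flash replicates (5 fF noise) for pool-recovery bias; 50 ten-second
noisy amperometric recordings (~500 events) for detection sensitivity
(≥95% observed 98.8%) and false discovery (≤5%, observed 0.4%); 200
noise-free feet for exact flicker-count fidelity; 200 assembly fits at
cv = 0.1 for the k-bias bound; 1000 null simulations for rank-test
calibration; 400-replicate nulls for Tukey family-wise error and
Mann–Whitney p-uniformity.

# Known limitations

* The flash fit assumes a flat pre-onset baseline inside the fit
  window; strong pre-flash drift should be handled by windowing or by
  `tonicRate()` first.
* Overlapping amperometric events are superposed, flagged, and
  excluded from kinetics — not deconvolved.
* Foot durations inherit the positive takeoff offset discussed above;
  comparisons between groups are unaffected (the offset is common),
  absolute durations carry it.
* The second-order assembly law assumes equimolar reactants and a
  single rate-limiting bimolecular step; mechanistically richer
  schemes (nucleation, intermediates) are out of scope.
* Similarity percentages depend on the "positive substitution score"
  convention; alternative similarity sets can be emulated only by
  swapping the substitution matrix.
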