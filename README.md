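# exokin

Kinetic analysis of regulated exocytosis in neuroendocrine cells, for
electrophysiologists and biochemists studying how complexin and the
SNARE machinery control vesicle fusion.

Chromaffin-cell secretion experiments produce four kinds of
quantitative data, and `exokin` implements the full analysis chain for
each of them:

1. **Flash-photolysis capacitance responses.** After Ca²⁺ uncaging,
   the membrane capacitance rises as two exponential burst components —
   the readily releasable pool (RRP) and the slowly releasable pool
   (SRP) — on top of a linear sustained component:

   *f(t) = A₀ + A₁(1 − e^(−t′/τ₁)) + A₂(1 − e^(−t′/τ₂)) + k·t′*,
   t′ = t − t₀.

   `fitFlashResponse()` estimates all parameters plus the burst onset
   t₀, whose distance from the UV flash is the *secretory delay*.
   `tonicRate()` and `deltaCm()` quantify premature (pre-stimulus)
   secretion.

2. **Carbon-fiber amperometry.** Single-granule release events are
   detected in 25 kHz current recordings (`detectSpikes()`); main-spike
   kinetics (50–90% rise time, half width, charge), prespike-foot
   parameters, fusion-pore *flicker* frequency (suprathreshold
   excursions of the 1.2 kHz-filtered current derivative beyond
   ±6 pA/ms, per ms of foot) and foot rms noise are quantified per
   event and aggregated as cell-weighted means of per-cell medians
   (`cellSummary()`).

3. **SNARE-assembly kinetics.** SDS-resistant ternary complex
   formation follows the integrated second-order law for equimolar
   reactants,

   *SC(t) = SC₀ + (SC∞ − SC₀)·A₀kt / (A₀kt + 1)*,

   fitted by `fitAssembly()` with A₀ fixed at the limiting reactant
   concentration (3 µM); group rates are compared by Kruskal–Wallis
   with Dunn's post test (`compareAssemblyRates()`).

4. **SN1-mimicry scoring.** The complexin-II C-terminal domain
   resembles the SNAP25 SN1 SNARE motif. `percentSimilarity()` scores
   segment pairs as the fraction of aligned positions with a positive
   BLOSUM62 score; `hydrophobicMoment()` computes the Eisenberg mean
   hydrophobic moment per residue,

   *µH = (1/N)·√[(Σ Hₙ sin nδ)² + (Σ Hₙ cos nδ)²]*, δ = 100°;

   `helicalWheel()` and `scanMimicry()` support projections and
   sliding-window scans. `snareSegments()` ships the relevant CpxII /
   SNAP25a / SybII / Syx1A segments.

Every estimator has a matching seeded generator
(`simulateFlashTrace()`, `simulateAmperometry()`,
`simulateAssembly()`) that emulates the statistical structure of the
corresponding recording and returns ground truth, so recovery can be
verified end to end.

## Worked example

```r
library(exokin)

## a synthetic Ca2+-uncaging experiment: 4 pF cell, known pools
params <- flashSimParams(A0_fF = 4000, A_rrp_fF = 180, tau_rrp_ms = 25,
                         A_srp_fF = 220, tau_srp_ms = 300, k_sus_fFps = 18,
                         onset_delay_ms = 2.5, noise_sd_fF = 5, seed = 7)
fitFlashResponse(simulateFlashTrace(params))
#> Flash-evoked capacitance decomposition
#>   A0      = 3997.5 fF
#>   RRP     = 183.3 fF  (tau = 24.8 ms)
#>   SRP     = 219.4 fF  (tau = 302.3 ms)
#>   sustained rate = 17.95 fF/s
#>   secretory delay = 2.58 ms
#>   residual rms = 5 fF

## helix mimicry of the CpxII C-terminus
hydrophobicMoment(snareSegments()$cpx2_ctd_box)
#> HelixWindow CpxII CTD box (delta = 100 deg, eisenberg scale): muH = 0.506
percentSimilarity(snareSegments()$cpx2_ctd_box, snareSegments()$snap25_sn1)
#> BLOSUM62 similarity (gapless): 9/18 positions = 50.0%
```

The fit recovers the generating pool sizes within the noise (RRP
183 fF vs 180 true, SRP 219 fF vs 220), the time constants and the
2.5 ms secretory delay; the residual rms equals the injected 5 fF
noise. The CpxII C-terminal comparison region is as amphipathic as the
SNAP25-SN1 motif (µH 0.506 vs 0.509) and shares half of its 18
positions at positive BLOSUM62 score.

## Documentation

The methods vignette (`vignettes/exokin-methods.Rmd`) describes the
models, the synthetic-data generators and their defaults, the
numerical choices and the known limitations.
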