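---
title: "Quantifying pheromone responses from sensillum tip-recordings: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pheromone responses from sensillum tip-recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrquant)
```

## The measurement problem

Moth pheromone-sensitive olfactory receptor neurons (ORNs) are recorded
extracellularly by slipping an electrode over the clipped tip of a trichoid
sensillum. Two channels are kept: the unfiltered **DC** trace, which carries
the slow transepithelial (sensillum) potential, and a 150 Hz high-pass
filtered **AC** trace in which action potentials stand out. A brief (50 ms)
pheromone pulse is delivered every 5 minutes over a two-hour recording; the
long inter-stimulus interval avoids desensitisation.

The spiking answer to each pulse has three consecutive components with
distinct kinetics: a *phasic* burst of roughly ten near-regular,
high-frequency spikes lasting under 100 ms; a *tonic* component of slower,
more irregular spiking over several hundred milliseconds; and — after a
pause — a sparse *late long-lasting response* (LLPR) that can persist for
minutes. Because the components encode different stimulus attributes
(concentration changes ride on the phasic component only), the pipeline
quantifies each stimulation by five separate parameters:

| parameter | definition |
|---|---|
| latency (ms) | first spike after the start of the DC response, minus that onset |
| F6AP (Hz) | mean of the five reciprocal inter-spike intervals of the first six spikes; missing if fewer than six spikes occur within 1 s |
| SPA (mV) | magnitude of the maximal negative DC deflection relative to the pre-stimulus baseline |
| #APs early | spikes in a fixed window after onset: 1 s for the standard protocol, 100 ms for paired toxin protocols |
| #APs LLPR | spikes from 5 s after a stimulus up to the next stimulus (a 295 s window at the 5-minute interval) |

Response *kinetics* are summarised separately: spikes of the first second
are pooled over all stimulations of one animal in 10 ms bins, and the
cumulative histogram is fitted with

$$AP(t) = \frac{AP_\max}{1 + \exp\!\big((t - t_{1/2})/k\big)},$$

which increases only for $k < 0$; $k$ is therefore constrained negative,
and a *steeper* response means $k$ *closer to zero*. Group statistics on
the slope magnitude use $\log_{10}|k|$.

## Drug effects as gated slopes

Pharmacological agents infused through the recording electrode reach the
sensillum lymph slowly and at unknown final concentration, so drug effects
appear as gradual changes over the two hours of stimulation. Each response
parameter of each animal is therefore reduced to the slope of an ordinary
least-squares line over recording time (units per minute). Slopes whose
two-sided *t* test against zero is not significant at $\alpha = 0.05$ are
set to exactly zero before any group comparison ("no significant change
over time"). Two deliberate edge-case rules:

* an exact zero-residual line counts as significant (the *t* statistic
  diverges; gating it to zero would discard a perfect trend);
* fewer than three usable points yield a missing slope with the gate
  closed.

Group comparisons then follow a fixed decision tree: Shapiro–Wilk per
group and a median-centred Levene (Brown–Forsythe) test across groups; if
both pass, one-way ANOVA with Tukey's post hoc test; if either fails and
all values are positive, the data are log-transformed and retested; if the
transformed data still fail, ANOVA on ranks (Kruskal–Wallis, statistic
*H*) with Bonferroni-adjusted Dunn tests. Exactly one branch is ever
reported, and the post hoc method always matches the branch. Paired toxin
designs (three control stimulations on day 1, six treatment stimulations
on day 2, same animal) use a one-way repeated-measures ANOVA on per-animal
condition means, removing the between-animal effect; the Tukey–Kramer
post hoc uses the within-animal error term. Groups with fewer than three
values, or with all values identical, cannot be tested for normality; they
are treated as "cannot reject" rather than as failures.

qPCR expression uses the standard $2^{-\Delta\Delta C_t}$ method with two
reference genes; the arithmetic mean of the two reference $C_t$ values is
used (equivalent to the geometric mean of the reference expression
levels), technical replicates are averaged first, and the calibrator is
the ZT1 group mean $\Delta C_t$ by default (the calibrator only rescales
fold changes globally; the ANOVA across zeitgeber times is invariant to
it). Amplification efficiency is fixed at 2; efficiency correction is out
of scope.

## What the synthetic generator emulates

Because no raw traces are deposited with the study this pipeline is
modelled on, every stage is validated against a ground-truth simulator:

* **Spike trains.** The phasic burst is a gamma-renewal process with high
  shape (default 50; `Inf` gives exactly regular intervals), capturing the
  near-regular high-frequency character; tonic and LLPR components are
  homogeneous Poisson processes, capturing "lower and more variable"
  firing; a silent pause separates tonic from LLPR. Spontaneous background
  spiking is Poisson over the whole recording. A hard 1.5 ms minimum
  interval is enforced after merging, and spike times are quantised to the
  sample grid so rendered traces and truth tables agree exactly.
* **Waveforms.** Spikes are a stereotyped ~2 ms biphasic template with a
  dominant positive lobe; the DC deflection is a smooth kernel with a fast
  but C¹-continuous drop and a slow recovery, reaching $-SPA$ about 40 ms
  after response onset. The soft (quadratic) start keeps the deflection's
  spectral content below the 150 Hz AC passband, as in real recordings
  where the sensillum potential does not masquerade as spikes.
* **Drift and noise.** Drug effects are linear drifts of generating
  parameters per minute of recording time (matching the linear-fit
  quantification); rates clamp at zero with a flag. Noise is additive
  white Gaussian per channel.

Defaults state the simulated world: 10 phasic spikes at 150 Hz (the burst
then spans ~60 ms, inside the 100 ms phasic window), 20 ms first-spike
latency, 5 mV SPA, 40 Hz tonic rate for 0.5 s, 2 s pause, 1 Hz LLPR,
0.2 Hz spontaneous rate, 1 mV spike amplitude, 0.05 mV noise SD. Tonic and
LLPR rate/duration distributions are **not** quantified by the study this
package emulates; the defaults are the package's own choices of plausible
values for moth trichoid sensilla and are documented here rather than
presented as measurements.

What a green test therefore establishes: that detection, feature
extraction, kinetics fitting and the statistical decision tree recover
known parameters from signals *of this stylised form*. Real recordings
additionally contain colored noise, movement and valve artifacts, slow
electrode drift, and a second (non-pheromone-sensitive) spiking unit per
sensillum — none of which are simulated, and spike sorting between the two
units is explicitly out of scope.

## Numerical choices

* **AC derivation.** The high-pass is implemented in the frequency domain
  on a mirror-extended trace using the squared magnitude response of an
  order-4 Butterworth filter — exactly the transfer function of the
  standard forward–backward (zero-phase) scheme, so spike timing is
  preserved for latency measurements. Edges of the trace ring slightly
  (the mirror junction); measurements avoid the outermost ~0.1 s.
* **Auto threshold.** $4.5\times$ the MAD-based noise SD of the AC trace,
  which is insensitive to the spikes themselves. Polarity is chosen as the
  side whose supra-threshold extrema carry more total amplitude above
  threshold — raw excursion *counts* are misleading when noise splits a
  weak secondary lobe into several shallow crossings. On noise-free traces
  the MAD collapses; if the trace has any excursions the threshold falls
  back to half the largest magnitude, otherwise an error demands an
  explicit threshold. At 4.5σ the false-positive rate is ~3.4·10⁻⁶ per
  sample, i.e. a few noise events per minute at 20 kHz: detection quality
  is therefore assessed in the per-stimulus epoch regime that the feature
  pipeline analyses, where F1 ≥ 0.995 at SNR 8.
* **Response onset.** The manual criterion ("start of the response",
  marked by eye in the source study) is replaced by a reproducible
  surrogate: on a running-median-smoothed DC trace (25 ms window; exact on
  monotone noiseless onsets and immune to spike waveforms), the onset is
  the start of the first sustained (≥ 2 ms) excursion below
  `baseline − max(3·SD, 0.01 mV)` within 200 ms of valve opening, walked
  back to the last sample at the baseline level. Baseline level and SD use
  the median and MAD of the 500 ms pre-stimulus window so that baseline
  spikes cannot bias them. The result is invariant to constant offsets.
* **F6AP convention.** "Average instantaneous frequency of the first six
  spikes" is read literally as the mean of the five reciprocal intervals,
  not $5/(t_6 - t_1)$; the alternative would weight long intervals more.
  Both interpretations scale identically under uniform ISI compression.
* **Sigmoid fit.** Unweighted nonlinear least squares on the cumulative
  histogram (not the PSTH), with a deterministic start: $AP_\max$ at the
  final count, $t_{1/2}$ at the first half-crossing bin centre, $k$ at
  $-(t_{75}-t_{25})/2.2$. Bounded (`port`) iterations keep $k < 0$; a
  bounded quasi-Newton fallback handles the rare failures, and
  non-convergence is reported (`converged = FALSE`), never silently
  replaced. In the step-response limit the fit drives $|k|$ below one bin
  width and places $t_{1/2}$ in the jump bin.
* **Degenerate statistics.** All-identical groups yield $F = 0, p = 1$;
  zero within-group variance with distinct means yields $F = \infty,
  p = 0$; thresholds are relative (10⁻¹² of total sum of squares), so
  "essentially perfect fits" are classified deliberately rather than by
  floating-point accident.

## Scaling of the validation suite

Statistical calibrations that need hundreds of animals (e.g. the null
cohort establishing that 92–98 % of gated slopes are exactly zero at
$\alpha = 0.05$) run on realised ground-truth feature series rather than
rendered 144-million-sample traces; trace-level fidelity is verified
separately on full-rate (20 kHz) recordings and per-stimulus epoch
renders, including end-to-end recovery of a −1 Hz/min F6AP drift through
spike detection, onset detection and slope fitting.

## Known limitations

* The two ORNs of a real sensillum are not separated; the simulator
  renders a single unit and the detector assumes one dominant waveform.
* Colored noise, stimulus artifacts and overlapping spikes are not
  modelled; the detector's merge behaviour under template overlap is
  untested beyond the refractory rule.
* The decision tree's behaviour at very small group sizes is inherently
  fragile: with $n = 3$ per group, Shapiro–Wilk false rejections
  occasionally route clearly parametric data to the rank branch, where the
  Bonferroni-adjusted Dunn test may be unable to reach significance at
  all. This mirrors the behaviour of the usual point-and-click statistics
  packages rather than improving on it.
* Reading the deposited per-animal tables is implemented against their
  published layouts (slope sheet and per-parameter raw sheets, with
  literal `"NaN"` for unextractable trials), but the tables themselves are
  not redistributable with the package; the corresponding reproduction
  test stays red unless they are dropped into
  `inst/extdata/extended-data/`.

## A minimal worked example

```{r example, eval = FALSE}
gt <- ground_truth_params(noise_sd = 0.05)
design <- cohort_design(stimulus_interval = 15,
                        recording_duration = 46 / 60, first_stimulus = 1)
sim <- generate_recording(gt, design, seed = 1)
features <- extract_features(sim$recording)
kin <- fit_recording_kinetics(sim$recording)
features
kin
```
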