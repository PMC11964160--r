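# ssrquant

Quantification of pheromone responses from insect single-sensillum
tip-recordings.

## What problem this solves

Extracellular tip-recordings of moth pheromone-sensitive olfactory
receptor neurons (ORNs) produce two channels: an unfiltered **DC** trace
carrying the slow transepithelial (sensillum) potential and a 150 Hz
high-pass **AC** trace in which spikes stand out. The ORN's answer to a
brief pheromone pulse has three components with distinct kinetics — a
phasic burst (~10 near-regular spikes, < 100 ms), a slower tonic
component, and a late long-lasting response (LLPR) of sparse spiking over
minutes — and each component must be quantified separately because they
encode different stimulus attributes.

`ssrquant` implements the full analysis chain for such experiments, for
electrophysiologists who repeat a 50 ms stimulus every 5 minutes over
two-hour recordings while a drug diffuses into the sensillum:

1. **Per-stimulus response parameters**: first-spike latency relative to
   the DC response onset; phasic frequency `F6AP` (mean of the reciprocal
   inter-spike intervals of the first six spikes, missing if fewer than
   six occur within 1 s); sensillum potential amplitude `SPA` (magnitude
   of the maximal negative DC deflection from the pre-stimulus baseline);
   spike counts in an early window (1 s, or 100 ms for paired toxin
   protocols); and the LLPR count from 5 s after a stimulus to the next
   one (a 295 s window at 5 min spacing).
2. **Response kinetics**: spikes of the first second, pooled over all
   stimulations of an animal in 10 ms bins; the cumulative histogram is
   fitted with `AP(t) = AP_max / (1 + exp((t - t_half)/k))` with `k < 0`
   (steeper responses have `k` closer to zero).
3. **Drug-effect statistics**: each parameter is reduced to a per-animal
   regression slope over recording time; slopes not significantly
   different from zero (two-sided *t* test, α = 0.05) are *gated to
   exactly zero*; gated slopes are compared across condition × zeitgeber
   time groups with a fixed decision tree (Shapiro–Wilk + Levene → one-way
   ANOVA/Tukey, log-transform rescue, or Kruskal–Wallis/Dunn), and paired
   toxin designs use one-way repeated-measures ANOVA.
4. **qPCR**: relative expression by `2^-ΔΔCt` with two reference genes and
   comparison across zeitgeber times.
5. **Synthetic ground truth**: a generator for dual-channel recordings and
   qPCR tables with known parameters (gamma-renewal phasic burst, Poisson
   tonic/LLPR, smooth DC deflection, linear parameter drift, white noise)
   so every stage is validated end-to-end without any external data.

## Worked example

```r
library(ssrquant)
gt <- ground_truth_params(noise_sd = 0.05)          # 1 mV spikes, SNR 20
design <- cohort_design(stimulus_interval = 15,
                        recording_duration = 46 / 60, first_stimulus = 1)
sim <- generate_recording(gt, design, seed = 1)     # 46 s, 3 stimuli
features <- extract_features(sim$recording)
features
#>   experiment_id stimulation_time_min latency_ms f6ap_hz spa_mv n_aps_early n_aps_llpr
#> 1           rec              0.01667      20.60   155.0  5.023          25         11
#> 2           rec              0.26667      20.55   155.2  5.016          26         13
#> 3           rec              0.51667      20.10   159.0  5.009          25         18
fit_recording_kinetics(sim$recording)
#> <sigmoid_fit> AP_max = 77.74, t_1/2 = 0.2061 s, k = -0.13998 s (rss 1.45e+03, converged)
fit_parameter_slope(features$stimulation_time_min, features$f6ap_hz)
#>   experiment_id parameter slope intercept p_slope gated_slope n_points
#> 1          <NA>      <NA>  7.89       154   0.311           0        3
```

Reading the output: the simulator was configured with a 20 ms true
latency, 150 Hz phasic rate and a 5 mV sensillum potential; the extracted
latency (20.1–20.6 ms), `F6AP` (155–159 Hz, upward-biased by ~2 % because
the mean reciprocal of jittered intervals exceeds the rate) and `SPA`
(5.01–5.02 mV) recover them. The kinetics fit pools all three
stimulations: ~78 spikes accumulate in the first second with the sigmoid
midpoint 206 ms after response onset. The slope fit shows the gating rule:
a 7.9 Hz/min trend over three stimulations is not significant (p = 0.31),
so the gated slope — the quantity that would enter a group comparison — is
exactly 0.

A command-line front end covering the same pipeline
(`simulate`, `extract`, `fit-kinetics`, `slopes`, `compare`, `qpcr`,
`convert`, `inspect`) is installed at `inst/cli/ssrquant`; see
`?ssr_cli`.

## Layout

```
R/                  synth, sigio, features, kinetics, stats, qpcr, cli
tests/testthat/     unit + property tests and test-acceptance.R
scripts/acceptance.R
vignettes/ssrquant-methods.Rmd   # methods, design choices, limitations
```
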