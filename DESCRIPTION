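Package: ssrquant
Title: Quantification of Pheromone Responses from Insect Single-Sensillum Recordings
Version: 0.1.0
Authors@R:
    person("ssrquant", "developers", email = "ssrquant@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for extracellular tip-recordings of insect
    pheromone-sensitive olfactory receptor neurons. Detects spikes on the
    high-pass filtered (AC) trace, locates the onset of the negative
    sensillum-potential deflection on the unfiltered (DC) trace, and
    quantifies each stimulation by five response parameters: first-spike
    latency, phasic instantaneous frequency of the first six spikes (F6AP),
    sensillum potential amplitude (SPA), early spike count, and the late
    long-lasting response (LLPR) count. Response kinetics are summarised by
    a sigmoid fitted to the cumulative 10-ms peri-stimulus time histogram.
    Drug effects over repeated stimulation are quantified as per-animal
    regression slopes with significance gating, compared across groups with
    a normality/equal-variance driven decision tree (one-way ANOVA,
    repeated-measures ANOVA, or Kruskal-Wallis with Tukey or Dunn post hoc
    tests). Includes qPCR relative expression by the 2^-ddCt method with
    dual reference genes, and a synthetic-recording generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rhdf5,
    readxl,
    optparse
Config/testthat/edition: 3
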