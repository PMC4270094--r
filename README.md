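# ripplephase

Analysis of single-cell discharges during hippocampal network oscillations.

Hippocampal interneurons time their action potentials to ongoing field
oscillations — theta (5–10 Hz), gamma (25–90 Hz) and epsilon (90–130 Hz)
during running, and sharp-wave ripples (90–200 Hz) during rest — and the
phase, strength and rate of that coupling is what distinguishes
functionally different cell classes (basket, axo-axonic, bistratified) and
their sub-classes. `ripplephase` implements the full analysis chain for
paired LFP + spike-train recordings, for electrophysiologists who need
these statistics reproducibly and for anyone validating such a pipeline
against ground truth:

* **Signal processing** — zero-phase Butterworth band filtering, anti-aliased
  downsampling, analytic-signal envelopes, a 96-band (4 Hz wide, 2 Hz step)
  z-scored envelope-power filterbank, and trigger-aligned time–frequency
  averaging.
* **Event detection** — run/rest segmentation with the >20 s / >200 s episode
  minimums, and dual-threshold ripple detection: envelope excursions
  reaching 5 SD, extended to their 2 SD crossings.
* **Phase coupling** — trough-anchored phase (0° = trough, 180° = peak), mean
  resultant vector `r = |Σ e^{iθ_j}|/n`, Rayleigh uniformity test,
  Watson–Williams comparison of mean directions, phase histograms.
* **Rate dynamics** — state/event firing rates, Monte-Carlo randomization
  tests (spike-shuffle or event-shuffle surrogates), ripple participation,
  early-spike fraction, doublet detection, 40/20/40 peri-event histograms.
* **Core frequency** — per-event intra-ripple frequency by zero-crossing,
  peak-interval and complex Morlet (fb = 5, fc = 1) wavelet methods, and
  spike-conditioned comparison of event frequencies.
* **Synthetic generator** — 1/f background, planted rhythms with
  cross-frequency coupling, Hann-enveloped ripple events, von Mises
  phase-locked spike trains with event gains and doublets — all with
  serializable ground truth, so every stage above is testable without any
  recorded data.

## Worked example

```r
library(ripplephase)

## a 6-cell synthetic cohort: 2 basket cells locked at 55 deg in the ripple
## cycle, 2 bistratified cells at 126 deg, 2 axo-axonic cells
res <- runPipeline(demoConfigPath(), outDir = "demo_out")

subset(res$summary, level == "cell_class",
       select = c(group, n, event_phase, event_r, rate_in, participation))
#>     group n event_phase   event_r   rate_in participation
#> 1     AAC 2   128.90083 0.5824718  13.29787        0.4375
#> 2      BC 2    40.97571 0.4383483 113.03191        0.9750
#> 3 Bistrat 2   127.91474 0.7084456  35.61930        0.7875

res$comparisons[1, ]
#>                  comparison            test statistic           p   n
#> 1 event_phase_BC_vs_Bistrat watson_williams  151.2992 0.006544606 2/2
```

The summary says: during detected ripples the basket cells fired at a mean
phase of 41° (early ascending limb) on virtually every event, while the
bistratified cells fired at 128° with lower in-event rates, and the
Watson–Williams test separates the two class mean directions at p < 0.01 —
the planted ordering (BC before Bistrat within the ripple cycle),
recovered by the full detection → phase → statistics chain. `demo_out/`
receives the per-cell results, detected events with core frequencies,
peri-event histograms, cohort summary, comparisons and a run log;
re-running with the same configuration reproduces every file byte for
byte.

A command-line wrapper is installed as `exec/ripplephase`:

```sh
Rscript exec/ripplephase all --config inst/extdata/demo_config.yaml --out demo_out
```

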