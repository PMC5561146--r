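---
title: "Analysing axonal conduction in microchannel-coupled MEAs"
author: "AxonVelocity authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing axonal conduction in microchannel-coupled MEAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AxonVelocity)
```

## The experimental system

Extracellular signals from thin axonal branches are ordinarily too small to
record reliably. Confining axons in 5 µm-high PDMS microchannels aligned
over MEA electrodes raises the sealing resistance around the axon and
amplifies its extracellular potential, so that the same action potential can
be followed across several electrodes as it travels down the channel. The
device this package models couples a 60-electrode MEA to a PDMS insert with
**8 interconnected reservoir modules** (somal compartments, two recording
electrodes each, up to 200 cells per module, 1,600 per device) each feeding
one **1 mm microchannel** instrumented with **5 electrodes at 200 µm
pitch**. Because an action potential entering the channel passes the five
electrodes in order, the inter-electrode arrival delays give its conduction
velocity:

$$ v \,[\mathrm{m/s}] = \frac{\Delta x\,[\mu m]}{\Delta t\,[s] \times 10^6} $$

`buildDefaultLayout()` encodes this geometry (channel electrode positions
100, 300, 500, 700, 900 µm from the entrance; channel index 0 is the
reservoir-proximal, i.e. stimulation, site).

## The analysis pipeline

The package implements the complete chain from raw voltage to inferential
statistics, each stage independently usable:

1. **Detection** (`highpassFilter`, `estimateNoise`, `detectSpikes`,
   `detectRecording`). Traces are high-pass filtered with a second-order
   Bessel filter (cutoff 200 Hz, matching the acquisition chain), and
   spikes are detected at a negative threshold of −4.5 times the noise
   s.d., one event per dead-time window, timestamped at the trough.
2. **Bursts** (`detectBursts`, `burstFeatures`). MaxInterval-style
   criteria: 20 ms maximum ISI to open a burst, 10 ms maximum ISI to
   extend it, 10 ms minimum inter-burst interval, 20 ms minimum duration,
   at least 4 spikes. Eight features per train feed the correlation
   analysis.
3. **Propagation** (`matchPropagatingSpikes`, `propagationEvents`,
   `channelVelocitySummary`, `proximalDistalVelocities`,
   `velocityHistogram`). Spikes that traverse the whole channel with a
   pairwise delay of up to 2 ms per 200 µm pair are chained into
   propagation events; the 2 ms bound implies the 0.1 m/s velocity floor.
   Velocities are summarized per channel, split into proximal/distal
   halves at 500 µm, and binned into the 11 domains covering 0.1–1.2 m/s.
4. **Stimulation** (`alignPeristimulus`, `windowRates`,
   `responseFidelity`, `evokedVelocity`). Trials of 1 Hz biphasic pulses
   are aligned to pulse onsets; the first 5 ms are blanked as artifact;
   rates are computed in configurable post-stimulus windows, response
   fidelity as the percentage of trials with at least one spike per 10 ms
   bin over 5–35 ms, and evoked velocities from 4-electrode chains
   (3 pairs distal to the stimulation site), classified into direct
   (5–35 ms) and polysynaptic (35–950 ms) windows.
5. **Statistics** (`normalizeSeries`, `pearsonCorrelation`,
   `activityVelocityTable`, `compareConditions`). Module-by-day feature
   and velocity observations are correlated either pooled across all
   recording days or for each day separately; condition contrasts
   (e.g. GABA-A blockade) are paired t tests. Normalization divides each
   module's series by its own study-long mean, removing between-module
   level differences.
6. **Orchestration** (`runPipeline`). YAML-configured stage execution
   with an MD5 manifest; reruns with the same seed reproduce identical
   hashes.

## The synthetic device

No public recordings exist for this device class, so the package carries a
generative model of it (`simulationConfig`, `simulateSpontaneous`,
`simulateStimulationSession`, `renderRawTraces`) whose hidden parameters
are returned as ground truth. Every analysis stage is validated by
parameter recovery against this simulator.

Each microchannel carries a configurable number of axons. An axon emits a
superposition of Poisson tonic spikes and Poisson-onset bursts
(intra-burst ISI 7 ± 1 ms, at least 4 spikes — deliberately inside the
MaxInterval acceptance region so burst recovery is testable), with a 2 ms
refractory dead time. Each emitted spike arrives at channel electrode $k$
at

$$ t_k = t_{\mathrm{emit}} + \frac{x_k}{v} + \varepsilon_k,\qquad
   \varepsilon_k \sim \mathcal N(0, \sigma_{\mathrm{jitter}}^2), $$

with jitter redrawn where it would invert arrival order (the matcher
assumes monotone arrival), and is observed independently with probability
`detectionProb`. Reservoir electrodes see the emission trains of a random
fraction of axons, which produces the reservoir–channel activity coupling
seen in such devices. Default velocities are drawn uniformly from
0.3–0.8 m/s, the bulk of observed conduction speeds; amplitudes span
40–1,000 µV and rendered noise gives signal-to-noise ratios in the
observed 2–35 band.

Stimulation sessions place `nTrials` (default 180) biphasic pulses at 1 Hz
on the proximal channel electrode. Per trial, a direct response chain is
inserted with probability `pDirect` at a latency uniform in 5–15 ms and
propagated down the four distal electrodes at the evoked velocity;
polysynaptic chains appear in late windows with probability `pLate`. The
amplitude-dependent defaults (250/500/1000 mV → direct 0.75/0.90/0.95,
late 0.05/0.25/0.35) are calibration knobs chosen once to emulate the
qualitative amplitude dependence of evoked responses — stronger pulses
respond more reliably and recruit polysynaptic activity — and are not
quantitative claims.

What the simulator does **not** model: biophysical cable properties, axon
growth and age-dependent velocity change mechanisms, spike waveform
diversity beyond one biphasic template per electrode, electrode drift, and
non-Gaussian noise. Passing recovery tests therefore show that the
analysis code measures what the generative model produces; they do not by
themselves validate the analysis against real tissue.

```{r example}
cfg <- simulationConfig(durationS = 60, nAxonsPerChannel = 1,
                        trueVelocityMS = 0.5, jitterMs = 0.05,
                        detectionProb = 1, seed = 7)
sim <- simulateSpontaneous(cfg, buildDefaultLayout(nModules = 1))
ev <- propagationEvents(sim$spikes, velocityMethod = "harmonic")
channelVelocitySummary(ev)
```

## Numerical and design choices

**Bessel high-pass.** The order-2 Bessel polynomial is $s^2 + 3s + 3$;
its normalized −3 dB frequency is the positive root of
$\omega^4 + 3\omega^2 - 9 = 0$ ($\omega \approx 1.36165$). The high-pass
prototype $H(s) = s^2/(s^2 + a_1 s + a_0)$ with $a_1 = \omega_N \Omega_c$,
$a_0 = a_1^2/3$ is discretized with a bilinear transform prewarped at the
cutoff. The filter is applied causally (forward-only) by default because
that matches an online acquisition chain and because zero-phase filtering
would shift absolute spike latencies that feed the velocity and
peri-stimulus computations; `zeroPhase = TRUE` is available for
applications where phase does not matter.

**Noise scale.** "Noise s.d." is estimated as the median absolute
deviation of the filtered trace scaled for Gaussian consistency
(MAD/0.6745). Unlike the raw s.d., this is insensitive to the sparse,
large spikes riding on the noise floor, so the −4.5σ threshold tracks the
noise and not the signal. Degenerate all-zero traces return σ = 0 with a
warning rather than an error.

**Spike matching.** A propagation event requires a spike on *every*
channel electrode with each pairwise delay in [one sample period, 2 ms].
The lower bound exists because a zero delay implies infinite velocity; one
sample at 25 kHz (0.04 ms) is the smallest resolvable delay. Matching is
anterograde only and injective (a spike belongs to at most one event).
Candidate partners are taken earliest-first; when that choice would strand
a later entrance spike whose only partner was consumed, the earlier chain
is re-routed to an alternative partner (a unit-capacity augmenting path).
Plain earliest-first greedy without this repair is suboptimal on rare
pathological instances (about 1 in 1,000 random interleaved-chain
instances); with the repair the matcher provably attains the maximum
number of disjoint complete chains while remaining deterministic, which is
what the brute-force equivalence suite checks.

**Per-spike velocity.** Two summaries of a chain's four pairwise
velocities are provided. `"arithmetic"` (the default) averages the four
$\Delta x/\Delta t_i$ values, following the conventional per-pair
averaging rule. Because $1/\Delta t$ is convex, this estimator is
Jensen-biased upward under timing jitter — at 0.8 m/s and 0.05 ms jitter
the bias reaches ~10%. `"harmonic"` (total path length over total transit
time) has bias of order $(\sigma/\Delta t_{\mathrm{total}})^2 \lesssim
0.5\%$ under the same conditions, and is therefore the estimator used in
the package's own parameter-recovery validation. For descriptive analyses
of real recordings the default remains the conventional arithmetic rule;
the choice matters only when jitter is an appreciable fraction of the
pairwise delay.

**Burst criteria interplay.** Candidate bursts are merged (gap <
minimum IBI) *before* the duration and spike-count filters, since a
minimum inter-burst interval is meaningless after filtering. With the
default criteria (extension ISI 10 ms = minimum IBI) merging can never
trigger, because a candidate only closes on a gap exceeding the extension
ISI. Merging becomes active — and the otherwise-intuitive monotonicity of
burst content in the extension ISI can fail — only when the extension ISI
is set below the minimum IBI. Burst duration is last-minus-first spike
time, the only definition computable from timestamps, and a burst cannot
open on a train's final spike (an ISI is needed to open one).

**Peri-stimulus windows.** The analysis windows default to
{5–15, 15–35, 35–100, 100–300, 300–950} ms, a superset covering the
direct (5–35 ms) and polysynaptic (35–950 ms) epochs and the decay range
examined in evoked-rate comparisons; fidelity uses the three 10 ms bins
partitioning 5–35 ms. Artifact handling is timestamp blanking (discard
< 5 ms, counted separately), not waveform subtraction. Evoked matching
requires completeness over the **four** electrodes distal to the
stimulation site only, because the first electrode is the stimulating one.

**Missing values.** "No events" is never coerced to zero: empty channels
yield `NA` summaries flagged by `n = 0`, and missing feature values
propagate as missing through the correlation and comparison tables.
Pooled correlations weight each module-day equally; an event-count
weighted variant was considered and not adopted (unweighted matches the
one-point-per-module-day convention), but the velocity tables expose the
counts needed to weight externally.

**Confound dissociation.** The package's key inferential pattern is that
culture age drives both burst features and conduction velocity, producing
strong pooled feature–velocity correlations that vanish when each
recording day is analysed separately, and that pharmacological
disinhibition (3-fold activity increase at fixed age) leaves velocity
unchanged. `simulateAgingStudy()` + `simulateDisinhibition()` generate
feature-level data with exactly this structure (independent day-to-day
fluctuations, shared age trend, multiplicative module effects), and the
test suite verifies that `activityVelocityTable()` reproduces the
dissociation over 20 seeded replicates. Normalization to each module's
study-long mean is applied before correlating, which removes the module
random effect that would otherwise leak a spurious within-day
correlation.

## Problem sizes used in validation

The shipped validation suite chooses sizes that make the statistics
decisive: 1,000 random instances for each brute-force equivalence
(burst detector and chain matcher, the latter capped at 12 spikes per
electrode so exhaustive search is exact), 10 seeds × 60 s recordings per
velocity recovery point, 50 seeds × 180 trials per fidelity recovery
point (tested against the 99% binomial CI of the configured probability),
and 20 seeded replicates of the aging-study dissociation. All bands
(±5% velocity recovery, 99% CI fidelity) were fixed from the sampling
theory above before the suites were run.

## Known limitations

* Single-unit identity is not tracked: events in one channel may come
  from different axons, and no waveform clustering is attempted.
* Retrograde propagation is out of scope; the matcher is anterograde.
* The arithmetic velocity default inherits the jitter bias discussed
  above; use `"harmonic"` when jitter is non-negligible.
* The stimulation simulator inserts idealized response chains; it does
  not model stimulation-induced plasticity or amplitude-dependent
  latency shifts.
* Repeated-measures ANOVA/post-hoc families are intentionally delegated
  to standard routines outside this package; only normalization, Pearson
  correlation and paired comparisons are first-class here.
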