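---
title: "Quantifying inferior-colliculus responses to tones, speech, and noise-burst trains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying inferior-colliculus responses to tones, speech, and noise-burst trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icspike)
```

## Overview

`icspike` analyses extracellular multi-unit recordings from the auditory
midbrain (inferior colliculus, IC) collected under a standard stimulus
battery:

* a **tone grid** of 1,296 frequency x intensity combinations (1-32 kHz in
  0.0625-octave steps x 0-75 dB SPL in 5-dB steps, one sweep per site), used
  to map the frequency receptive field;
* **15 consonant-vowel-consonant speech presentations** (11 words at 60 dB;
  'dad' and 'shad' additionally at 45 and 75 dB; 20 repeats each), used to
  quantify driven rates, latencies and single-trial neural discrimination;
* a **noise-burst train** (six 25-ms bursts at 10 Hz, 20 repeats), used to
  quantify temporal following and phase locking.

The scientific setting is a two-group design: a control group (`saline`)
and a treated group (`vpa`, a prenatal valproic-acid rodent model of autism
spectrum disorder).  The phenomenon the pipeline is built to resolve is a
*dissociation*: speech-evoked responses are weakened in the treated group
while tone and noise-train responses are statistically indistinguishable
between groups.

Because the original recordings are not publicly archived, the package
ships a seeded synthetic-cohort generator with exactly this structure, and
every analysis stage is validated against it.

## Response metrics

All spike times are stimulus-onset-relative (ms).  For speech sounds the
driven response is counted over three fixed windows: the **entire sound**
`[0, 400)` ms, the **consonant onset** `[0, 40)` ms, and the **vowel
portion** `[140, 440)` ms.  The vowel window deliberately extends 40 ms
past the 400-ms "entire sound" window; both windows are implemented exactly
as specified rather than reconciled, and the two definitions coexist
without interaction because each metric is reported separately.

*Driven spikes* per presentation are baseline-corrected: the mean spike
count per trial in the window minus the count expected from the
spontaneous rate over the same duration.  The spontaneous rate comes from
the pooled pre-stimulus baseline `[-100, 0)` ms.  The recorded window
starts 100 ms before onset — a conventional choice that yields at least
2,000 ms of baseline per speech stimulus at 20 repeats; correction can be
disabled (`correction = "none"`), and group contrasts are invariant to the
choice whenever the groups share spontaneous statistics.  Driven values may
be slightly negative when a site's evoked count dips below its baseline
expectation; they are left as computed.

*Onset latency* is defined per trial as the first spike in `(0, 100]` ms
and summarised across trials by the median (mean and pooled-first-spike
summaries are available); the median was chosen for robustness to
spontaneous outliers, since a single early spontaneous spike otherwise
dominates.  *Peak latency* is the argmax of the 1-ms PSTH after a centred
5-point moving average (edge-truncated); the unsmoothed argmax is tie-prone
at realistic counts.  Ties resolve to the earliest bin.

## Receptive-field extraction

The tone sweep has a single repeat per condition, so per-cell statistics
are very noisy and smoothing-first is mandatory.  The adopted procedure:

1. count evoked spikes in `[0, 50)` ms per condition into an 81 x 16 matrix;
2. smooth with an edge-truncated 3 x 3 box filter;
3. mark cells responsive where the smoothed count exceeds
   `spont + 2 * sqrt(spont + 0.25)` — a variance-stabilised Poisson
   criterion whose `+0.25` term keeps the bound strictly positive at zero
   spontaneous rate;
4. keep the largest 4-connected responsive component, requiring at least 5
   cells;
5. read off: threshold (lowest level in the component), CF (frequency of
   the responsive cell at threshold; frequency ties take the median index,
   lower of two middles), and BW10/BW40 (octave span of component cells at
   threshold + 10/40 dB, missing when that level exceeds the 75-dB grid
   ceiling).

The criterion multiplier, minimum component size and evoked window are
exposed as arguments.  Two systematic effects of this procedure are worth
knowing.  The box filter dilates a sharp responsive region by about one
grid step, so thresholds read ~5 dB low and bandwidths ~0.06-0.12 octaves
wide relative to a noiseless geometric construction; parameter-recovery
tests therefore assert CF within ±0.25 octave and threshold within ±5 dB
(one grid step), which clean simulations meet for ≥90% of sites.  Sites
whose CF sits within ~0.15 octave of the 1- or 32-kHz grid edge can lose
part of their responsive region to truncation and account for most
recovery failures.

Pooled-PSTH tone latencies use the component conditions only: onset is the
first post-onset 1-ms bin whose smoothed rate exceeds baseline mean + 3 SD,
the peak is the subsequent argmax, and end-of-peak is the first bin after
the peak falling below half the peak elevation.  The moving average
advances the detected onset by ~1-2 ms; this bias is constant across
groups and therefore cancels in contrasts.

For classifier reporting, sites split into a low-CF band (1-8 kHz,
inclusive at 8 kHz) and a high-CF band (above 8 kHz); the boundary is fixed
at 8 kHz inclusive-low because the conventional "1-8 / 9-32 kHz" phrasing
leaves CFs between 8 and 9 kHz unassigned.

## Temporal coding

Noise-burst-train responses are summarised by the driven rate per burst
(baseline-corrected count over `[0, 600)` ms divided by 6), the first-peak
latency (argmax of the smoothed 1-ms PSTH in `[0, 100)` ms; flat smoothed
maxima resolve to the bin with the highest raw rate), and **vector
strength** at the 10-Hz train rate,

$$VS = \frac{1}{n}\sqrt{\Big(\sum_i \cos\theta_i\Big)^2 +
  \Big(\sum_i \sin\theta_i\Big)^2},\qquad \theta_i = 2\pi f t_i/1000,$$

computed over all spikes in `[0, 600)` ms.  Spontaneous spikes are included
(no exclusion rule is imposed); a `driven_only` flag restricts to
post-burst windows.  Under Gaussian spike-time jitter with SD $\sigma$ the
expected VS follows the wrapped-Gaussian form
$\exp(-(2\pi f\sigma)^2/2)$, which the simulator reproduces within ±0.02
and the tests assert for $\sigma \in \{2, 5, 10\}$ ms.

## Neural discrimination

The classifier is a leave-one-out nearest-neighbour template matcher on
single-trial binned spike counts.  Consonant discrimination uses the 40-ms
onset at 1-ms resolution (40 bins); vowel discrimination uses a single
300-ms bin over `[140, 440)` ms.  For each held-out trial, the template of
its own sound is the per-bin mean of the remaining 19 repeats, while the
competing sound's template uses all 20 — the literal reading of a
"remaining 19 repeats" template rule; a symmetric 19/19 variant is
available and the difference is negligible at n = 20.  Assignment is by
smaller Euclidean distance; exact ties are broken by a seeded fair coin,
which keeps the accuracy lattice at exact multiples of 2.5% (40
classifications per pair at full repeats) and avoids the bias of
deterministic tie rules.  Euclidean distance is computed on counts; with a
common bin width, distances on counts and on rates are proportional, so
the assignment is identical.

The default pair sets are the within-manner consonant pairs — stops
(d/g/t: 3 pairs), affricates (ch/j: 1), fricatives (f/h/s/sh: 6) — and the
three vowel pairs (dad/deed/dood), all at the 60-dB presentations; a flag
switches to every consonant-differing pair (52).

## Group statistics

Each site-level metric passes a **Lilliefors normality gate** (delegated to
`nortest::lillie.test`) per group at alpha = 0.05; only when both groups
test normal does the comparison take the parametric branch (Welch's
t-test, labelled as such).  Otherwise the two-sided **Mann-Whitney
rank-sum** test is used: exact null distribution when there are no ties
and both groups have n < 50, else the normal approximation with tie and
continuity corrections.  Group medians are reported with **95% bootstrap
percentile confidence intervals** (50,000 resamples by default).  Raw
p-values are reported without multiplicity correction, matching the
presentation conventions of this literature.  Sites are nested within
rats and the site-level rank-sum test does not model that dependency; the
appropriate mixed-model analysis (site nested in rat as a random factor)
is deliberately delegated to established routines (e.g. `lme4`) rather
than re-implemented, and conclusions drawn from site-level tests on real
data should be checked against it.

## The synthetic cohort generator

`simulate_cohort()` draws a site table (`sample_cohort()`) and simulates
every stimulus family per site with inhomogeneous Poisson spike trains.
Defaults encode the reference study conditions: 5 rats x 20 sites per
group (100 sites/group, a reduced-scale counterpart of the several-hundred
site cohorts such data sets contain), 20 repeats per speech/noise
stimulus, one tone sweep, and a treated-group effect confined to speech:
a multiplicative rate gain with mean 0.7 (site SD 0.10, rat-level random
effect SD 0.05) and a -1 ms onset-latency offset (the treated group
responding slightly *earlier*, matching the direction reported for this
model).  Tone and noise-train parameters are drawn from identical
distributions in both groups, mirroring the dissociation under study.

Site parameters are drawn near published midbrain multi-unit values: CF
log-uniform on 1-32 kHz, threshold ~N(20, 8) dB, BW10 ~N(1.5, 0.3)
octaves with BW40 = BW10 plus a positive increment, spontaneous rate
Gamma with mean 25 spikes/s, onset latency ~N(8, 1) ms, peak driven rate
~N(200, 40) spikes/s.

* **Tones**: the frequency-dependent threshold rises from the CF threshold
  as a power law of octave distance calibrated so the responsive region
  spans exactly BW10 at threshold + 10 dB and BW40 at threshold + 40 dB
  (the quadratic special case corresponds to BW40 = 2 BW10); above
  threshold the rate is a sigmoid of level saturating at `rmax_hz`.
  Driven spikes follow an alpha-function (Gamma shape-2) time course with
  a 5-ms time constant, giving unambiguous peak latencies.
* **Speech**: an onset transient confined to 0-40 ms (alpha kernel,
  3-ms time constant, at the site's onset latency plus a per-consonant
  shift of 0-6 ms) plus a sustained vowel component uniform over
  140-440 ms.  Onset amplitude scales with consonant-class salience
  (stops > affricates > fricatives), a per-consonant amplitude factor, and
  presentation level; the vowel component scales with a per-vowel gain and
  level.  Both components are multiplied by the site's `speech_gain` and a
  CF-dependent spectral weight (high-CF sites emphasise consonant onsets,
  low-CF sites the vowel) — a modelling device that gives the CF-band
  classifier analyses something real to resolve, not a claim about IC
  physiology.
* **Noise trains**: each burst contributes Poisson-count spikes at burst
  onset + onset latency + Gaussian jitter (SD 4 ms by default).

Everything is deterministic under the master seed (byte-identical event
tables), and spike times are quantised to 0.01 ms — below any analysis
bin — so datasets round-trip byte-stably through CSV.

What the generator does *not* emulate: realistic spectrotemporal
modulation of the actual recorded words, rate adaptation across repeats,
correlated noise between nearby sites, or non-Poisson spike-count
dispersion.  Passing tests therefore demonstrate that the analysis code
correctly measures the quantities it defines, and that the pipeline
resolves effects of the designed size and direction — not that real IC
data will show them.

## Problem sizes and numerical choices

The test suite validates calibration at sizes chosen to make sampling
error negligible relative to each tolerance: 50 clean sites for
receptive-field recovery; 200 stimulus-blind site simulations for the
classifier chance level (50 ± 2%); 500 replicates for bootstrap-CI
coverage (95 ± 3%, 2,000 resamples per interval); 200 matched mini-cohorts
for type-I error of the group pipeline (accepted band 2-10% at
alpha = 0.05); and 100 independent full-scale cohorts (100 sites/group)
for the direction-of-effect pattern.  For that last property each
component of the pattern — speech deficit significant and in the right
direction, tone contrast non-significant, noise-train contrast
non-significant, high-CF stop-pair accuracy lower in the treated group —
is required to hold in at least 90% of replicates.  The components are
assessed individually because a conjunction of several independent
5%-level null checks fails ~5% of the time per null metric by type-I
arithmetic alone, which would make a joint ≥90% requirement impossible to
meet regardless of implementation quality.

Other numerical conventions: PSTH bins are half-open `[t, t + bin)`;
moving averages are edge-truncated rather than NA-padded; component
labelling scans deterministically in column-major order so ties between
equally sized components are stable; empty spike lists yield `NA` vector
strength (logged) rather than an error; and a dataset stores only events,
so a trailing trial with zero spikes is indistinguishable from a missing
repeat — the validator reports such cases as warnings, not errors.

## Known limitations

* Event-only storage cannot represent "present but silent" trials
  explicitly (see above).
* The rank-sum tests treat sites as independent; rat-level clustering is
  acknowledged but not modelled on the nonparametric path.
* Receptive-field estimates carry the small systematic biases described
  above (threshold ~one grid step low; onset latency ~1-2 ms early);
  these cancel in between-group contrasts but matter if absolute values
  are compared against other studies.
* The classifier's template asymmetry (19 vs 20 trials) induces a
  negligible (<1%) bias at chance; the symmetric variant is provided for
  sensitivity analyses.
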