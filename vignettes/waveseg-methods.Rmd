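---
title: "Methods: retinal wave analysis and eye-specific segregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retinal wave analysis and eye-specific segregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waveseg)
```

This vignette documents the models behind `waveseg`, the parameters that
matter, the numerical and design choices made where the procedures are
underdetermined, and what the synthetic generators do and do not emulate.

## 1. The spike-train pipeline

### Inputs and preprocessing

The pipeline starts from sorted units: one spike-timestamp vector per
unit, each assigned to an electrode on a rectangular grid (by default 8×8,
200 µm pitch, 10-minute recordings). Spike sorting itself is upstream and
out of scope.

Two cleaning rules run first:

* **Artifact rejection** (`reject_artifacts()`). Mechanical disturbances
  hit the whole array at once, so spikes co-occurring within a 1 ms window
  on ≥ 70% of channels are discarded. The scan is greedy over the
  channel-merged, time-sorted spike list: a window `[t, t + 1 ms]` opens at
  every spike not already consumed by an artifact group, and a qualifying
  group is removed wholesale. This placement rule is deterministic and
  order-independent given sorted input. The 70% criterion counts
  *channels bearing at least one unit*, not grid positions: an electrode
  with no sorted unit cannot report an artifact. Because the unit registry
  (not spike presence) fixes the denominator, the operation is idempotent.
* **Unit validity** (`flag_invalid_units()`). Units with a mean rate
  strictly below 0.25 Hz over the whole recording indicate poor
  electrode–retina contact, and units on the ground channel are
  uninterpretable; both are excluded from all downstream stages. The
  comparison is strict: a unit at exactly 0.25 Hz (150 spikes in 600 s) is
  kept.

### Burst detection

A spike run of $n$ spikes spanning $T$ seconds from a unit of mean rate
$r$ (computed over the full cleaned recording) has Poisson surprise
$S = -\log_{10} P(X \ge n)$ with $X \sim \mathrm{Poisson}(rT)$. Runs with
$S \ge 4$ — tail probability below $10^{-4}$ — are bursts. The base of the
logarithm is fixed by that correspondence ($S = 4 \Leftrightarrow
P = 10^{-4}$); a natural-log convention would pair 4 with $e^{-4} \approx
0.018$ and contradict it.

The search (`detect_bursts()`) is a deterministic hill climb in the
Legéndy–Salcman tradition: candidate runs are seeded wherever consecutive
inter-spike intervals drop below half the unit's mean ISI, extended
forward and then backward one spike at a time while the surprise
increases, emitted at $S \ge 4$, and merged where extents overlap (the
higher-surprise extent wins, which also guarantees non-overlapping
output). A hill climb can miss a qualifying run that only a non-monotone
extension would reach, so the property the tests enforce is one-sided:
the detector never fires on a train where exhaustive enumeration finds no
qualifying run, and detection frequency on sparse Poisson trains never
exceeds the enumeration oracle's. Analyses downstream use bursts far
above threshold, where the search detail is immaterial. Burst start and
end are the first and last spike times (no padding), matching how burst
durations are reported.

Kept bursts must satisfy three exclusions (`filter_bursts()`): duration
within [0.75 s, 15 s], start ≥ 7.5 s, and end ≤ duration − 7.5 s. The 7.5 s
edge margin is definitionally half the maximum burst duration, ensuring a
burst interrupted by starting or stopping the recording can never
masquerade as a complete one. Spikes of excluded bursts are pooled and
still count toward every rate and count property — exclusion removes
bursts from burst-level statistics, never spikes from the unit.

### Wave-associated bursts

Each kept burst is divided into 10 equal bins. Two bursts associate when
some pair of bin-start times differs by at most $\Delta t$, half the sum
of the two bin durations; the comparison is inclusive (ties are
measure-zero on continuous times) and "bin starts" are read as the 10
left edges, since a bin has one start. Bursts on the same unit or the
same channel never associate, and a neighbouring channel supports a
burst at most once regardless of how many of its units burst. A burst
supported by ≥ 2 of its up-to-8 surrounding electrodes (5 on an edge, 3
in a corner) is a wave-associated burst (WAB).

### Spiking properties

`compute_properties()` evaluates an 11-property registry per unit: mean
WAB duration (s), in-WAB firing rate (Hz), spikes per WAB, inter-WAB
interval (s), WAB count, WAB rate (per min), total spikes, spikes outside
WABs, out-of-WAB firing rate (Hz), overall mean rate (Hz), and the
fraction of spikes inside WABs. The original analysis compared 22
properties whose full enumeration is not public; the registry covers the
reported effects (longer WABs, higher in-burst rates, more spikes, shorter
inter-burst intervals, more out-of-WAB spikes) and is the documented
default. Conventions:

* the inter-WAB interval runs from the end of one WAB to the start of the
  next on the same unit (the "interval" is the silent gap);
* in-WAB rate divides WAB spikes by total WAB time; out-of-WAB rate
  divides the remaining spikes by the remaining time;
* retina-level values are unweighted means over units, the retina being
  the experimental unit for statistics;
* units with zero WABs contribute to count-type properties but are left
  out of the WAB-conditional means (duration, spikes/WAB, in-WAB rate;
  the interval needs ≥ 2 WABs) — the alternative is 0/0.

### Correlation

The spike time tiling coefficient (`sttc()`) uses ±50 ms windows clipped
to the recording and merged where they overlap. Undefined pairs (an empty
train, or a vanishing denominator) are dropped from curves with a count,
not set to 0, which would bias medians toward zero. Pair distance is the
Euclidean electrode separation; pairs are grouped by exact distance (the
grid guarantees a discrete set), and same-channel (distance 0) pairs are
included by default — with it, the 8×8 grid at 200 µm pitch has exactly
10 distinct distances up to the 800 µm statistics cutoff, matching the
family size m = 10 used for the distance-wise comparisons. STTC is
computed over the full recording; the edge-margin rule is defined for
bursts only.

### Group statistics

Two-tailed Welch t-tests (unequal variances, Welch–Satterthwaite df) on
retina-level values, with Holm–Bonferroni step-down control over each
family. Decisions use adjusted p ≤ α, which is equivalent to the literal
step-down rule; ties in the sort are broken by original index and
adjusted p-values are made monotone by the running maximum. Note that at
very small group sizes (n = 4) the Welch test is conservative, so the
realised familywise error under the complete null sits below the nominal
0.05 (about 0.027 in the 10,000-replicate calibration).

## 2. The image pipeline

### Percent overlap

Each channel is binarised at the *maximum* intensity over a region of the
section containing no retinal innervation — a maximum, not a percentile,
so every background pixel is off; binarisation is therefore strictly
greater-than. Percentages are taken over all pixels of the dLGN ROI
("the whole dLGN"), not over supra-threshold pixels. Percentages are
invariant under rescaling a channel together with its background, since
the threshold scales along.

### R-value distributions

The per-pixel quantity is $R = \log_{10}((I_{ipsi} + 1)/(I_{contra} + 1))$
with a one-intensity-unit offset keeping the ratio defined at zero; the
sign convention puts ipsi-dominant pixels at positive R. Reference
distributions come from ROIs maximally innervated by each eye (explicit
input masks; the original workflow selects them interactively), pooled
across the 15-section stack. The contra cutoff is the 99.9% quantile of
the contra reference, the ipsi cutoff the 0.1% quantile of the ipsi
reference — each reference contributes the cutoff beyond which 99.9% of
its own pixels lie toward its own pole — and pixels strictly between the
cutoffs are unsegregated. This is the only orientation under which a
perfectly segregated stack scores near 0 and a fully mixed one near 1;
crossed cutoffs are flagged degenerate and reported as fraction 1 with a
warning. The variance of the dLGN R-distribution is reported alongside:
wider distributions mean more eye-specific extremes and fewer balanced
pixels.

A caveat the tests respect: variance is monotone in binocular mixing only
when the R-distribution is roughly symmetric. In a strongly
contra-dominant field (mean R far below 0), converting contra pixels to
R = 0 moves them *away* from the mean and the variance initially rises.
The programmed monotone-series check therefore uses a balanced field
(ipsi territory = 50% of the ROI); the unsegregated fraction is monotone
regardless, by construction of the nested mixed-pixel sets.

### SC density profiles

`sc_profile()` bins the retinorecipient SC outline into 4 µm
medio-lateral bins from the medial mask edge and reports
100 × CTB⁺ pixels / mask pixels per bin; empty bins are missing, not 0.
Profiles stack into a dorsal-view reconstruction
(`sc_reconstruction()`), optionally rendered as a thermal map anchored at
0% = blue and 100% = red.

## 3. The synthetic generators

`simulate_mea()` is *artifact plumbing with programmed truth*, not a
biophysical wave model. Waves arrive as a Poisson process (default one
per 45 s); each is a planar front with uniformly random direction,
starting at a random electrode and crossing the grid at 200 µm/s. A front
reaching an electrode triggers, on each of its units, a burst of
homogeneous Poisson spikes at 10 Hz lasting 2 s × log-normal jitter
(sdlog 0.1), on top of 0.1 Hz Poisson background firing. Design notes:

* planar fronts are the simplest geometry producing the co-bursting of
  neighbouring channels that the WAB rule assumes; front-arrival delays
  (1 s per pitch at the defaults) keep neighbouring bursts overlapping;
* burst spike counts are floored at 2, so every ground-truth interval is
  a spiking episode surely rather than almost surely;
* no published wave frequency or speed accompanies the recordings this
  emulates, so the defaults are round placeholder values; every test
  depends only on programmed values, never on literature ones.

What the generator does **not** emulate: cholinergic wave dynamics,
refractory wave domains, curved or annihilating fronts, unit count
variation per electrode, electrode noise, or sorting errors. Passing
tests therefore demonstrate that the pipeline recovers what it is defined
to measure on data obeying its assumptions — they do not validate the
detector against real recordings.

`simulate_dlgn_sections()` rasterises exact pixel counts: the ipsi patch
is the `round(fraction × mask)` nearest pixels to a jittered patch
centre, and its core keeps contralateral signal so that the programmed
overlap is exact in the noise-free limit (recovery errors below 0.001 pp
measured; the 1 pp tolerance in the tests covers rasterisation at other
geometries). A border strip guaranteed free of signal provides the
background region. The `mixing` parameter replaces a programmed fraction
of mask pixels by the channel mean; the mixed sets are nested across
levels for a fixed seed, making programmed series monotone by
construction. `simulate_sc_sections()` realises a density profile
column-by-column with deterministic rounding to whole pixels.

## 4. Problem sizes and calibration choices

Sizes used by the test suite and the acceptance script, chosen once as
realistic for this kind of study (the original MEA comparison pooled
275 and 245 spike trains per group, i.e. roughly 4–5 retinas a side):

* **Recordings**: 600 s, 8×8 grid, one unit per channel, ~13 waves per
  recording.
* **Null calibration**: m = 22 properties, 4 retinas per group, 10,000
  replicates.
* **Power on programmed effects**: condition B scales burst duration
  ×1.5 and background rate ×2; 6 retinas per condition, 100 replicates.
  Six (not fewer) retinas because the out-of-WAB spike count inherits
  large between-retina variance from the Poisson number of edge-clipped
  waves, and a pilot at n = 4 left the duration effect at only 80%
  detection.
* **STTC curve power**: the detectable manipulation is background rate ×4
  (4 retinas, 6 replicates). Doubling the *wave rate* does not separate
  the curves — STTC is insensitive to event rate by design, and the
  measured shift (~0.02 at 200 µm) is within one between-retina SD; this
  is a property of the statistic, not a pipeline defect.

## 5. Known limitations

* The burst search is a deterministic approximation to a proprietary
  implementation; only the published criterion (surprise ≥ 4, i.e.
  $P < 10^{-4}$) is reproduced exactly.
* The 22-property registry of the original analysis is not public; the
  11-property registry here covers the reported effects.
* The R-value formula and the tail orientation of the 99.9% rule are
  reconstructed from the cited method, not printed in the source; both
  are documented above and isolated behind single functions
  (`r_map()`, `unsegregated_stats()`) should a different convention be
  needed.
* Section registration, dLGN outlining and reference-ROI selection are
  manual upstream steps; the package consumes masks, it does not find
  them.
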