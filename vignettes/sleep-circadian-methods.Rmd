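---
title: "Methods: vigilance staging, sleep architecture and circadian rhythm analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vigilance staging, sleep architecture and circadian rhythm analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnoscope)
```

somnoscope analyses mouse polysomnography (EEG/EMG) and locomotor
activity the way rodent sleep labs do: vigilance states scored on a
10-s epoch grid, architecture statistics folded onto the zeitgeber
clock, and rhythm robustness quantified with the chi-square
periodogram. This vignette documents the models, the tunable
parameters, the numerical choices, and what the bundled synthetic-data
generator does and does not emulate.

## Signals, epochs and spectra

Recordings are multichannel EEG/EMG at a fixed sampling rate, 128 Hz by
default, carried as EDF. Recordings are required to start on a whole
zeitgeber hour (ZT0 = lights-on; all bins are half-open $[a, b)$) so
that epochs and bins align exactly. Vigilance labels live on a 10-s
epoch grid with integer codes W = 0, N = 1, R = 2, fixed package-wide.

The per-epoch spectrum is the mean of five consecutive, non-overlapping
2-s FFT windows that tile the epoch. At 128 Hz a 2-s window is 256
points, so the frequency resolution is 0.5 Hz. Each window is
Hann-tapered and demeaned; power is normalised so that the bin sum
equals the window-weighted mean square of the segment,
$\sum_k P_k = \sum_t w_t^2 x_t^2 / \sum_t w_t^2$, which makes the
Parseval-style conservation check an identity up to floating-point
error. The Hann taper is a choice (it reduces leakage between the
closely spaced 0.5-Hz bins); rectangular windows would satisfy the same
conservation property with more leakage.

Band powers sum bins with $lo \le f < hi$; a band whose upper edge sits
exactly at the Nyquist frequency includes the Nyquist bin, so the full
band equals total power. Slow-wave activity (SWA) is delta power
(0.5-4 Hz) in NREM epochs. The theta band is fixed at 6-9 Hz, the usual
rodent hippocampal-theta range; the delta band follows the SWA
definition. A 2nd-order Butterworth 49-51 Hz band-stop is available for
mains interference on real recordings; synthetic data do not need it
and the config leaves it off by default. Amplifier pass-bands of
acquisition hardware (e.g. an analog 0.5-250 Hz EEG filter wider than
the digital Nyquist) are treated as metadata and never re-applied
digitally.

Two nonlinear features complement band power. Sample entropy
SampEn($m{=}2$, $r{=}0.2\,\mathrm{SD}$) is the negative log conditional
probability that templates matching within Chebyshev tolerance $r$ at
length $m$ still match at $m+1$, self-matches excluded; with no matches
the function returns an `Inf` sentinel flagged for downstream QC.
(Sample entropy is one of several entropy variants used for EEG
irregularity; it was chosen here for its bias properties on short
segments, and that choice is a package decision.) The detrended
fluctuation analysis (DFA) exponent is the slope of
$\log F(n)$ vs $\log n$ with linear detrending over non-overlapping
windows; the default scales are 8 log-spaced sizes from 16 to 512
samples, suited to a 25-s window at 128 Hz (3,200 samples, satisfying
the length $\ge 4 \times$ max-scale requirement). White noise
calibrates to $\alpha \approx 0.5$ and integrated noise to
$\alpha \approx 1.5$, and the test suite checks both.

## Rule-based vigilance staging

The stager reproduces the classical cue hierarchy used by human
scorers: muscle tone first, then cortical delta, then theta
regularity. For every second $t$, the 25-s window $[t-12, t+13)$
(clipped at the record edges; centred alignment is a package decision,
since trailing windows would lag boundaries by half a window) is
scored:

1. **Wake** if window EMG tone (RMS) exceeds the subject's wake cut;
2. else **NREM** if the delta ratio $\delta / (\delta + \theta)$ is at
   least 0.55;
3. else **REM** if theta regularity (peak bin $\pm$ 0.5 Hz over total
   theta power) is at least 0.5;
4. else **NREM** (fallback; a silent EEG also defaults to NREM).

Window spectral features are means of the 2-s periodograms starting at
each whole second inside the window (24 overlapping windows in a full
25-s window); the 1-s step matches the 1-s label resolution. Per-second
labels are aggregated to 10-s epochs by majority, ties broken with the
fixed priority W > N > R (wake cues are the most reliable, so a
wake-heavy tie should not be absorbed into sleep).

The wake cut is per-subject adaptive. The default is an automatic
bimodal split: 2-means on log window tone, cut at the midpoint of the
cluster centres (geometric-mean midpoint on the natural scale). A fixed
tone quantile is also accepted, but a quantile default is brittle: the
tone distribution is strongly bimodal, and any quantile that does not
happen to fall in the gap between the sleep and wake modes splits one
mode in half, which is catastrophic whenever the subject's true wake
fraction differs from the assumed one. The bimodal split has no such
assumption and needs no tuning across genotypes with different
wake amounts. Both delta-ratio and theta-regularity cuts stay fixed
(0.55, 0.5): they act on ratio scales that are already normalised.

Staging error concentrates at state boundaries: a centred 25-s window
cannot resolve a transition to better than about half a window, so
per-second labels may be off by up to ~13 s around each true boundary.
On the preset synthetic day this yields ≥ 90% epoch accuracy and
≥ 80% per-state recall (the suite pins both), with the residual errors
almost entirely single-epoch boundary shifts. Manual review is out of
the automated path; an override table (epoch index → label) is applied
after aggregation instead.

## Architecture statistics

Episodes are maximal same-state runs with no smoothing and no minimum
bout length (a single 10-s epoch is an episode). Episode summaries
assign each episode to the ZT bin containing its onset; state-time
profiles split time across bins exactly, so states sum to the bin
length in every bin; transitions are assigned to the bin containing the
post-transition epoch. These onset/post-state conventions are the
package's own (any consistent convention conserves totals; these are
the unambiguous ones).

Only five transition types are analysed — W→N, N→W, N→R, R→N, R→W.
Direct wake-to-REM transitions are biologically anomalous in rodents;
they are excluded from tables and matrices by construction and counted
in a QC field instead. Conditional probabilities divide each
transition count by all transitions out of the same pre-state in the
same bin (e.g. $P(N{\to}R) = \#(N{\to}R) / (\#(N{\to}W) + \#(N{\to}R))$),
so rows of the phase transition matrices sum to 1 wherever defined.

REM latency is the time from NREM sleep onset to REM onset. The latency
clock starts at a W→N transition and, under the strictest reading of
"NREM sleep onset", any wake episode resets it; `wake_reset_min_epochs`
relaxes this so brief arousals (shorter than the threshold) are
tolerated, since published analyses are usually silent on this point.
Chained N→R→N→R sequences without intervening wake all measure from the
same onset. REM episodes with no preceding onset (e.g. REM at the
recording start) are excluded and QC-counted. Histograms use 50-s bins
from 0 to 600 s plus an open overflow bin, with phase assigned by the
REM onset ZT.

The SWA time course averages delta power over NREM epochs per 6-h bin
and normalises each subject to its own 24-h NREM mean (= 100%), which
removes electrode-impedance scale differences between animals; bins
without NREM epochs are missing. Group spectra are reported over
0.5-30 Hz with each epoch's spectrum normalised to its total power in
that range (relative power) when genotypes are compared, absolute power
being retained internally.

## Chi-square periodogram

For a candidate period of $K$ bins with $N$ complete cycles (the tail
is truncated; only complete cycles enter), the Sokolove-Bushell
statistic is

$$Q_p = \frac{N \sum_{h=1}^{K} (M_h - \bar M)^2}{\mathrm{Var}(x)}$$

with $M_h$ the K column means of the folded series and the variance
taken over the bins used. Under an i.i.d. null $Q_p \sim \chi^2_{K-1}$
approximately, giving the per-candidate significance threshold at
$\alpha$. The candidate grid runs 20-28 h in steps of one data bin (the
finest step the fold supports). Because commercial packages differ in
whether they report the raw peak or its excess over the threshold, both
`best_qp` and `best_excess` are returned. Note the threshold is
per-candidate: the peak over the (correlated) candidate grid exceeds it
on pure noise more often than $\alpha$, so `best_excess > 0` alone is a
liberal rhythm test; the suite therefore checks the per-candidate
exceedance calibration.

Activity onset detection (20% of daily smoothed max after ≥ 4 h below)
exists only for QC of free-running drift; period estimates always come
from the periodogram.

## The synthetic cohort

The generator produces data with exactly the statistical structure the
analyses assume — and no more.

**Hypnograms** come from a first-order Markov chain stepped per 10-s
epoch with phase-switched 3×3 transition matrices (light, dark, and an
optional mid-dark "nap" window at ZT19-21 scored with the light
matrix, on in the wild-type preset). First order is the simplest
structure the transition-matrix analysis can recover; it also implies
approximately geometric REM latencies, a known simplification — real
latency distributions have a refractory mode the chain cannot produce,
so latency *histogram shapes* should not be over-interpreted, though
group differences in counts are faithfully injected. $P(W{\to}R) = 0$
structurally.

**Preset kinetics** (per-epoch probabilities) place the wild type at
roughly 36/55/9% W/N/R in the light and 68/31/1% in the dark. The
mutant preset lowers light-phase $P(N{\to}R)$ (0.025 → 0.012), raises
it in the dark (0.008 → 0.022) and reduces dark wake maintenance, so
REM becomes nearly phase-flat — the attenuated circadian REM modulation
phenotype — while light-phase short-latency REM entries become rarer.
These values were chosen once to sit in the physiological range for
C57BL/6-background mice (REM bouts ~1 min, NREM bouts ~1.5-2.5 min)
and give unambiguous effect directions at cohort sizes of ~12/genotype.

**Signals** are synthesised per episode: each state's EEG is a sum of
narrow-band oscillations (frequency drawn once per episode around the
band centre, phase continuous across epoch boundaries within the
episode, reset at episode boundaries — continuity avoids spectral-leakage
artifacts dominating the staging tests) over 1/f background noise, and
the EMG is white noise at the state's RMS tone. The preset recipe is
delta-dominant NREM (2 Hz, 40 µV), sharp-theta REM (7 Hz, 30 µV),
broadband low-voltage wake, EMG tone 30/8/4 µV RMS for W/N/R —
amplitudes typical of mouse epidural screw electrodes. There are no
spindles, K-complexes, movement artifacts or state-transition
dynamics: passing staging tests on these data shows the rule logic and
its windowing are correct, not that the stager matches expert scoring
on real recordings.

**Activity** follows a parametric nocturnal waveform — a dark-phase
fraction of daily counts with an early-dark peak weight — locked to the
24-h zeitgeber under LD and free-running at `period_h` under DD with
phase continuous at the transition. Counts are negative-binomial
(beam-break counts are over-dispersed; dispersion is a model
parameter). Presets: wild type 23.75 h, 10 counts/min, 85% dark,
front-loaded; mutant 23.68 h, 6.5 counts/min, 80% dark, flatter — i.e.
slightly shorter period, lower and less front-loaded nocturnal
activity. Seven LD days precede ten DD days, matching common
wheel-running protocols.

All generators are bit-for-bit reproducible given a seed; the pipeline
derives per-subject seeds by stable hashing of subject ids so cohorts
can grow without reshuffling.

## Statistics

The battery mirrors standard prism-style genotype analyses: pooled
unpaired two-tailed t with Cohen's d (pooled SD); two-way
fixed-effects ANOVA with interaction, Type III sums of squares via
effect coding (robust to the unbalanced n of animal cohorts; in
balanced designs the decomposition $SS_A + SS_B + SS_{AB} + SS_e =
SS_T$ is exact and tested); Sidak adjustment
$p' = 1 - (1-p)^m$ with the family size equal to the number of bins
compared (24 for 1-h profiles, 4 for 6-h bins); Fisher's LSD on the
ANOVA's pooled MSE; Shapiro-Wilk per group (skipped with a flag below
n = 3 or for constant groups) and Brown-Forsythe (one-way ANOVA on
absolute deviations from group medians, computed directly from sums of
squares with a degeneracy guard).

Time-course comparisons are deliberately fixed-effects, not
repeated-measures: subject-by-bin values are treated as independent
observations. For the synthetic cohorts this is the generating truth
(bins are conditionally independent given the chain); for real
longitudinal data it is anticonservative, and the output metadata says
so (`model_note`). A Welch fallback for the t-test is available when
variance homogeneity is rejected, off by default to match the standard
pooled analysis.

## Problem sizes and numerical tolerances

The validation suite runs at sizes chosen to make its statistical
assertions sharp while staying desk-scale: 30-day single-subject
chains for transition-probability recovery (binomial 95% CIs, three
seeds, with coverage judged jointly across the ~30 simultaneous
checks rather than entry-by-entry); one full synthetic day for staging
fidelity; 12 subjects/genotype × 2 days for effect-direction recovery;
10 DD days at 1-min bins for period recovery (grid step 1 min ⇒ ±0.1 h
easily resolved); 20 seeds × 3,200 samples for DFA calibration; 200
null replicates for type-I calibration. Exact identities (Sidak,
conservation, oracle equivalences) are asserted at 1e-8 to 1e-12;
stochastic calibrations at their Monte-Carlo CIs.

## Known limitations

- The stager is a transparent rule set, not a trained classifier; on
  real data it needs per-subject review, which is why overrides exist.
- The Markov generator cannot produce REM refractory periods,
  ultradian NREM-REM cycling, or state-dependent spectra drifting with
  time-of-day (e.g. SWA decline across the rest phase); SWA time-course
  code is exercised with constructed spectra instead.
- Fixed-effects time-course ANOVA is anticonservative for repeated
  measures on real animals.
- The EDF layer covers continuous 16-bit recordings with one sampling
  rate; EDF+ annotations and discontinuous files are out of scope.
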