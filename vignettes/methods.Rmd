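---
title: "Methods: oscillatory analysis of visual working-memory errors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oscillatory analysis of visual working-memory errors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis problem

`wmosc` analyses EEG recorded during a fast-paced visual working-memory
(VWM) recognition task. In every trial a subject encodes four sequentially
presented images of one object category (0.25 s each), maintains them over
a short retention interval, and then classifies two probe images as old or
new. Three behavioural outcomes are defined by the probe/response
contingency: *correct* (both probes classified correctly), *false memory*
(a never-shown category lure accepted as old while the accompanying target
is also recognised), and *error* (all other answered combinations);
no-response trials are *unanswered*. The scientific question is whether the
oscillatory signatures of encoding (occipital theta) and retention
(parieto-occipital alpha-beta) distinguish these outcomes.

The pipeline implements the full chain from raw continuous EEG plus a
behavioural log to cluster-level statistics:

1. zero-phase Butterworth bandpass (0.2–100 Hz, order 4 per pass),
2. 3 s epochs from −1.00 to 2.00 s around the first-stimulus onset,
   demeaned per trial and channel,
3. FastICA ocular-artifact removal keyed on EOG correlation,
4. peak-to-peak artifact-trial rejection,
5. sliding Hanning spectrograms (500 ms windows, 50 ms steps, 2–32 Hz in
   2 Hz bins) with percent-change baseline normalisation,
6. equal-N trial balancing with response-time prioritisation and merged
   conditions for the false-memory contrasts,
7. individual central frequency (ICF) detection and alignment,
8. cluster-based permutation tests over channel–frequency–time triplets,
9. behavioural statistics (Friedman, Wilcoxon signed-rank with effect
   sizes, Spearman correlations, serial-position accuracy, Lilliefors
   normality screening).

## Baseline normalisation

Power is expressed per subject as percent change from a pre-stimulus
baseline,

$$P_{norm}(f_i, t_j) = 100 \times
  \frac{P(f_i, t_j) - P_{baseline}(f_i)}{P_{baseline}(f_i)},$$

where $P_{baseline}(f_i)$ is the mean raw power per channel and frequency
over **all** trials (condition-agnostic) and all spectrogram window centres
falling in the −1.00 to −0.30 s interval. Two consequences are tested
explicitly: a bin equal to its baseline maps to exactly 0 %, and the
normalised maps are invariant to rescaling the raw signal (power scales as
$c^2$ in numerator and denominator alike).

Window centres are restricted to the range where a full 500 ms window fits
inside the epoch (−0.75 to 1.75 s); windows are never padded, so the
effective baseline bins are the centres in −0.75 to −0.30 s. The spectral
estimator is a single periodic Hanning taper with the squared magnitude of
the Fourier coefficient at each 2 Hz bin, scaled so a unit-amplitude
sinusoid at a bin frequency yields power 1/2 (amplitude²/2); no
zero-padding or interpolation is used. Baselines are pooled over
post-rejection trials only — balancing happens after normalisation, so the
baseline never depends on the analysed contrast.

## Trial selection

Condition imbalance changes the signal-to-noise ratio of trial-averaged
spectrograms, so every contrast uses an equal number of trials per arm.
The larger arm is subsampled by a seeded draw that prefers trials whose
response time lies within one standard deviation of that condition's mean
RT (computed per subject on answered trials, after artifact rejection),
falling back to out-of-window trials only when the typical pool is
exhausted. For the merged conditions (*error + false memory* and
*correct + false memory*) every merged-in false-memory trial is retained
unconditionally; the provenance of merged trials is kept in a dedicated
column so the original partition can always be recovered.

## ICF detection and alignment

The retention-interval alpha-beta rhythm peaks at a subject-specific
frequency. The ICF is defined as the frequency in 10–26 Hz with the
largest normalised power increase averaged over the right
parieto-occipital channels (P4, P8, O2) and the second half of the
retention interval (1.5–2.0 s), all trials pooled, with ties broken toward
the lower frequency. A deterministic argmax replaces any visual screening
step, for reproducibility; a per-subject override hook exists in the
pipeline configuration for manual curation. If no candidate frequency
shows an increase the argmax is still returned with a low-SNR warning.

For group statistics each subject's frequency axis is translated by whole
2 Hz bins so all ICFs land on a common reference — the cohort median ICF
by default, snapped to the analysis grid. Bins shifted outside 2–32 Hz
become missing and are **excluded** from cluster statistics rather than
zero-filled, to avoid fabricating power; alignment is exactly invertible on
the surviving bins. Right-minus-left lateralization of ICF-band retention
power (P4/P8/O2 vs P3/P7/O1) is tested with a paired two-sided t-test and
reported with $r = \sqrt{t^2/(t^2 + \mathrm{df})}$.

## Cluster-based permutation statistics

A dependent-samples t-value is computed at every (channel, frequency,
time) triplet of the analysis box. Triplets with two-sided $p < 0.05$ form
clusters when contiguous and of a common sign; contiguity combines
channel adjacency (template 10-20 positions, neighbours within 0.55 outer
ring radii — a threshold at which O1–Oz–O2 and P4–P8–O2 are connected)
with ±1 grid bin in frequency and in time; diagonal moves do not connect,
and singleton triplets are discarded. The cluster statistic is the sum of
member t-values.

The null distribution exchanges the two condition means within each
subject — equivalently, flips the sign of each subject's difference map —
and records the maximum positive and minimum negative cluster mass per
permutation (30000 Monte Carlo permutations by default). Cluster p-values
use the +1-corrected estimator $p = (1 + \#\{\text{null} \geq
\text{obs}\})/(1 + n_{perm})$, so no finite run reports $p = 0$; each tail
is tested at 0.025. With 16 or fewer subjects an exact mode enumerates all
$2^n$ sign patterns instead, which the test suite uses as an oracle for
the Monte Carlo path. For the two merged-condition analyses a Bonferroni
factor of 2 is applied and recorded in the output; the multiplicity family
of the primary correct-vs-error contrasts (encoding and retention analysed
separately) is deliberately left uncorrected, with the factor stored
explicitly in every result.

The encoding analysis box is O1/Oz/O2 × 4–14 Hz × 0–1 s, covering the
theta (4–8 Hz) and alpha (10–14 Hz) bands of interest in one test so
clusters can form in either band; the retention box is P4/P8/O2 ×
[ref − 2, ref + 2] Hz × 1–2 s on the aligned maps.

## Behavioural statistics

Response-time condition effects use Friedman's ANOVA on per-subject
condition medians (tie-corrected $\chi^2$, df = 2), followed by Wilcoxon
signed-rank post hocs with a tie-corrected normal approximation and a
Bonferroni-corrected threshold of 0.05/3 ≈ 0.017. Effect sizes use
$r = Z/\sqrt{N}$ with $N$ the total number of observations (twice the
number of pairs, zero differences included) — the convention under which a
34-pair comparison has $N = 68$; this convention reproduces the published
effect sizes exactly from their Z statistics, which the acceptance tests
verify. Normality screening uses the Lilliefors variant of the
Kolmogorov–Smirnov test (parameters estimated from the sample). Spearman
correlations default to the t approximation for p; an exact permutation
mode is available because the t approximation can disagree noticeably with
permutation p-values at small n, and the package surfaces that choice
rather than hiding it. The correlation between retention-cluster power and
mean RT excludes subjects outside the bivariate normal 95 % confidence
ellipse (squared Mahalanobis distance above the $\chi^2_2$ quantile), a
concrete reading of an "outside the 95 % confidence interval" rule.

## The synthetic cohort generator

No public recordings exist for this paradigm, so the generator produces
cohorts with the statistical structure the analysis assumes, and the test
suite validates every stage against that ground truth. Per subject it
draws:

* **Behaviour** — conditions i.i.d. from the cohort rates (defaults:
  correct 51.10 %, false memory 9.75 %, error 38.18 %, unanswered 0.97 %);
  probe types balanced across the three layouts with lure probes reserved
  for false-memory trials; responses consistent with the contingency
  table; shifted-lognormal response times whose defaults approximate the
  observed medians and IQRs (1.145, 1.176, 1.330 s — errors slower); and
  per-position recognition flags with a recency boost (≈ 92.5 % at
  position 4 vs ≈ 66 % earlier).
* **EEG** — 32 channels (30 scalp 10-20 sites + VEOG/HEOG) at 250 Hz by
  default: 1/f background noise (exponent 1, 10 µV RMS) with a slow
  log-normal amplitude modulation that gives the background the
  waxing-and-waning, super-Gaussian character of real EEG (this also makes
  the mixture identifiable for ICA — stationary Gaussian noise is not);
  an ongoing narrowband posterior alpha rhythm (10 Hz centre, 3 Hz
  bandwidth, 2.5 µV RMS — posterior alpha is a band, not a line) that
  desynchronizes by 70 % during encoding, producing the canonical
  stimulus-induced alpha power decrease; Hanning-tapered 7 Hz theta bursts
  over O1/Oz/O2 during encoding (0.3–0.7 s) with amplitudes 4/4/7/4 µV for
  correct/false-memory/error/unanswered; a sinusoidal burst at the
  subject's ICF (uniform over even 10–26 Hz) over P4/P8/O2 during late
  retention (1.5–2.0 s) with amplitudes 3/5.5/5.5/3 µV and a 0.25-weight
  left-hemisphere counterpart (producing the right lateralization);
  250 µV biphasic blinks at 0.2 Hz, written undiluted to the EOG channels
  and propagated to the scalp with distance-decaying weights; and a 6.5 %
  per-trial chance of a large non-ocular artifact, calibrated so that
  roughly 202 of 216 trials survive the default 200 µV rejection rule.

Envelope shapes differ deliberately between the two bursts. The encoding
theta burst is Hanning-tapered (smooth onset/offset, no edge splatter).
The retention ICF burst instead uses a flat-topped Tukey taper: a 0.5 s
Hann envelope would smear almost half of the burst power into the
adjacent ±2 Hz spectrogram bins, and since the 1/f-plus-alpha baseline
falls with frequency, the percent-change argmax would then systematically
prefer the bin *above* an alpha-range ICF. A flat-topped burst keeps the
line narrow (and ICF recovery reliable) while still tapering the edges.

Burst amplitudes are not published quantities; they were fixed once at
values giving realistic percent-change magnitudes (grand-average encoding
theta around +15 to +20 %, alpha desynchronization around −20 %) at which
the qualitative contrasts are reliably detectable, and the tests treat
them as the study conditions. What passing tests on this cohort shows is
that the *pipeline* recovers planted effects of realistic size and
calibrates correctly under the null; it cannot show how the analysis
behaves under real-EEG phenomena the generator omits — volume-conducted
correlated noise, saccades and muscle artifacts, non-stationary peak
frequencies, or trial-to-trial latency jitter.

## Numerical and design choices

* **Zero-phase filtering** (forward–backward, amplitude squared at the
  edges, ≈ −6 dB at the cutoffs) avoids phase distortion of
  time-frequency latencies.
* **ICA**: symmetric fixed-point FastICA with tanh contrast on eigenvalue
  whitening; the unmixing matrix is estimated on an evenly decimated
  subset of at most 20000 time points and applied to all samples;
  components whose absolute correlation with either EOG channel exceeds
  0.7 are zeroed. Non-convergence restarts with a fresh random
  initialisation up to five times before failing hard. The component count
  defaults to the number of EEG channels.
* **Rejection** replaces visual inspection with a deterministic
  peak-to-peak rule (default 200 µV) so results are reproducible.
* **Degenerate inputs**: a zero baseline power is a hard error; zero
  difference variance at a triplet yields t = 0 with a warning; a fully
  tied Friedman table returns χ² = 0, p = 1; identical hemispheres give a
  lateralization t of 0 with p = 1; constant input to the normality screen
  is an error.
* **Determinism**: every stochastic step (generation, balancing, ICA
  initialisation, permutations) takes an explicit seed, recorded in the
  outputs together with an MD5 digest of the configuration.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run the cohort at the package's
reduced desk scale — 250 Hz sampling, 10 subjects × 216 trials for the
end-to-end run, 8 subjects × 36 trials per replication for the detection
power study (50 replications), 50 subjects × 36 trials for ICF recovery,
200 replications × 1000 permutations for the null calibration of the
cluster test, and 1000 permutations for the end-to-end contrasts. The
full-scale protocol values (1000 Hz, 28 subjects, 30000 permutations)
remain the configuration defaults and are available by setting
`synth_config(sampling_rate = 1000, n_subjects = 28)` and leaving
`pipeline_config()$cluster$n_perm` untouched.

## Known limitations

* The generator plants condition effects as fixed-amplitude bursts; it
  does not model trial-level amplitude variability beyond the background
  noise, so measured effect sizes on synthetic cohorts are not predictions
  of real-data effect sizes.
* ICF detection operates on the 2 Hz analysis grid; fractional-Hz peak
  interpolation is out of scope.
* Channel adjacency comes from template 2-D positions, not recorded
  electrode locations.
* The BrainVision writer/reader supports the binary MULTIPLEXED INT_16 and
  IEEE_FLOAT_32 dialects only.
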