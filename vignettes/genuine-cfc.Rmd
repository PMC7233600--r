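---
title: "Identifying genuine interareal cross-frequency coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying genuine interareal cross-frequency coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfcnet)
```

## The problem

Cross-frequency coupling (CFC) between neuronal oscillations comes in two
statistical forms: *cross-frequency phase synchrony* (CFS), a nonrandom
phase relation between oscillations whose center frequencies are in an
integer 1:m ratio, and *phase-amplitude coupling* (PAC), a correlation
between the phase of a slow oscillation and the amplitude envelope of a
faster one. Both are estimated here with phase-locking statistics on
Morlet-filtered analytic signals:

* within-frequency phase synchrony (PS):
  $\mathrm{PLV}_{a,b} = \frac{1}{N}\left|\sum_t e^{i(\theta_a - \theta_b)}\right|$,
  and the mixing-insensitive weighted phase-lag index
  $\mathrm{wPLI}_{a,b} = |E\{\Im X_{ab}\}| / E\{|\Im X_{ab}|\}$ with
  $X_{ab} = Z_a Z_b^*$;
* CFS: $\mathrm{PLV}_{CFS,a,b,m} = \frac{1}{N}\left|\sum_t
  e^{i(m\theta_{a,LF} - \theta_{b,HF})}\right|$, with the LF phase
  unwrapped, interpolated to the HF sample times, and "accelerated" by
  multiplication with $m$;
* PAC: $\mathrm{PLV}_{PAC,a,b} = \frac{1}{N}\left|\sum_t
  e^{i(\theta_{a,LF} - \theta_{b,HF,LFenv})}\right|$, where
  $\theta_{b,HF,LFenv}$ is the phase of the HF amplitude envelope filtered
  at the LF center;
* amplitude-envelope correlation (AC): the PLV between two channels'
  LF-filtered HF envelopes.

A single nonsinusoidal or non-zero-mean process projects signal components
into several frequency bands after filtering, producing *local* CFC at one
sensor without any interaction between two oscillators. Combined with
ordinary within-frequency synchrony between two areas, such one-process
components also masquerade as *interareal* CFC. The package's central
operation removes those ambiguous observations: a significant interareal
CFS edge $a \to b$ (with $a$ the LF node) is discarded when it closes a
*triangle motif* — significant local CFS at the LF end together with
significant interareal HF PS, or significant local CFS at the HF end
together with significant interareal LF PS. For PAC the motif legs are
local PAC at the HF end + interareal LF PS, or local PAC at the LF end +
interareal HF envelope correlation. Edges left without a complete motif
cannot be explained by one source and are reported as genuine. The test is
deliberately conservative: genuine coupling that happens to sit inside a
full motif is removed too, so the pruned connectome is a lower bound.

## Edge significance

Per-edge significance uses circular-rotation surrogates: the second series
of each pair is shifted by a uniform draw from 10–90% of its length, which
preserves autocorrelation while destroying alignment, and one surrogate
value per pair is pooled into a null mean per subject, metric and
frequency (pair). PLV-family statistics of uncorrelated phases are
Rayleigh distributed, and a Rayleigh distribution reaches its 99th
percentile at 2.42 times its mean, so edges are declared significant at
nominal $p < 0.01$ when they exceed $2.42 \times$ the surrogate mean. For
wPLI the null standard deviation is also pooled and the rule is a z-score
above 2 (nominal $\alpha = 0.02$); both rules use strict inequalities. The
two alphas follow the respective rules' conventions and are reported, not
harmonized. Connection density $K$ is the fraction of significant over
admissible edges minus the 1% expected under the null (not clamped at
zero); after pruning, the corrected density divides the kept edges by the
admissible edges left after removing the pruned ones (a fixed-denominator
variant is available for sensitivity analysis).

## Spectral front end

Recordings are decomposed with complex Morlet wavelets of width $m = 5$
cycles on a geometric grid (49 frequencies from 1.2 to 315 Hz by default;
`frequency_grid()`). The wavelet is DC-corrected so the lowest bands carry
no mean leakage, and samples within one wavelet half-support (3 standard
deviations) of segment edges or rejected artifact windows are invalidated;
all estimators skip invalid samples. Narrowband series are decimated by
`floor(rate / (5 f0))` so roughly five samples per cycle remain — the
narrowband filter itself bounds the bandwidth, so plain subsampling
suffices — and original-sample indices are retained so series at different
rates can be realigned exactly. Cross-frequency analysis pairs are grid
pairs whose frequency ratio is within 5% of an integer 1:m (ties broken by
minimum deviation, then the lower HF index). Line noise is removed with a
zero-phase Butterworth band-stop cascade at the line frequency and all
harmonics below Nyquist. High-amplitude artifact windows (e.g. interictal
events) are flagged in 500-ms windows when a channel's band envelope
exceeds its mean by 5 SD, and a window is rejected globally when at least
10% of channels are flagged in more than half of 18 log-spaced bands at or
below 100 Hz; the exact band set is configurable because it is a
convention, not a derived quantity. Channel pairs closer than 20 mm or
sharing a reference contact are excluded from connectivity analysis.

## The synthetic-data generator

`gen_recording()` emulates the signal families that make this problem
hard. Each channel's base oscillator is Morlet-filtered white noise at its
center frequency: a stochastic narrowband process with Rayleigh-fading
amplitude and diffusive phase whose memory is filter-limited (about
$m/f_0$ seconds). This matters for the surrogate machinery — a
deterministic oscillator with random-walk phase retains a frozen frequency
offset that circular rotation cannot destroy, which inflates rotation
nulls in some realizations; filtered noise has no such frozen component.
Waveform families: `sinusoid` (the plain process), `harmonic_rich`
(phase-locked harmonics, the nonsinusoidal case), and `nonzero_mean_am` (a
non-zero-mean carrier amplitude-modulated at half its frequency, which
leaks a phase-locked low-frequency component). Planted couplings: PS edges
mix the lagged driver phasor into the target's phase
(strength-weighted, so the residual deviation is bounded); CFS edges
inject a separate phase-locked component at $m \times$ the driver phase
into the target channel — two separable processes by construction, which
is what makes the planted interareal coupling genuine; PAC edges modulate
the target's amplitude with depth equal to the planted strength. 1/f
noise (exponent 1 by default) is added at a specified band SNR measured in
the process' lowest oscillation band. Default scenario conditions are 20 s
at 200 Hz and 20 dB band SNR, with planted strengths of 0.9.

`gen_triangle_scenarios()` realizes the canonical two-channel
constellations: (d) sinusoid phase-coupled to a harmonic-rich process —
the interareal CFS observable from the first channel's LF band to the
second's HF band is spurious; (e) a non-zero-mean AM process HF-coupled to
a sinusoid — spurious via the LF-side motif; (f) genuine interareal CFS
with no complete motif — must be kept; (g) genuine CFS embedded in a full
motif (the two processes fully phase-locked) — removed, documenting the
method's conservatism; (h) harmonic-rich at both ends with LF PS —
spurious both ways. What these fixtures do *not* emulate: volume
conduction with realistic lead fields, nonstationary coupling epochs,
heterogeneous electrode noise, or genuine multi-band rhythms; passing the
suite shows the estimator/pruning chain is sound on its own terms, not
that real recordings meet its assumptions.

## The four-population validation model

Two "areas" each hold an LF and an HF population ($f_{HF} = 2 f_{LF}$) of
phase oscillators on a discrete unit-step map: each iteration the phase
advances by an intrinsic increment $\omega$ plus the internal mean-field
term $\kappa_{int} R_k \sin(\psi_k - \theta)$ ($\kappa_{int} = 0.12$,
order parameter $R_k$, mean-field phase $\psi_k$) plus, for each external
link, $\kappa M_l \sin(n\psi_l - m\theta)$ — the n:m generalization of
mean-signal coupling, reducing to $\sin(\psi_l - \theta)$ for 1:1 links.
External couplings are $\kappa = c\,\varepsilon$ with a shared factor $c$.
The printed internal-coupling sum is applied in mean-field (per-capita)
form: an unnormalized all-to-all sum with $N = 500$ would add increments
of order 60 rad per iteration and diverge.

The intrinsic increments are drawn uniformly from
$[\pi/15m', \pi/m']$ with $m' = 1$ (HF) and $2$ (LF). Among the candidate
readings of the model's stated frequency heterogeneity, this wide spread
is the only one that reproduces the intended regime: each population stays
partially incoherent, mean fields fluctuate ("intermittent
synchronization"), and increasing $c$ strengthens the measured 1:1 and
1:2 phase correlations gradually. Narrower spreads
(e.g. $[\pi/15m', \pi/5m']$) cross the synchronization threshold and snap
every population into near-perfect lock ($R \approx 0.96$) as soon as
$c > 0.02$; the mean fields then turn periodic, rotation surrogates of a
periodic series stay locked (null $\approx$ observed), and no observation
can ever be declared significant — the opposite of the intended behavior.
The range is exposed as `omega_range` in `kuramoto_config()`.

The validation experiment sets $\varepsilon_{interareal} = 0$,
$\varepsilon_{local} = 0.3$, $\varepsilon_{PS} = 0.5$ and sweeps $c$ over
$[0, 0.3]$. All significant interareal 1:2 CFS is then spurious, arising
indirectly from PS plus local CFS. Observations are tested at nominal
$p < 0.01$ with the $2.42\times$ surrogate-mean rule, using 200 rotation
surrogates of the mean-field phase series per observation (pooled mean)
rather than the analytic Rayleigh mean, because mean-field phases are
autocorrelated. An interareal observation counts as a surviving false
positive when it is significant but not excluded by simultaneous
significant local CFS and the corresponding significant 1:1 PS; the
false-positive rate is the fraction of surviving false positives over all
interareal observations (two per simulation), and repetitions of the whole
sweep give its mean and SD. Desk-scale problem sizes used throughout the
tests and the acceptance script: 200 oscillators per population, 20,000
iterations, 64 coupling values, and 5 sweep repetitions; the reference
full-scale experiment uses 500 oscillators, 100,000 iterations (5,000 HF
cycles at the nominal increment $\pi/10$) and 512 coupling values. At the
reduced sample size the surrogate thresholds are about $\sqrt{5}$ higher,
so the local-CFS exclusion leg reaches significance later in the sweep
than at full scale and the scaled false-positive rate is expected to sit
slightly above the full-scale reference while remaining near the nominal
level.

```{r, eval = FALSE}
cfg <- kuramoto_config(n_per_pop = 200L, n_iter = 20000L)
val <- kuramoto_validation(cfg, c_grid = seq(0, 0.3, length.out = 64),
                           reps = 5)
val            # post-pruning FPR, SD across sweeps, unpruned rate
summary(val)   # per-coupling detection curves over c
```

## Topology statistics

Channel-level connectomes collapse to an atlas via `collapse_to_atlas()`,
which keeps both aggregated per-parcel-pair counts (significant edges,
summed strengths, possible connections $N_{C,pot}$) and the individual
significant connection strengths. Two complementary hubness statistics
mark whether a parcel is predominantly the HF or the LF node of its CFC
edges: the *relative directed degree* (in-degree fraction minus out-degree
fraction, both normalized by $N_{C,pot}$) and the permutation-tested
*parcel directionality*, built from the per-pair statistic
$Dir_{LH} = (\sum \mathrm{PLV}_{p_1\,HF} - \sum \mathrm{PLV}_{p_2\,HF})/N$
with pairs below 8 significant connections forced to zero. Significance
pools the two orientations' connection strengths and reassigns them
randomly 1,000 times; the observed magnitude must exceed 95% of permuted
magnitudes. (A one-sided comparison on the observed sign was considered
and rejected: selecting the tail after seeing the sign doubles the false
call rate to ~10% under an orientation-symmetric null, while the
magnitude rule calibrates at the intended ~5%.) The permutations operate
on individual connection strengths — permuting replicated orientation
means would make the observed value an extreme permutation by
construction. Distance profiles use three equal-count Euclidean-distance
bins (stable tie-break); laminar analyses group contacts by gray-matter
proximity index into superficial (0.5–1.2) and deep (−0.3–0), dropping
unassigned contacts rather than imputing. Group comparisons are paired
Wilcoxon signed-rank tests with Benjamini–Hochberg correction at
$q = 0.05$; map comparisons use Spearman correlation and the two-sample
Fisher z test.

## Peak-locked single-pair evidence

For a single channel pair, `detect_events()` finds the largest LF peaks or
troughs (local extrema gated at the 75th envelope percentile with
near-one-cycle separation; the selection criterion is a convention and is
exposed), `epoch_average()` averages 1,000-ms segments time-locked to
them — phase-locked oscillations survive, unlocked activity shrinks as
$1/\sqrt{n}$ — and `tf_zscore()` z-scores the average's Morlet amplitude
against baselines at −500..−200 and 200..500 ms. `amplitude_tf()` averages
HF envelopes over the segments, where PAC appears as LF-periodic stripes.
`sliding_cfc()` estimates CFS or PAC in 200-ms windows with phase
differences concatenated across segments, against a null from equally
many randomly placed segments (100 draws), significant again at
$2.42\times$ the null mean.

## Numerical conventions and edge cases

* wPLI with an identically zero imaginary cross-spectrum returns 0 (no
  evidence of lagged coupling); a degenerate wPLI null SD raises an error
  rather than a silent pass.
* The LF phase is unwrapped before interpolation to HF sample times and
  re-wrapped after, preserving instantaneous frequency across 2$\pi$
  jumps.
* Valid-sample masks intersect before every estimate; $N$ in the PLV
  formulas is the retained-sample count.
* Rotation surrogates exclude the outer 10% of shifts to avoid
  near-identity surrogates; surrogates are drawn from R's seeded RNG, so
  every analysis is reproducible from its seed.
* `detect_artifact_windows()` flags on strict exceedance of mean + 5 SD;
  boundary values never reject.
* Equal-distance ties in `distance_bins()` resolve by original pair
  order (stable sort).
* The corrected-density denominator excludes pruned edges (the literal
  reading); `fixed_denominator = TRUE` restores the alternative.

## Known limitations

The pruning rule is intentionally a lower bound: panel-g-type genuine
coupling inside complete motifs is lost, and nothing here diagnoses
waveform shape (sharpness or asymmetry indices are out of scope). The
synthetic generator does not model realistic volume conduction, so the
minimum-distance and shared-reference exclusions are exercised only
structurally. EDF support covers continuous 16-bit recordings without
EDF+ annotations. The narrowband cache uses R's native serialization
rather than a hierarchical binary container. At desk-scale simulation
sizes the validation model's false-positive rate carries wider sweep-to-
sweep variability (binomial granularity of 1/128 per sweep) than the
full-scale reference.
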