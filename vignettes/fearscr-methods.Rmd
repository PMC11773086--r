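---
title: "Methods: simulating and analysing differential fear conditioning with skin conductance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing differential fear conditioning with skin conductance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fearscr)
```

## The problem this package addresses

In a differential fear-conditioning experiment one neutral stimulus (the
CS+) is paired with an aversive event (the US, here a fearful face plus a
scream) while a second stimulus (the CS-) is never paired. Conditioned
responding is indexed by the skin conductance response (SCR): a phasic rise
in electrodermal conductance, in microsiemens, a second or more after
stimulus onset. The experimental protocol has four phases — habituation,
acquisition, extinction learning and a delayed retention test — and the
scientific questions concern how the CS+/CS- differential emerges, decays
and returns, and whether those dynamics differ between children,
adolescents and adults.

`fearscr` implements the full analysis path as a tested pipeline:
schedule construction, continuous-signal simulation, SCR preprocessing and
trial scoring, head-motion censoring, and the mixed-effects inference
stage. Because no subject-level data are distributed with the design, the
simulator is a first-class component: it generates cohorts with *known,
planted* effects so every downstream stage can be validated by parameter
recovery rather than by eyeballing.

## Protocol generation

`default_protocol()` encodes the task: habituation presents 4 CS+ and 4
CS- for 7 s; acquisition presents 10 of each, the CS+ for 6 s and the CS-
for 7 s, with 8 of the 10 CS+ followed immediately by a 1 s US (80%
reinforcement); extinction and retention present 10 of each for 7 s with
no US. Inter-trial intervals are Gaussian with mean 12 s and SD 1 s, and
stimulus order is pseudorandom with no more than two identical CS types in
a row.

Several details are underdetermined by that description, and the package
fixes them as follows:

* **Which 2 CS+ go unreinforced** is chosen uniformly at random per
  schedule, seedable, and can be pinned via
  `phase_config(reinforced_positions = ...)` for designs that always
  reinforce, say, the first CS+.
* **ITI support.** An unbounded Gaussian occasionally produces
  implausibly short or long fixations, so draws are truncated to
  mean ± 3 SD by resampling (`sample_iti()`). With the default
  parameters all intervals fall in [9, 15] s and the mean is unchanged to
  well under the 0.05 s tolerance we test.
* **Habituation ITIs** follow the same distribution as every other phase;
  there is one ITI rule.
* **Pseudorandomisation** is rejection sampling of uniform shuffles:
  shuffle the 20 labels, accept if the run-length bound holds. This makes
  the distribution over admissible orderings exactly uniform (verified by
  chi-square against the enumerated valid set for small designs), at the
  cost of a bounded retry loop (default 10,000 attempts, then an error —
  which only triggers for infeasible configurations such as 10 vs 0
  trials with a run bound of 2).
* **Orders are regenerated per subject** from per-subject seeds; nothing
  in the design requires a shared order, and regeneration is the more
  conservative choice for group-level inference.
* **Time origin** is phase-relative (first onset at 0 s); absolute
  session timing is out of scope.

## The generative signal model

A recording is

$$y(t) = \mathrm{tonic} + \mathrm{drift}\cdot t +
  \sum_{e} A_e\, k(t - t_e) + \varepsilon(t),$$

where $k$ is a Bateman kernel — the standard phasic sudomotor impulse
response — normalised to unit peak:

$$k(t) \propto e^{-t/\tau_d} - e^{-t/\tau_r}, \qquad
  \tau_r = 0.75\,\mathrm{s},\; \tau_d = 2\,\mathrm{s},\;
  \mathrm{latency} = 1\,\mathrm{s}.$$

These constants place the response peak at
$t^\* = \mathrm{latency} + \ln(\tau_d/\tau_r)\,\tau_r\tau_d/(\tau_d-\tau_r)
\approx 2.18$ s after onset, comfortably inside the 1–5 s scoring window.
The tonic level defaults to 5 µS (log-normally varied across subjects),
drift is a small linear trend, and $\varepsilon$ is white measurement
noise (0.02 µS SD). Recordings include a 10 s pre-roll before the first
event and a 15 s tail, as real acquisition does; this also keeps filter
edge transients away from every scored window.

Amplitudes $A_e$ are zero-inflated log-normal: with probability
`p_nonresponse` (default 0.15) a trial yields nothing; otherwise
$A_e = \exp(\mu + b_i + \epsilon)$ with subject intercept
$b_i \sim N(0, 0.4^2)$ and trial noise SD 0.4. The deterministic part
$\mu$ encodes the planted psychology on the log scale:

| component | default | meaning |
|---|---|---|
| `base_log_uS` | log 0.4 | modal CS response, µS |
| `habituation_slope` | −0.06/trial | within-phase response decline |
| `acq_diff_slope` | +0.10/trial | CS+ differential growth in acquisition |
| `ext_diff_start`, `ext_diff_slope` | 0.8, −0.08/trial | differential at extinction start and its decay |
| `ret_early_boost`, `ret_diff` | 0.5, 0.1 | return of fear on the first two retention trials |
| `us_log_uS`, `us_slope` | log 1.2, −0.08/trial | US response level and habituation |
| `group_offsets` | child +0.25, adult −0.10 | children respond more strongly overall |

No group difference is planted in retention, so the retention group
regression doubles as a null calibration. The zero-inflated log-normal was
chosen deliberately: it reproduces the right-skewed, zero-heavy amplitude
distributions that motivate square-root transforming SCR in the first
place.

Ratings come from a proportional-odds generative model: thresholds
(0.5, 2.0, 3.5, 5.0) on a latent logistic scale, a CS+ effect of 0.3 at
baseline rising by 2.5 after acquisition and 1.0 after extinction, and a
subject intercept with SD 1.2. Head motion is a six-parameter random walk
(steps 0.05 mm / 8·10⁻⁴ rad per volume at motion level 1) plus occasional
abrupt movements; group motion levels (child 1.0, adolescent 0.45, adult
0.15) produce the child > adolescent > adult censoring gradient seen in
developmental imaging without matching any particular cohort's counts.
Awareness probabilities default to 0.79/0.85/0.95 and covariates (SES, US
sound level, days between sessions) are drawn around the observed group
means of the motivating study design.

The native sampling rate defaults to 1000 Hz so that the 10 ms median
window and the downsampling step are exercised non-trivially; tests that
do not probe the filters use 250–500 Hz to stay fast.

**What the simulator does not emulate:** overlapping/compound SCRs that
would require deconvolution, respiratory and ECG artifacts, electrode
drift or detachment, non-stationary tonic arousal, and any dependence
between motion and the electrodermal channel. Passing recovery tests on
synthetic cohorts therefore demonstrates that the *pipeline machinery* is
correct and calibrated — not that the preprocessing choices are optimal
for any particular real recording.

## The preprocessing chain

`score_phase()` applies, in fixed order: a 10 ms sliding median; a
first-order Butterworth band-pass (0.03–5 Hz); downsampling to 100 Hz;
baseline-corrected peak extraction per event (max over [onset+1 s,
onset+5 s) minus the mean over [onset, onset+1 s)); the amplitude rules
(values below 0.01 µS become 0, values above 5 µS become missing); and a
square-root transform. Numerical conventions:

* **Zero-phase filtering.** The band-pass is applied forward-backward.
  A single-pass first-order filter would delay the waveform by tens of
  milliseconds in a frequency-dependent way, shifting peaks relative to
  their event-locked windows; zero-phase application avoids that and its
  gain is the squared magnitude response, which our tests check against
  the closed form $|H(f)|^2 = (1 + W(f)^2)^{-1}$,
  $W = (f^2 - f_{lo}f_{hi})/(f(f_{hi}-f_{lo}))$. Single-pass application
  remains available (`zero_phase = FALSE`). The recursion runs in
  compiled code with reflective padding of three low-edge time constants.
* **Median window parity.** `round(window × rate)` is forced odd (+1 if
  even) so the window is centred; edges are handled by reflection. The
  implementation is tested for exact elementwise agreement with a naive
  sliding-median oracle.
* **Downsampling** is plain decimation for integer rate ratios (the 5 Hz
  band edge is far below the 50 Hz target Nyquist, so no extra
  anti-aliasing is needed) and linear interpolation otherwise.
* **Sample windows** are closed-open in samples with the onset mapped to
  the first sample at or after the event time; scores are therefore
  invariant to the recording's start-time offset.
* **Negative peaks** (baseline above the window maximum) need no special
  case: the floor rule maps them to 0.
* **Visual inspection** of recordings is replaced by automated QC flags
  (flat-line, railing, gaps); flagged recordings are excluded only when
  `exclude_flagged = TRUE`, so the default pipeline is fully
  deterministic.
* The peak is the window maximum minus the pre-window baseline mean (not
  a within-window trough-to-peak rise), and US-locked responses use the
  same windows as CS-locked ones.

With noise-free single-event input the chain returns the planted
amplitude times a constant attenuation factor (~0.95 with the default
kernel), constant across amplitudes — the residual is the band-pass
response to the kernel's slow tail, and the tests bound it at 5%.

## Motion QC

Framewise displacement is the absolute sum of volume-to-volume parameter
differences, rotations converted to arc length on a 50 mm sphere (the
conventional radius; configurable), with FD of the first volume defined
as 0. Censoring uses a strict threshold (FD > 0.9 mm) and also emits the
one-indicator-regressor-per-censored-volume matrix used by scrubbing-style
first-level models. BOLD modelling itself is out of scope.

## Statistical models

Phase-wise SCR models are Gaussian random-intercept LMMs fitted by REML
(`lmerTest`), outcome √SCR, fixed effects CS × trial with CS- as
reference and trial as a raw 1–10 integer covariate (centring is
available but off by default, matching the within-phase trial-index
reading of the design). P-values use Satterthwaite degrees of freedom.
Group analyses add age group and all interactions, with the reference
group switchable between adolescents (adolescent-dip contrasts) and
children (progressive-development contrasts) — the two codings are exact
reparameterisations, which the tests verify via identical likelihoods and
fitted values. Extinction-retention is additionally summarised per
subject as the mean √SCR difference of the first two CS+ minus the first
two CS- trials, regressed on group by OLS; a subject's score requires all
four early trials by default (available-case means are an option). US
habituation is the same LMM machinery on US-locked responses with
trial × group effects.

Rows with missing outcomes are dropped listwise. Boundary (singular)
subject variance is reported as converged with a note; genuine optimizer
failures are flagged, never silently replaced by a fallback. No multiple-testing
correction is applied anywhere, and every printed table says so.

Ordinal 1–5 fear ratings are analysed with a cumulative-link
(proportional-odds) mixed model: logit link, four ordered thresholds,
treatment coding with CS- and the post-acquisition rating point as
references, and a Gaussian subject random intercept. Because no installed
package provides this model class, `fit_clmm()` implements it directly:
the marginal likelihood integrates the random intercept out by *adaptive*
Gauss–Hermite quadrature — nodes are centred and scaled at each subject's
conditional mode, found by damped Newton iterations on the integrand
(15 nodes by default; 1 node gives the Laplace approximation) — and is
maximised by BFGS from deterministic starting values (a `MASS::polr` fit
without random effects, and log σ = 0). Thresholds are parameterised as
cumulative exponentials to keep them ordered. Wald z tests come from the
numerical Hessian at the optimum. With σ fixed at 0 the fit reproduces
`MASS::polr` to better than 10⁻³ — that oracle equivalence, plus recovery
of the generative parameters from simulated cohorts, is how the
implementation is validated. All fits are deterministic given the data.

Contingency awareness is the strict rule: aware iff the participant
reports that the CS+ screamed and the CS- did not; any missing answer
yields a missing classification. Sensitivity analyses refit the base
models adding SES and US sound level as covariates, the retention models
adding days between sessions, and all models on the aware-only subset,
then tabulate sign and significance stability against the base fits.

## Problem sizes and runtime choices

The test suite calibrates the CS-term type-I error on 1,000 null
simulations of 40-subject cohorts drawn directly from the mixed model
(bypassing the signal chain, which is validated separately), checks
parameter recovery on 200 replicates, and runs one full 120-subject
end-to-end cohort (36/40/44 per group, 1000 Hz native rate) through
simulation, preprocessing, and every model. The full cohort run completes
in roughly three minutes on a single core; smaller determinism and
structure checks use 6-subject cohorts at 250 Hz. These sizes are the
package's chosen trade-off between Monte-Carlo precision and a test suite
that runs everywhere in minutes.

## Known limitations

* The generative parameters are plausible for developmental
  electrodermal work but are not calibrated to any real dataset; absolute
  effect sizes from the simulator should not be compared to published
  coefficients.
* The preprocessing stage scores each event independently; closely
  spaced responses superpose and the later peak inherits part of the
  earlier tail (mitigated, not removed, by the band-pass).
* The CLMM assumes proportional odds and a single random intercept;
  random slopes and scale effects are not implemented.
* Satterthwaite approximations can be anticonservative for very small
  cohorts; the calibration suite covers the 40–120 subject range the
  design targets.
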