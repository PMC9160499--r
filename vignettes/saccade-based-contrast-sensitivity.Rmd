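---
title: "Saccade-based adaptive contrast sensitivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Saccade-based adaptive contrast sensitivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saccadecs)
```

## The measurement problem

Contrast sensitivity (CS) in the peripheral visual field is classically
measured with a subjective forced-choice report. An objective alternative
exploits reflexive saccades: a suddenly appearing peripheral target evokes
an involuntary eye movement toward it, so the *occurrence and direction*
of that movement — read live from an eye tracker — can replace the button
press. `saccadecs` implements that test as a closed loop between an
adaptive Bayesian procedure choosing stimulus contrasts and a response
classifier scoring gaze streams, together with the offline analysis that
turns trial outcomes into a contrast sensitivity function (CSF), and a
statistical simulated observer so the entire chain can be validated
without human participants or hardware.

## The psychometric model

The probability of a correct (or "detected") response at Michelson
contrast $x \in (0, 1]$ is the cumulative Weibull in log contrast,

$$\Psi(x; m, w, \gamma, \lambda) = \gamma + (1-\lambda-\gamma)
\left[1 - e^{\log(0.5)\, e^{\,c (\log x - m)/w}}\right],
\qquad c = \log(-\log 0.05) - \log(-\log 0.95) \approx 4.067 .$$

$m$ is the threshold — the log contrast at which the base
($\gamma=\lambda=0$) curve crosses $0.5$ — and $w$ the log-contrast span
between the base curve's 5 % and 95 % points; the constant $c$ makes that
interpretation of $w$ exact, and the slope used by the adaptive procedure
is $s = c/w$ (a *narrower* curve is *steeper*, which is why the
relation is a reciprocal and not a product). The guess rate is fixed by
the response channel: $\gamma = 0$ for yes/no saccade scoring, $\gamma =
0.25$ for the four-alternative (4AFC) orientation report. All logs inside
the model are natural; conversion to sensitivity happens at the very end:
$CT = e^m$, $CS = 1/CT$, and reporting uses $\log_{10} CS = -m/\ln 10$.

Assumptions worth stating: responses are conditionally independent
Bernoulli trials given the contrast, the lapse rate is small and
contrast-independent, and a single stationary $(m, w)$ pair describes a
location for the duration of a session.

## The adaptive procedure

Each visual-field meridian (0°, 90°, 180°, 270° in the screen frame) runs
its own QUEST+ instance: a posterior mass over a discretised
threshold × slope grid,

- thresholds: the logs of 15 contrast levels spaced geometrically from
  0.00024 to 0.66 (so uniformly in log contrast);
- slopes: 0.5 to 5.5 in steps of 0.5 (11 values);
- asymptotes fixed, never estimated: $\gamma$ by mode as above,
  $\lambda = 0.02$ (a conventional lapse default — only threshold and
  slope have published parameter spaces, and 30 trials per location
  cannot identify asymptotes);
- prior: uniform over the 165 cells (no prior information is assumed);
- stimulus domain: the same 15 contrasts that form the threshold space.

After each trial the posterior is multiplied by the outcome likelihood
$\Psi$ (correct) or $1-\Psi$ (incorrect) and renormalised. The next
contrast minimises the *expected posterior Shannon entropy*, with the
outcome probability marginalised over the current posterior; ties break
deterministically to the lowest contrast so that a degenerate posterior
cannot produce machine-dependent behaviour. Stopping is a fixed trial
budget (30 per location), never an entropy criterion, so every location
yields the same amount of data. The running posterior-mean threshold
exists for monitoring; published estimates always come from the offline
maximum-likelihood refit of the aggregated rates.

## Scoring saccades from gaze streams

Gaze is sampled at 1 kHz. Fixation is enforced inside a 1° radius around
the screen centre; leaving it requires *strictly* exceeding the radius
(so "exactly at 1°" is well defined as held). At the first boundary
crossing the saccade direction is
$\beta_g = \mathrm{atan2}(y_{eye}-y_{center},\, x_{eye}-x_{center})$,
computed in the raw screen-pixel frame (y grows downward). Because the
target meridian is expressed in the same frame, the axis convention
cancels in the acceptance test: a response is correct when the circular
distance between $\beta_g$ and the meridian is at most 22.5° (boundary
inclusive — the four 45°-wide cones then tile exactly half the circle and
never overlap). Only the first crossing is scored; later samples are
ignored. A blink (invalid samples) inside the window signals a repeat.
Mapping of screen meridians to visual-field labels (right eye tested:
0° = temporal, 90° = inferior, 180° = nasal, 270° = superior) is applied
at reporting time only.

The response window is the 500 ms presentation limit plus a post-stimulus
grace period (default 500 ms), since the orientation report was permitted
after saccade execution or stimulus expiry; whether late saccades counted
as correct in the original procedure is not documented, so the grace
period is a configurable parameter (`grace_ms`) rather than a constant.

## Trial scheduling

Each condition (eccentricity 2.0°, 6.5° or 11.0°; spatial frequency from
0.8/1.4/2.2/4.3 cpd, plus 7.2 cpd at 6.5° and 7.2 + 10.7 cpd at 2.0°)
receives 120 target presentations with exactly 30 per meridian *and* 30
per orientation. Joint 4 × 4 balance is impossible (120/16 = 7.5), so the
scheduler balances the margins: a base table of 7 per cell plus two
independent random permutation matrices gives integer cell counts with
all margins 30, and the trial list is then fully shuffled. Saccadic-mode
sessions interleave 12 catch trials (no target) at uniformly random
positions — 132 trials in total; catch trials follow the same workflow but
never touch the adaptive procedure. Fixation durations are drawn
uniformly from 500–650 ms (the source range without a stated
distribution; uniform is the natural choice). After a blink the
interrupted trial is re-queued *with the same stimulus parameters* and
the remaining order is reshuffled. Non-saccadic sessions carry no catch
trials and no saccade channel; whether blink repeats apply there is
undocumented, so the package repeats in both modes for symmetry.

## The simulated observer

The observer emulates the statistical structure the test relies on:

- **Detection.** Ground-truth thresholds per meridian come either from a
  direction-specific log-parabola CSF (inverted to
  $m = -\ln 10 \cdot \mathrm{CS}_{\log}$) or from fixed values — the
  latter is what parameter-recovery studies use to place the truth on the
  QUEST+ grid. Default CSFs are shaped like the known visual-field
  anisotropy: nasal ≈ temporal > superior > inferior, with peak
  sensitivity and peak frequency decreasing with eccentricity.
- **Saccade latency.** $t = t_0 + g\, e^{-x/c_0} + \varepsilon$, with
  defaults $t_0 = 200$ ms, $g = 900$ ms, $c_0 = 0.1$,
  $\varepsilon \sim N(0, 150^2)$ ms. The form is a modelling choice (only
  the *direction* of the contrast dependence is established); the
  defaults deliberately push near- and sub-threshold latencies beyond the
  response window occasionally, so faint targets are sometimes seen but
  not saccaded in time — the mechanism proposed for the saccade channel's
  slightly lower measured CS. Setting $g = 0$ yields a latency-neutral
  observer.
- **Direction noise.** Gaussian, $\sigma = 5°$ by default, keeping almost
  all true detections inside the ±22.5° cone.
- **False positives.** On catch trials a fixational excursion beyond 1°
  occurs with per-trial probability 0.043 (the observed human rate), in a
  uniformly random direction.
- **4AFC answers.** If the orientation was perceived (Weibull with
  $\gamma = 0$), the answer is correct unless a lapse occurs; otherwise a
  uniform guess (25 % correct). The same perception draw drives both
  channels within a trial, which is what makes the latency loss a
  *saccade-specific* penalty.
- **Blinks.** Per-trial probability 0.02, triggering the repeat path.

Two gaze channels expose the same behaviour: `"events"` emits the exit
event analytically (fast; used for replicate studies), `"trace"` expands
each event into a 1 kHz synthetic trace — fixational jitter clamped inside
0.8°, a 40 ms constant-velocity excursion, invalid-sample runs for
blinks — and scores it through the real classifier. The trace channel
draws its jitter from an RNG stream isolated per (seed, attempt), so both
channels see identical observer behaviour; the test suite asserts their
verdicts agree except possibly at 1 kHz discretisation of the window
edge.

What the simulator does *not* emulate — and what passing tests therefore
cannot show about real data: saccade dynamics (main sequence, curvature,
landing-point scatter), microsaccades and drift structure, attention and
fatigue drifts across a session, eye-tracker noise and calibration error,
and any contrast dependence of the *decision* to saccade beyond the
Weibull detection model. Recovery rates measured here are statements
about the estimation chain under its own assumptions, not about clinical
performance.

## Offline fitting: numerical choices

**Psychometric fits** maximise the binomial likelihood over
$(m, \log w, \lambda)$ with L-BFGS-B, $\lambda \in [0, 0.1]$, $\gamma$
fixed by mode, and a deterministic 15-point multistart (five threshold
quantiles × three widths); probabilities are clipped at $10^{-10}$ before
taking logs. Duplicate contrast rows are merged first, which makes the
fit invariant to row splitting and ordering. Degenerate tables (all
correct, or all at the guessing floor) are flagged and the threshold is
clamped to the sampled contrast range rather than extrapolated.

**CSF fits** minimise squared error of the log-parabola in log10-SF
space. A quadratic regression supplies the starting vertex (closed form:
$u_0 = -b/2c$, $\beta_0 = 2\sqrt{\log_{10}2 / (-c)}$), refined under
bounds $SF_{max} \in [\min SF/2,\, 2\max SF]$, $\beta \in (0, 4]$,
$\gamma_{max} \in [1, 10^4]$ with additional deterministic starts. The
bandwidth $\beta$ is taken in log10-cpd units with the half-height at
$\beta/2$ — the literal reading of the fitting function; octave
conventions differ only by a constant factor. No low-frequency truncation
is applied. Flat input data push $\beta$ to its upper bound and are
flagged as non-unique. Mean CSFs average $\log_{10} CS$ across subjects
per frequency before fitting, excluding (with a warning) subjects missing
a frequency.

**Agreement statistics** use the sample ($n-1$) SD and the conventional
1.96 multiplier for Bland–Altman limits of agreement (no multiplier is
documented in the source analyses).

## Problem sizes in the tests and acceptance script

The stochastic suites run at the study's own budget of 30 trials per
location: 200 replicates for QUEST+ threshold-cell recovery, 100
full closed-loop sessions for end-to-end $\log_{10} CS$ recovery, 16
replicate sessions for the latency-mechanism direction, 10,000 catch
trials for the false-positive rate, and a four-participant simulated
cohort over all 15 eccentricity × frequency conditions and both modes for
the correlation/Bland–Altman machinery. These sizes keep the whole
analysis within a few minutes on one CPU while leaving the binomial
standard errors well below the asserted margins.

## Known limitations

- The threshold grid's floor and cap (0.024 %–66 %) clip extreme
  observers; fits near the boundary are flagged but still reported.
- With 30 trials per location the slope and lapse are weakly identified;
  only the threshold (and hence CS) is a reliable per-session output.
- The latency model's parameters are qualitative placeholders — they
  reproduce a mechanism, not measured latency distributions.
- The log-parabola vertex estimator is a ratio of noisy quantities: under
  heavy noise its mean is drawn toward the search bounds (the suite
  asserts the median instead).
- Correlations computed on small simulated cohorts are lower than those
  of a real multi-eccentricity human study simply because between-subject
  variance is a free simulation parameter; they exercise the machinery,
  not the effect size.
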