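# saccadecs

Objective measurement of peripheral contrast sensitivity (CS) with
reflexive saccades, as a fully simulation-testable closed loop.

Standard CS tests require a subjective report ("which orientation did you
see?"). When a low-contrast target appears in the peripheral visual field,
however, observers also launch a reflexive, visually-guided saccade toward
it — and the occurrence of that saccade can be read from an eye tracker and
used as an *objective* "seen" response. `saccadecs` implements the complete
measurement and analysis chain for such a test:

- **Adaptive contrast placement (QUEST+).** Each of the four visual-field
  meridians (0°, 90°, 180°, 270°; nasal/temporal/superior/inferior) runs an
  independent Bayesian grid procedure over threshold × slope, with the
  threshold space spanning 15 contrast levels from 0.024 % to 66 %
  (log-spaced) and slopes 0.5–5.5 in steps of 0.5. The next stimulus
  minimises the expected Shannon entropy of the posterior.
- **Psychometric model.** The cumulative Weibull in log-contrast,

  Ψ(x; m, w, γ, λ) = γ + (1 − λ − γ)\[1 − e^{log(0.5)·e^{c(log x − m)/w}}\],

  with c = log(−log 0.05) − log(−log 0.95) ≈ 4.07, threshold *m* (the 50 %
  point of the base curve), width *w* (log-contrast span between the 5 %
  and 95 % points; slope s = c/w), guess rate γ (0 for saccade scoring,
  0.25 for the 4AFC keyboard task) and lapse rate λ.
- **Saccade scoring from gaze streams.** Fixation is enforced in a 1°
  window; at the first boundary crossing the saccade direction
  β_g = atan2(y_eye − y_center, x_eye − x_center) is computed, and the
  response is correct when β_g lies within ±22.5° of the target meridian.
- **Trial scheduling.** 120 target presentations per condition, exactly 30
  per meridian and 30 per orientation (45/90/135/180°), plus 12 hidden
  catch trials (no target) in saccadic mode — 132 trials in total; blinks
  re-queue the interrupted trial and reshuffle the remaining order.
- **Simulated observer.** Weibull detection driven by direction-specific
  log-parabola CSFs, contrast-dependent saccade latency (slow saccades to
  faint targets can overrun the response window), fixational false
  positives on catch trials (default rate 4.3 %), 4AFC guessing and
  blinks. It stands in for the participant *and* the eye tracker, so every
  stage is testable without human data.
- **Offline analysis.** Maximum-likelihood Weibull fits of per-contrast
  response rates, CT = e^m, CS = 1/CT, log₁₀(CS), and the log-parabola CSF

  CS(SF) = log₁₀ γ_max − log₁₀(2)·\[(log₁₀ SF − log₁₀ SF_max)/(β/2)\]²,

  per subject and as cross-subject means.
- **Method agreement.** Pearson correlations and Bland–Altman limits of
  agreement between the three response channels (saccade-in-saccadic,
  keyboard-in-saccadic, keyboard-in-non-saccadic).

## Worked example

```r
library(saccadecs)

cond    <- condition_spec(6.5, 2.2, mode = "saccadic")  # 6.5 deg, 2.2 cpd
obs     <- default_observer(6.5)
session <- run_session(cond, obs, seed = 42)
session
#> Session (saccadic, ecc 6.5 deg, 2.2 cpd): 132 trials done
#>   (120 targets, 12 catch, 1 false positives), 1 repeats

analyze_session(session)[, c("vf_label", "channel", "m", "log_cs")]
#>   vf_label  channel     m log_cs
#> 1 temporal  saccade -3.33   1.45
#> 2 temporal keyboard -3.57   1.55
#> 3 inferior  saccade -2.88   1.25
#> 4 inferior keyboard -2.89   1.25
#> 5    nasal  saccade -3.17   1.37
#> 6    nasal keyboard -3.04   1.32
#> 7 superior  saccade -3.24   1.41
#> 8 superior keyboard -3.74   1.62
```

The session runs the full closed loop: 132 scheduled trials, one QUEST+
instance per meridian (30 updates each — catch trials never update), and
per-channel Weibull fits. `m` is the fitted log-contrast threshold;
`log_cs = −m/ln 10` is the log₁₀ contrast sensitivity at that location
(1.45 ⇒ the observer detects ≈ 3.5 % contrast at the temporal meridian).

Fitting a CSF across spatial frequencies:

```r
fit_csf(c(0.8, 1.4, 2.2, 4.3, 7.2), c(1.28, 1.36, 1.38, 1.21, 0.82))
#> CSF fit over 5 points (RSS 0.003843):
#>   Log-parabola CSF: peak sensitivity 25.3 (log10 1.40) at 1.67 cpd,
#>   bandwidth 0.93
```

A command-line surface wraps the same functions
(`simulate-session`, `simulate-study`, `generate-observer`, `fit`,
`report`):

```sh
Rscript $(Rscript -e 'cat(system.file("cli/saccadecs.R",
                                       package="saccadecs"))') \
    simulate-session --mode saccadic --eccentricity 6.5 --sf 2.2 \
    --seed 3 --out outdir
```

File formats (versioned CSV/JSON) are documented with examples in
`inst/FORMATS.md`.

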