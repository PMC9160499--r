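# File formats

All tabular artifacts are plain CSV with a `#` comment header carrying the
format version (`saccadecs-v1`) and, where applicable, the generating
seed. Nested state is JSON. Units everywhere: angles in degrees, times in
milliseconds, contrasts as linear proportions (0.66 = 66 %), sensitivities
as log10 values.

## Gaze trace CSV (`write_gaze_csv` / `read_gaze_csv`)

One row per 1 kHz sample from trial onset; `valid = FALSE` marks
blink/track-loss samples. Long files may add a `trial_id` column.

```
# saccadecs gaze trace, format saccadecs-v1
"t_ms","x_px","y_px","valid"
0,959.4,540.7,TRUE
1,960.2,539.9,TRUE
2,1103.5,612.1,TRUE
```

## Session trial log CSV (`write_session_csv` / `read_session_csv`)

One row per trial attempt. `status` is `done` or `repeated` (blink);
`is_catch` rows have no meridian/orientation/contrast; `saccade_correct`
is empty in non-saccadic mode, `keyboard_correct` is the 4AFC answer.

```
# saccadecs-v1 session log, seed=3
"attempt","trial_id","meridian_deg","orientation_deg","is_catch","contrast","fixation_ms","exited","exit_time_ms","beta_g","saccade_correct","keyboard_correct","status"
1,1,270,45,FALSE,0.0126,587.87,TRUE,286,272.2,TRUE,TRUE,"done"
```

## QUEST+ state JSON (`quest_to_json` / `quest_from_json`)

Grids, fixed asymptotes, stimulus domain, the posterior as a flat
row-major list (threshold-major), and the trial count; supports session
resume and audit.

```json
{"format":"saccadecs-v1","thresholds":[-8.335,...],"slopes":[0.5,...],
 "gamma":0,"lam":0.02,"stimulus_domain":[0.00024,...],
 "posterior_row_major":[0.0061,...],"trial_count":30,"location_label":"0"}
```

## Observer config JSON (`write_observer_json` / `read_observer_json`)

Either per-meridian log-parabola CSFs (`csf`, keys `"0","90","180","270"`)
or fixed log-contrast thresholds (`m_fixed`), plus slope, lapse, guessing,
latency-model, false-positive and blink parameters.

```json
{"csf":{"0":{"gamma_max":26.3,"sf_max":1.5,"beta":2.5},...},
 "true_slope":3,"lapse":0.02,"guess_4afc":0.25,
 "latency_base_ms":200,"latency_contrast_gain_ms":900,"latency_c0":0.1,
 "latency_sd_ms":150,"dir_noise_sd_deg":5,"fp_rate":0.043,
 "blink_rate":0.02,"format":"saccadecs-v1"}
```

## Study manifest JSON (`write_manifest_json`)

Master seed plus one record per session:

```json
{"format":"saccadecs-v1","master_seed":1,
 "sessions":[{"participant":1,"eccentricity_deg":2,
              "spatial_freq_cpd":0.8,"mode":"saccadic",
              "session_seed":159073}, ...]}
```

## Sensitivity table CSV (`write_cs_csv`)

Tidy per-cell estimates, one row per
(participant, eccentricity, spatial frequency, meridian, method):

```
# saccadecs-v1 sensitivity table, seed=2
"participant","eccentricity_deg","spatial_freq_cpd","meridian_deg","vf_label","method","log_cs"
1,6.5,2.2,0,"temporal","saccade_saccadic",1.447
```
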