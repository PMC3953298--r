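# gnrhpulse

Kinetic modelling of pulsatile GnRH signalling to ERK and ERK-driven
transcription.

Gonadotropin-releasing hormone (GnRH) is secreted as pulses, and pituitary
gonadotropes decode pulse *frequency*, *width* and *amplitude* into graded
transcriptional output through the ERK cascade. `gnrhpulse` implements a
ten-species ODE model of this pathway and the in-silico experiments used to
study pulse decoding:

- square-wave GnRH input `G(t) = p` for `t mod Π < t_p`, with washout and
  MEK-inhibitor interventions;
- receptor occupancy (`HR`), G-protein consumption (`GQ`), effector
  production (`E`), algebraic Michaelis–Menten MEK activation
  `ppMEK = MEK_tot·E/(K_MM,MEK + E)`;
- distributive dual ERK (de)phosphorylation (fluxes v1–v5), ERK shuttling
  between cytoplasm and nucleus (amount-conserving, volume ratio
  `C_cn = 3`), negative feedback of active ERK on the effector;
- a saturating transcription tier (`TF1`, `TF1DT`);
- integrated-response (AUC above baseline) analyses over pulse frequency,
  width, amplitude and receptor number;
- a rank-selection genetic algorithm for the historically fitted parameter
  subset, and a synthetic-data generator emulating ERK2-GFP
  nuclear:cytoplasmic imaging and dose–response readouts.

The observables are the measurement-facing quantities: whole-cell ppERK
(volume-weighted), the nuclear:cytoplasmic ERK ratio (0.8 at rest), and
ppMEK.

## A worked example

```r
library(gnrhpulse)
params <- gnrh_parameters()          # published best-fit values (uM, min)

## a single 1-min pulse of 1e-7 M GnRH, washed out, watched for 30 min
tr <- simulate_protocol(params, single_pulse(1e-7, width = 1, horizon = 30),
                        output_step = 0.1)
tr$time[which.max(tr$pperk_wholecell)]
#> [1] 4
max(tr$pperk_wholecell)
#> [1] 0.3969409
post_pulse_fraction(params, width = 1, amplitude_molar = 1e-7, horizon = 30)
#> [1] 0.9796681
```

Whole-cell ppERK peaks at 4 min — three minutes *after* the hormone is
gone — and 98% of the integrated ppERK response occurs after the pulse:
MEK saturation lets a brief occupancy transient drive a much longer
kinase response. Terminating the same pulse with a MEK inhibitor instead
of washout cuts the downstream transcript accordingly:

```r
termination_ratio(params, widths = c(1, 5, 15, 30, 60),
                  amplitude_molar = 1e-7, total_time = 360)$ratio
#> [1] 0.01896943 0.77445885 0.92712552 0.95591155 0.96951743
```

The inhibitor/washout transcript ratio is far below 1 for a 1-min pulse
(nearly all of its transcriptional effect depends on post-pulse ERK
activity) and approaches 1 by 60-min pulses.

Frequency decoding is summarized by `frequency_response()`, which
integrates every measure along the cascade over a grid of pulse intervals
and normalizes to the constant-stimulation maximum:

```r
fr <- frequency_response(params, width = 1,
                         intervals = c(1, 15, 30, 45, 60, 90, 120, 240),
                         amplitude_molar = 1e-7, horizon = 480)
subset(fr, interval_min == 45 & measure %in% c("HR", "E", "TF1DT"))
#>    measure width_min interval_min amplitude_uM R0_uM frequency_per_h       auc auc_normalized
#> 23      HR         1           45          0.1   0.1        1.333333  1.137806     0.02395381
#> 24       E         1           45          0.1   0.1        1.333333 10.810212     0.23378843
#> 28   TF1DT         1           45          0.1   0.1        1.333333 29.040641     0.18242707
```

At 45-min intervals the input duty cycle is 1/45 ≈ 2.2%: receptor
occupancy integrates to 2.4% of its constant-stimulation value (it tracks
the input), the effector to 23% and the transcript to 18% — robustness to
pulse fragmentation grows moving down the cascade.

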