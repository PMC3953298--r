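# Example configuration: 5-min pulses of 1e-7 M GnRH at 60-min intervals
# for 8 h, with two parameter overrides. Unlisted parameters take their
# default (published best-fit) values.
parameters:
  R0: 0.1
  GQ_tot: 1.0
protocol:
  amplitude_molar: 1.0e-7
  width: 5
  interval: 60
  horizon: 480
options:
  output_step: 0.5
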