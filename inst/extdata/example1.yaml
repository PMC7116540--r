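# Worked example: moderate obstructive sleep apnea-hypopnea trial.
# Control-arm AHI anticipated in [15, 30] events/hour; a 15% reduction at
# the lower end (delta = 2.25) is the target effect.
schema: 1
problem:
  lambda0: [15.0, 30.0]
  lambda1: [15.0, 30.0]
  delta: 2.25
  alpha: 0.05
  beta: 0.2
  lambda_ess: 15.0
mode: single_plan
engine: exact
K: 1
pi_A: [0.2]
pi_R: [0.05]
n_cap: 100
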