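seed: 1
design:
  n_participants: 6.0
  trials_per_condition: 30.0
  framing: selection
  conditions:
  - exclusive
  - inclusive
  n_products: 200.0
  conflict_coefs:
    b0: 2.4
    b1: 0.3
    b2: 1.2
    b3: -0.12
    b4: -0.45
    b5: -0.8
  conflict_sd: 0.6
  keep_temperature: 0.8
  bad_participants: []
params_by_condition:
  exclusive:
    k: 1.0
    m: 0.8
    g: 0.25
    c: 0.8
    a: 3.0
    beta: 0.25
    dt: 0.001
    t_max: 10.0
    collapse: exponential
  inclusive:
    k: 1.0
    m: 0.3
    g: 0.25
    c: 0.8
    a: 3.0
    beta: 0.25
    dt: 0.001
    t_max: 10.0
    collapse: exponential
  low_urgency:
    k: 1.0
    m: 0.8
    g: 0.25
    c: 0.8
    a: 3.0
    beta: 0.25
    dt: 0.001
    t_max: 10.0
    collapse: exponential
  high_urgency:
    k: 1.0
    m: 0.8
    g: 0.25
    c: 0.8
    a: 1.8
    beta: 0.55
    dt: 0.001
    t_max: 10.0
    collapse: exponential
log_rt: no
conflict_covariates: no
grid:
  m:
  - 0.3
  - 0.55
  - 0.8
  a:
  - 1.8
  - 2.4
  - 3.0
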