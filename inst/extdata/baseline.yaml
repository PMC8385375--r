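# Baseline configuration: the default parameter set of the damage-response
# population models. Every omitted key falls back to these values.
params:
  N0: 20000
  Nmax: 100000
  gamma1: 0.1
  gamma_ad: 0.35
  gamma_r: 0.0
  delta: 0.02
  alpha_m: 0.5
  sigma: 0.5
  mu_a: 1.0
  beta_m: 0.5
  p: 3.0
  mu_b: 3.886
environment:
  kind: stable
experiment:
  model: ode
  replicates: 10000
  base_seed: 1
  t_max: 500
  n_nodes: 200
output:
  dir: "."
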