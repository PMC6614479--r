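# Default lacdfe configuration.
# Concentrations and rates are in consistent arbitrary units; fitness is in
# benefit units (lactose metabolized per unit time). These numeric values are
# package defaults, not taken from any published parameter table; they are
# chosen so the model is well-posed over the whole mutable box and has a
# nontrivial fitness optimum (see the methods vignette).
fixed:
  kd1: 0.02        # LacZ degradation (1/time)
  kd2: 0.02        # LacY degradation (1/time)
  kd3: 0.02        # LacI degradation (1/time)
  K: 10            # half-saturation of LacI-lactose binding (conc)
  k1: 1            # maximal lactose influx per LacY (1/time)
  k2: 10           # influx half-saturation (conc)
  k3: 1            # maximal lactose metabolism per LacZ (1/time)
  k4: 10           # metabolism half-saturation (conc)
  lac_out: 100     # extracellular lactose (environment, conc)
cost:
  alpha: 20                      # cost per protein molecule per unit time
  alpha_z: 0.02                  # (1023/1023) * kd1
  alpha_y: 0.0081524926686217     # (417/1023) * kd2
  alpha_i: 0.0070381231671554     # (360/1023) * kd3
mutable:
  bas1: {min: 0, max: 0.5}       # basal lac-promoter activity
  bas2: {min: 0.001, max: 2}     # basal lacI-promoter activity
  Ky: {min: 0, max: 20}          # maximal-promoter-activity numerator
  Kmy: {min: 0.01, max: 50}      # promoter-activity half-saturation
  Kt: {min: 0.01, max: 1}        # LacY:LacZ translational capacity
kernel:
  cv: 0.1                        # proposal std as fraction of current value
  policy: resample               # out-of-range proposals: resample | clip
  max_attempts: 100
solver:
  method: analytic               # analytic | root | integrate
  tol: 1.0e-09
  t_max: 1.0e+06
experiment:
  fractions: [0.001, 0.1, 0.5]   # fitness levels as fractions of fmax
  n_sets: 100
  n_mutations: 10000
  n_backgrounds: 4000
  target_tol: 0.01               # relative tolerance on achieved fitness
  neutral_epsilon: 0
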