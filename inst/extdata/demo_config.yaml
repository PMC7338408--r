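# Demo analysis over synthetic fixtures with embedded ground truth.
seed: 42
modules:
  permeability:
    true_PD: 1.0e-6
  morphometry:
    n_cells: 20
    ki67_fraction: 0.2
    golgi_angles: [0, 45, 90, 135]
    junctional_fraction: 0.5
  secretome:
    fold_changes:
      CK1: 3.0
      CK6: 0.5
  mechanics:
    E: 130
    n_curves: 6
    noise_sd: 2.5e-9
  transport:
    P_D: 1.0e-6
    duration: 300
  stats:
    measurement: demo_measurement
    groups:
      control: [1.1, 0.9, 1.0, 1.2, 0.8]
      mutant_a: [1.6, 1.8, 1.7, 1.5, 1.9]
      mutant_b: [1.0, 1.1, 0.9, 1.3, 0.7]
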