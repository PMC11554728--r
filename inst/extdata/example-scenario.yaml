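# Example deployment scenario: a helical filling coil into a synthetic
# "very small" dome aneurysm, inserted to 15% packing density.
seed: 1
geometry:
  synthetic:
    dome_radius_mm: 2.5
    neck_radius_mm: 1.0
    resolution: 40
    bump_amplitude: 0.04
coils:
  - shape: helix
    D1_mm: 0.05          # stock-wire diameter
    D2_mm: 0.305         # coil diameter
    D3_mm: 2.0           # imprint (loop) diameter
    E_w_GPa: 168         # platinum stock wire
    mu_w: 0.38
    pitch: 1.1
    alpha: 0.1           # axial inextensibility penalty weight
    packing_density: 0.15
    n_nodes: 300
simulation:
  v_push_mm_s: 20
  post_swap_fraction: 0.10
occlusion:
  N_V: 70
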