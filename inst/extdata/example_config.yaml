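# Example synthetic-mode configuration: an untreated control and one
# high-dose condition with swollen, rougher cells. Six fields per condition.
mode: synthetic
control: control
seed: 1
pixel_size_um: 0.0136
groups:
  - label: control
    n_images: 6
    params:
      n_cells: 45
      occluded_fraction: 0.25
  - label: zno_200
    n_images: 6
    params:
      n_cells: 45
      occluded_fraction: 0.25
      mean_area_um2: 0.458     # ~24% swollen
      roughness_amplitude: 0.028
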