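# Demo configuration for discgrowth::run_pipeline()
# Small synthetic study: one well scene, a 6-dose oxaliplatin-style
# dilution series with 4 replicates, and a 4-experiment rate table.
seed: 1
output_dir: "discgrowth_demo_out"
scene:
  image_shape: [256, 256]
  pixel_size: 27        # um/px; 6 mm disc -> radius ~111 px
  n_cells_on: 40
  n_cells_off: 15
segmentation:
  std_kernels: [7, 9]
  candidate_thresholds: [60, 100]
  struct_sizes: [5, 8]
  circularity_weight: 0.5
growth:
  n0: 100
  rate: 0.03            # per hour
  times: [0, 12, 24, 36, 48, 60, 72]
  noise_cv: 0.05
dose_response:
  doses: [0, 0.062, 0.185, 0.555, 1.667, 5]   # uM
  hill_ic50: 0.32
  hill_slope: 1
  n_replicates: 4
effects:
  n_experiments: 4
  n_replicates: 3
stats:
  chains: 2
  iter: 4000
  warmup: 1000
  contrast:
    factor: plate
    a: softwell_2kPa
    b: softwell_0.2kPa
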