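# Default experiment configuration: three preset lesions rendered through
# the eight imaging settings on the five-scanner measurement schedule.
lesions: [L1, L2, L3]
grid_spacing_mm: 2.5
fine_spacing_mm: 1
fov_mm: 80
discretization:
  B: 0.3125   # SUV bin width, absolute (FBS) discretization
  D: 64       # bin count, relative (FBN) discretization
resampling: [native]      # add 4, 3, 2.5, 1 for the spatial-resampling study
reference_setting: D
seed: 1
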