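# Default phantom presets: per-group echo-intensity mean (mu) and within-ROI
# spread (sigma_within) at the rat-liver B-mode scale; sigma_between,
# breathing and drift are phantom parameters (see the methods vignette).
groups:
  normal:
    mu: 25.4
    sigma_within: 13.2
    sigma_between: 0.25
  steatosis:
    mu: 34.7
    sigma_within: 12.0
    sigma_between: 0.25
  fibrosis:
    mu: 55.9
    sigma_within: 16.3
    sigma_between: 0.25
cases_per_group: 4
frames_per_case: 60
frame_size: [64, 64]
rois_per_frame: 5
roi_size: 16
rho: 0.5
tissue_scale_px: 4
breath_period_frames: 35
breath_amplitude: 4
amp_growth: 1.1
drift_per_frame: 0.02
seed: 1
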