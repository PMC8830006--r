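# Example simulation configuration.
# Omitted fields fall back to the defaults of cohort_config(); without a
# `blocks:` entry the full three-group, five-site calibration is used.
seed: 20260101
rho: 0.5            # exchangeable correlation of the radius triple
alpha_shift: 0      # aneurysm effect: degrees added to alpha at aneurysmal sites
r0_shift: 0         # aneurysm effect: mm added to r0 at aneurysmal sites
output: morphometry # or "landmarks" to also emit 3D points
pmw_coupled: false
angle_noise_sd: 10
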