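# Default analysis configuration.  Every constant of the standard
# two-session seed-connectivity analysis lives here, nothing is
# hard-coded in the package.
low_hz: 0.008        # band-pass lower edge, Hz (detrending band)
high_hz: 0.08        # band-pass upper edge, Hz
fwhm_mm: 6           # Gaussian smoothing kernel FWHM, mm
voxel_p: 0.001       # cluster-forming voxel-level p (one-sided)
k_min: 20            # cluster extent rule: report clusters with k > 20
n_perm: 1000         # permutations for cluster-level FWE
n_seeds_bonferroni: 13   # across-seed Bonferroni: flag FWE p < 0.05/13 (< 0.003)
fcm_m: 2             # fuzzy c-means fuzzifier
fcm_n_init: 20       # FCM random restarts (lowest objective kept)
dual_gap: 0.15       # dual-membership gap threshold
rng_seed: 1
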