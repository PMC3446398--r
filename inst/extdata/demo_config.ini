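# Demo pipeline configuration: synthetic cohort with the built-in
# BRCA2 haplotype system.

[simulate]
n_samples = 120
seed = 1
meas_cv = 0.10
n_reps = 3
carrier_n = 2754
carrier_maf = 0.16
n_studies = 11

[dae]
threshold_fold = 1.2

[risk]
stratify_by_study = false
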