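# Demonstration configuration: pure simulation at reduced cohort size.
# Coordinates throughout are 1-based closed intervals.
seed: 20240901
serology:
  spec:
    n_healthy: 150
    n_cld: 100
    n_hcc: 160
    n_peptides_per_group: [59, 281, 1671]
    ebs_location_shift: 1.0
    diagnosis_or_per_ebs_unit: 0.9
    arb_hazard_ratio: 2.0
    censor_rate: 0.3
mimicry:
  spec:
    n_background_proteins: 400
    n_spiked_surface_mimics: 1
    mimic_identity_fraction: 0.8
    enrichment_fold_spiked: 500
    intensity_noise_cv: 0.2
expression:
  spec:
    n_tumors: 97
    n_seropositive: 48
params:
  fc_cutoff: 100
  pseudocount: 1.0
  antibody_mode: any
  cell_line_mode: all
  k_panel: 40
  nk_cutoff: 0.01
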