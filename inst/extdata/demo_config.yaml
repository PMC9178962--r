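# Reduced-size demonstration configuration for run_pipeline();
# load with read_run_config(). All stages derive their seeds from `seed`.
seed: 7
n_normative: 200
normative_age_range: [20, 80]
n_control: 60
n_patient: 80
casecontrol_age_range: [18, 59]
mode: ms
delta_years: 10
injection_regions: decreasing
fdr_q: 0.01
fdr_method: BH
n_perm: 199
pls_n_perm: 199
pal_n_per_group: 40
n_regions: 120
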