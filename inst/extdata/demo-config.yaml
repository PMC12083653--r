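# Demonstration experiment: full pipeline on a synthetic corpus and cohort.
master_seed: 42
n_notes: 5000
n_patients: 5000
tune_frac: 0.1
test_frac: 0.1
model_a_accuracy: 0.85
model_b_accuracy: 0.75
dating_category: true
student_l2: 0.001
student_min_count: 2
reference_group: MARRIED
age_tolerance_years: 1
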