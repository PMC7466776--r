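d_drugs_min: 5.0
d_sep_min: 1.0
siv_ml: 2.0
sfv_ml: 4.0
resolution_s: 1.0
seed: 1
catalog_path: ~
matrix_path: ~
cohort_path: ~
out_dir: '.'
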