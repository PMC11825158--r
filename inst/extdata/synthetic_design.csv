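"sample_id","subject_id","condition","tissue_type"
"example_sample","subj01","control","fetal"
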