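design = balanced_rejection
n = 60
total_snps = 8
alpha = 0
table_form = threshold
table_mafs = 0.25,0.25
linear_columns = 
epistatic_columns = 1,2
seed = 435966639
replicate = 1
form = threshold
target_h2 = 0.25
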