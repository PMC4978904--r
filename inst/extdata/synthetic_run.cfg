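# pamscape end-to-end demonstration config: everything synthetic, fully
# seeded, so two runs produce byte-identical outputs.
genome = synthetic
n_records = 2
record_length = 50000
exons = synthetic
n_exons = 25
exon_length_min = 100
exon_length_max = 300
pam_classes = NGG,NGA,NNGRRN,NNGRRT,NNNRRN,NNNRRT
spacer_length = 20
bed_span = union
composition = uniform
seed = 42
outdir = pamscape_out
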